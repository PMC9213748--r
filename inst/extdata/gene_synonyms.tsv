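alias	canonical
cox1	cox1
coi	cox1
co1	cox1
cox-1	cox1
coxi	cox1
cox2	cox2
coii	cox2
co2	cox2
coxii	cox2
cox3	cox3
coiii	cox3
co3	cox3
coxiii	cox3
cob	cob
cytb	cob
cyt-b	cob
cyb	cob
atp6	atp6
atpase6	atp6
atp8	atp8
atpase8	atp8
nad1	ND1
nd1	ND1
nadh1	ND1
nad2	ND2
nd2	ND2
nadh2	ND2
nad3	ND3
nd3	ND3
nadh3	ND3
nad4	ND4
nd4	ND4
nadh4	ND4
nad4l	ND4L
nd4l	ND4L
nadh4l	ND4L
nad5	ND5
nd5	ND5
nadh5	ND5
nad6	ND6
nd6	ND6
nadh6	ND6
trnw	trnW
trna-trp	trnW
trnw-uca	trnW
trnm	trnM
trna-met	trnM
trnm-cau	trnM
rrns	s-rRNA
s-rrna	s-rRNA
srrna	s-rRNA
12s	s-rRNA
rns	s-rRNA
12s-rrna	s-rRNA
rrn12	s-rRNA
rrnl	l-rRNA
l-rrna	l-rRNA
lrrna	l-rRNA
16s	l-rRNA
rnl	l-rRNA
16s-rrna	l-rRNA
rrn16	l-rRNA
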