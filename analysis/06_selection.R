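#!/usr/bin/env Rscript
# Stage 6: NG86 pairwise dN/dS on the concatenated 13 PCGs (terminal
# stops stripped) and the deep-vs-shallow omega contrast. The simulated
# truth is omega 0.05 on deep branches vs 0.12 on shallow branches, a
# background/foreground fold ratio of 2.4; for scale, the published
# branch-model estimates for the real genomes (background 0.08422,
# foreground 0.03431) give a 2.45-fold difference.

library(mitocompare)

in_dir <- "results/simulated_family"
out_dir <- "results/selection"

ids <- sub("\\.fasta$", "", list.files(in_dir, pattern = "^(deep|shal).*\\.fasta$"))
genomes <- lapply(ids, function(id)
  read_feature_table(file.path(in_dir, paste0(id, ".fasta")),
                     file.path(in_dir, paste0(id, ".features.tsv"))))
grouping_tab <- read.delim(file.path(in_dir, "grouping.tsv"))
grouping <- setNames(grouping_tab$depth_class, grouping_tab$id)

cds <- lapply(genomes, concat_genes, drop_terminal_stops = TRUE)
names(cds) <- ids
ct <- group_omega_contrast(cds, grouping)

write_report_tables(
  list(omega_pairs = ct$pairs,
       omega_contrast = data.frame(
         omega_foreground = ct$omega_foreground,
         omega_background = ct$omega_background,
         fold_ratio = ct$fold_ratio,
         foreground_kind = ct$foreground_kind,
         method = ct$method)),
  out_dir, digits = 4)

cat(sprintf(
  paste0("NG86-pairwise omega on %s codons of concatenated PCGs ",
         "(%d pairs):\n  foreground (deep pairs)  omega = %.4f ",
         "(true 0.05)\n  background (shallow pairs) omega = %.4f ",
         "(true 0.12)\n  fold ratio background/foreground = %.2f ",
         "(true 2.4)\n",
         "All outputs are labelled method = NG86-pairwise: this is a ",
         "counting\nestimator, not a branch-model likelihood fit.\n"),
  format(ct$pairs$S[1] + ct$pairs$N[1], big.mark = ","),
  nrow(ct$pairs), ct$omega_foreground, ct$omega_background,
  ct$fold_ratio))
cat("Tables written to", out_dir, "\n")
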