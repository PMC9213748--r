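#!/usr/bin/env Rscript
# Stage 5: circular signed gene orders, the ND5-anchored order map, and
# pairwise breakpoint distances against the canonical actiniarian order.

library(mitocompare)

in_dir <- "results/simulated_family"
out_dir <- "results/gene_order"

ids <- sub("\\.fasta$", "", list.files(in_dir, pattern = "^(deep|shal).*\\.fasta$"))
genomes <- lapply(ids, function(id)
  read_feature_table(file.path(in_dir, paste0(id, ".fasta")),
                     file.path(in_dir, paste0(id, ".features.tsv"))))

orders <- lapply(genomes, extract_gene_order)
canon <- gene_order("canonical", canonical_gene_order())
bp <- breakpoint_table(c(list(canon), orders))
map <- order_map(c(list(canon), orders))

write_report_tables(list(breakpoints = bp, order_map = map),
                    out_dir, digits = 4)

vs_canon <- bp[bp$genome_a == "canonical", ]
cat(sprintf(
  paste0("Gene orders of %d genomes vs the canonical 17-gene ",
         "actiniarian order:\n  identical (0 breakpoints): %d/%d — the ",
         "simulator rearranges nothing,\n  so all orders match, as in ",
         "most sea anemone mitogenomes.\n"),
  length(orders), sum(vs_canon$identical), nrow(vs_canon)))
cat("Tables written to", out_dir, "\n")
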