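#!/usr/bin/env Rscript
# Stage 3: start/stop audit, codon usage and RSCU under translation
# table 4, amino-acid profiles, and the deep-vs-shallow amino-acid usage
# comparison (Welch t-tests, no multiple-testing correction, Bonferroni
# column added for transparency).

library(mitocompare)

in_dir <- "results/simulated_family"
out_dir <- "results/codon_usage"

ids <- sub("\\.fasta$", "", list.files(in_dir, pattern = "^(deep|shal).*\\.fasta$"))
genomes <- lapply(ids, function(id)
  read_feature_table(file.path(in_dir, paste0(id, ".fasta")),
                     file.path(in_dir, paste0(id, ".features.tsv"))))
grouping_tab <- read.delim(file.path(in_dir, "grouping.tsv"))
grouping <- setNames(grouping_tab$depth_class, grouping_tab$id)

code <- genetic_code(4)
audits <- do.call(rbind, lapply(genomes, function(g)
  cbind(genome = g$id, audit_start_stop(g, code))))

profiles <- list(); rscu_rows <- list()
for (g in genomes) {
  cds <- lapply(canonical_pcgs(), function(x)
    extract_feature_sequence(g, x))
  cu <- compute_rscu(count_codons(cds, code))
  rscu_rows[[g$id]] <- cbind(genome = g$id, rscu_table(cu))
  profiles[[g$id]] <- amino_acid_profile(cu, g$id)
}
rscu <- do.call(rbind, rscu_rows)
contrast <- suppressWarnings(compare_depth_groups(profiles, grouping))

write_report_tables(list(start_stop = audits, rscu = rscu,
                         depth_contrast = contrast),
                    out_dir, digits = 4)

r1 <- rscu[rscu$genome == ids[1], ]
top5 <- r1[order(-r1$rscu), ][1:5, ]
aa1 <- profiles[[1]]$aa_percent
cat(sprintf(
  paste0("Start/stop audit: %d/%d CDS use ATG; stop codons: %s.\n",
         "%s codon usage: most-used amino acid %s (%.2f%%), least %s ",
         "(%.2f%%).\nTop-5 RSCU codons: %s.\n"),
  sum(audits$start_ok), nrow(audits),
  paste(names(table(audits$stop_codon)),
        table(audits$stop_codon), collapse = ", "),
  ids[1], names(which.max(aa1)), max(aa1),
  names(which.min(aa1)), min(aa1),
  paste(sprintf("%s (%s, %.2f)", top5$codon, top5$amino_acid, top5$rscu),
        collapse = ", ")))
sig <- contrast[!is.na(contrast$p) & contrast$p < 0.05, ]
sig_bonf <- contrast[!is.na(contrast$p_bonferroni) &
                       contrast$p_bonferroni < 0.05, ]
cat(sprintf(
  paste0("Depth-group usage contrast (%d deep vs %d shallow): %d of %d ",
         "labels at\n  uncorrected p < 0.05 and %d after Bonferroni. ",
         "The family shares one\n  ancestor with no depth-linked codon ",
         "bias, so nominal hits at these\n  group sizes are chance; the ",
         "corrected column makes the null call.\n"),
  sum(grouping == "deep"), sum(grouping == "shallow"),
  nrow(sig), nrow(contrast), nrow(sig_bonf)))
cat("Tables written to", out_dir, "\n")
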