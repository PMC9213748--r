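test_that("base counting is exact, N-aware and additive", {
  c1 <- count_bases("AATTGC")
  expect_equal(c(c1$A, c1$T, c1$G, c1$C), c(2, 2, 1, 1))
  expect_equal(c1$at_percent, 100 * 4 / 6)

  cn <- count_bases("NNNN")
  expect_equal(cn$length, 4)
  expect_equal(cn$A + cn$T + cn$G + cn$C, 0)
  expect_true(cn$undefined)
  expect_true(is.na(cn$at_percent))

  set.seed(1)
  for (k in 1:5) {
    s1 <- rand_seq(50, c("A", "C", "G", "T", "N"))
    s2 <- rand_seq(30, c("A", "C", "G", "T", "N"))
    both <- count_bases(paste0(s1, s2))
    added <- count_bases(s1) + count_bases(s2)
    expect_equal(both[c("A", "T", "G", "C", "N", "length")],
                 added[c("A", "T", "G", "C", "N", "length")])
  }
  expect_error(count_bases("ACGU"), "outside")
})

test_that("skew follows (A-T)/(A+T), (G-C)/(G+C) with flagged zeros", {
  sk <- compute_skew(structure(list(A = 30, T = 30, G = 20, C = 20, N = 0,
                                    length = 100, at_percent = 60,
                                    gc_percent = 40, undefined = FALSE),
                               class = "base_composition"))
  expect_equal(c(sk$at_skew, sk$gc_skew), c(0, 0))
  sk2 <- compute_skew(structure(list(A = 0, T = 10, G = 3, C = 1, N = 0,
                                     length = 14, at_percent = NA,
                                     gc_percent = NA, undefined = FALSE),
                                class = "base_composition"))
  expect_equal(c(sk2$at_skew, sk2$gc_skew), c(-1, 0.5))
  sk3 <- compute_skew("GGCC")
  expect_true(is.na(sk3$at_skew))
  expect_true(sk3$at_undefined)
  expect_false(sk3$gc_undefined)
})

test_that("both skews flip sign under reverse complement", {
  set.seed(7)
  for (k in 1:20) {
    s <- rand_seq(sample(10:200, 1))
    a <- compute_skew(s)
    b <- compute_skew(revcomp(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
  }
})

test_that("per-gene skew table flags engineered outlier genes", {
  # atp8 built G-rich, every other CDS C-rich: exactly one positive
  # gc_skew among the per-gene rows
  cfg <- sim_config(seed = 5)
  anc <- generate_ancestor(cfg)$genome
  f <- anc$features
  pieces <- strsplit(anc$sequence, "")[[1]]
  set.seed(5)
  for (i in which(f$kind == "CDS")) {
    gc_skew <- if (f$name[i] == "atp8") 0.6 else -0.6
    span <- (f$start[i] + 4):(f$end[i] - 3)   # keep start/stop codons
    probs <- c(A = 0.31, T = 0.31, G = 0.19 * (1 + gc_skew),
               C = 0.19 * (1 - gc_skew))
    pieces[span] <- sample(names(probs), length(span), replace = TRUE,
                           prob = probs / sum(probs))
  }
  g <- mito_genome("engineered", paste(pieces, collapse = ""), f)
  tab <- per_gene_skew_table(list(g))
  genes <- tab[startsWith(tab$scope, "gene:"), ]
  expect_equal(sum(genes$gc_skew > 0), 1)
  expect_equal(genes$scope[genes$gc_skew > 0], "gene:atp8")
  # identical genomes give identical tables
  tab2 <- per_gene_skew_table(list(g, g))
  half <- nrow(tab2) / 2
  expect_equal(tab2$gc_skew[seq_len(half)], tab2$gc_skew[half + seq_len(half)])
  # a missing canonical gene yields a flagged row, not an error
  g_missing <- mito_genome("m", g$sequence, f[f$name != "atp8", ])
  tabm <- per_gene_skew_table(list(g_missing))
  expect_true(tabm$missing[tabm$scope == "gene:atp8"])
})

test_that("intergenic extraction complements the feature spans", {
  # features tiling the whole circle leave nothing
  g <- toy_genome(strrep("ACGT", 25),
                  rbind(feat_row("a", 0, 40, kind = "rRNA"),
                        feat_row("b", 40, 100, kind = "rRNA")))
  expect_equal(nrow(extract_intergenic(g)), 0)

  g2 <- toy_genome(strrep("ACGT", 25),
                   rbind(feat_row("a", 0, 40, kind = "rRNA"),
                         feat_row("b", 45, 100, kind = "rRNA")))
  ign <- extract_intergenic(g2)
  expect_equal(nrow(ign), 1)
  expect_equal(c(ign$start, ign$end, ign$length), c(40, 45, 5))
  expect_equal(c(ign$flank_up, ign$flank_down), c("a", "b"))

  # gap crossing the origin is one region with end > L
  g3 <- toy_genome(strrep("ACGT", 25),
                   feat_row("a", 10, 90, kind = "rRNA"))
  ign3 <- extract_intergenic(g3)
  expect_equal(nrow(ign3), 1)
  expect_equal(c(ign3$start, ign3$end, ign3$length), c(90, 110, 20))
})

test_that("feature lengths plus intergenic total the genome length", {
  for (seed in 1:3) {
    g <- generate_ancestor(sim_config(seed = seed))$genome
    ign <- extract_intergenic(g)
    expect_equal(sum(g$features$end - g$features$start) + sum(ign$length),
                 nchar(g$sequence))
  }
})

test_that("the default synthetic genome reproduces the planned spacers", {
  anc <- generate_ancestor(sim_config(seed = 2))
  ign <- extract_intergenic(anc$genome)
  expect_equal(nrow(ign), 17)
  expect_equal(sum(ign$length), 1112)
  expect_equal(max(ign$length), 223)
  longest <- ign[which.max(ign$length), ]
  expect_equal(c(longest$flank_up, longest$flank_down), c("ND5", "ND1"))
  cr <- ign[ign$flank_up == "s-rRNA", ]
  expect_equal(cr$length, 147)
  spacer <- substr(anc$genome$sequence, cr$start + 1, cr$end)
  expect_gte(nrow(find_cr_motif(spacer, min_run = 3)), 1)
})

test_that("motif scan matches the brute-force oracle", {
  expect_equal(find_cr_motif("GAAAT", 3),
               data.frame(start = 0L, run_length = 3L))
  expect_equal(nrow(find_cr_motif("GAAT", 3)), 0)
  # maximal run: G AAAA T counts as one hit of run 4
  expect_equal(find_cr_motif("GAAAAT", 3)$run_length, 4L)
  set.seed(11)
  for (k in 1:40) {
    s <- rand_seq(sample(20:200, 1), c("G", "A", "T", "C"))
    mr <- sample(1:4, 1)
    expect_equal(find_cr_motif(s, mr), bf_motif_scan(s, mr),
                 info = paste("seed case", k))
  }
})

test_that("circular motif scan sees matches crossing the origin", {
  # ...T | GAAA wraps to GAAAT
  s <- paste0("AAAT", strrep("C", 10), "GA")
  expect_equal(nrow(find_cr_motif(s, 3, circular = FALSE)), 0)
  hits <- find_cr_motif(s, 3, circular = TRUE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, nchar(s) - 2)
})
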