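test_that("translation table 4 has stops TAA/TAG and TGA as Trp", {
  code <- genetic_code(4)
  expect_setequal(code$stops, c("TAA", "TAG"))
  expect_equal(unname(code$map["TGA"]), "W")
  expect_equal(length(code$map), 64)
})

test_that("start/stop audit reports first and last codons with flags", {
  g <- toy_genome(paste0("ATGGTTTAA", "GTGGTTTAG", "CC"),
                  rbind(feat_row("a", 0, 9), feat_row("b", 9, 18)))
  aud <- audit_start_stop(g)
  expect_equal(aud$start_codon, c("ATG", "GTG"))
  expect_equal(aud$stop_codon, c("TAA", "TAG"))
  expect_equal(aud$start_ok, c(TRUE, FALSE))
  expect_equal(aud$stop_ok, c(TRUE, TRUE))
})

test_that("the default synthetic genome audits as 12x ATG/TAA + ND3 TAG", {
  g <- generate_ancestor(sim_config(seed = 4))$genome
  aud <- audit_start_stop(g)
  expect_equal(nrow(aud), 13)
  expect_true(all(aud$start_codon == "ATG"))
  expect_equal(aud$stop_codon[aud$gene == "ND3"], "TAG")
  expect_true(all(aud$stop_codon[aud$gene != "ND3"] == "TAA"))
})

test_that("codon counting pools sequences and tallies stops separately", {
  cu <- count_codons("ATGTAA")
  expect_equal(unname(cu$counts["ATG"]), 1)
  expect_equal(unname(cu$stop_counts["TAA"]), 1)
  expect_equal(cu$total_codons, 1)

  cu2 <- count_codons(c("ATGGTTTAA", "ATGGTTTAA"))
  expect_equal(unname(cu2$counts[c("ATG", "GTT")]), c(2, 2))

  # additivity over concatenating CDS lists
  set.seed(3)
  seqs <- replicate(4, paste0("ATG", rand_seq(30)))
  a <- count_codons(seqs[1:2])
  b <- count_codons(seqs[3:4])
  both <- count_codons(seqs)
  expect_equal(both$counts, a$counts + b$counts)

  # codons containing N are skipped and logged
  expect_message(cu3 <- count_codons("ATGANTGGG"), "skipped")
  expect_equal(cu3$n_skipped, 1)
  expect_equal(cu3$total_codons, 2)
})

test_that("RSCU equals count over family mean, with exact invariants", {
  code <- genetic_code(4)
  # uniform usage in every family -> all RSCU 1
  sense <- names(code$map)[code$map != "*"]
  cu <- count_codons(sense)           # each sense codon once
  cu <- compute_rscu(cu)
  expect_true(all(abs(cu$rscu - 1) < 1e-9))

  # 2-codon family used 3:1 -> 1.5 / 0.5 (Lys: AAA, AAG)
  cu2 <- compute_rscu(count_codons(c("AAA", "AAA", "AAA", "AAG")))
  expect_equal(unname(cu2$rscu[c("AAA", "AAG")]), c(1.5, 0.5))
  # unexpressed families are NA, not 0
  expect_true(all(is.na(cu2$rscu[code$map[names(cu2$rscu)] == "G"])))

  # family mean 1 and family sum = degeneracy on random usage
  set.seed(9)
  cu3 <- compute_rscu(count_codons(paste0(
    "ATG", rand_seq(3 * 500), "TAA")))
  for (aa in setdiff(unique(code$map), "*")) {
    fam <- names(code$map)[code$map == aa & code$map != "*"]
    fam <- intersect(fam, names(cu3$rscu))
    if (sum(cu3$counts[fam]) == 0) next
    expect_equal(mean(cu3$rscu[fam]), 1, tolerance = 1e-9)
    expect_equal(sum(cu3$rscu[fam]), length(fam), tolerance = 1e-9)
  }
})

test_that("amino-acid profiles sum to 100 and follow the class table", {
  cu <- count_codons(c("ATG", "ATG"))
  prof <- amino_acid_profile(cu, "onlymet")
  expect_equal(unname(prof$aa_percent["M"]), 100)
  expect_equal(unname(prof$class_percent["nonpolar"]), 100)

  set.seed(13)
  for (k in 1:3) {
    cu <- count_codons(paste0("ATG", rand_seq(3 * 200), "TAA"))
    p <- amino_acid_profile(cu, "r")
    expect_equal(sum(p$aa_percent), 100, tolerance = 1e-9)
    expect_equal(sum(p$class_percent), 100, tolerance = 1e-9)
  }
})

test_that("a codon-bias override raises the targeted amino acid", {
  base <- generate_ancestor(sim_config(seed = 21))
  biased <- generate_ancestor(sim_config(seed = 21,
                                         codon_bias = c(GTT = 4, GTA = 4,
                                                        GTG = 4, GTC = 4)))
  prof_of <- function(g) {
    cds <- lapply(canonical_pcgs(),
                  function(x) extract_feature_sequence(g, x))
    amino_acid_profile(count_codons(cds), g$id)
  }
  v0 <- prof_of(base$genome)$aa_percent["V"]
  v1 <- prof_of(biased$genome)$aa_percent["V"]
  expect_gt(v1, v0 + 5)
})

fake_profile <- function(id, aa_percent) {
  classes <- c("nonpolar", "polar_uncharged", "charged")
  cls <- vapply(classes, function(k)
    sum(aa_percent[names(mitocompare:::AA_CLASSES)[
      mitocompare:::AA_CLASSES == k]]), numeric(1))
  structure(list(genome = id, aa_percent = aa_percent,
                 class_percent = cls, aa_count = aa_percent,
                 total_codons = 100), class = "aa_profile")
}

test_that("identical depth groups give t = 0, p = 1 everywhere", {
  aa <- setNames(rep(5, 20), mitocompare:::AA_ORDER)
  profs <- lapply(c("a", "b", "c", "d"), fake_profile, aa_percent = aa)
  grouping <- c(a = "deep", b = "deep", c = "shallow", d = "shallow")
  res <- suppressWarnings(compare_depth_groups(profs, grouping))
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("an elevated-valine deep group is detected by the Welch test", {
  set.seed(101)
  n_deep <- 2; n_shallow <- 12
  mk <- function(id, valine) {
    aa <- setNames(abs(rnorm(20, 5, 0.3)), mitocompare:::AA_ORDER)
    aa["V"] <- valine
    fake_profile(id, 100 * aa / sum(aa))
  }
  profs <- c(lapply(seq_len(n_deep), function(i)
    mk(paste0("d", i), rnorm(1, 8.5, 0.04))),
    lapply(seq_len(n_shallow), function(i)
      mk(paste0("s", i), rnorm(1, 7.5, 0.3))))
  grouping <- setNames(c(rep("deep", n_deep), rep("shallow", n_shallow)),
                       vapply(profs, `[[`, character(1), "genome"))
  res <- compare_depth_groups(profs, grouping)
  aa_rows <- res[res$label %in% mitocompare:::AA_ORDER, ]
  expect_lt(aa_rows$p[aa_rows$label == "V"], 0.01)
  others <- aa_rows[aa_rows$label != "V", ]
  expect_true(all(others$p > 0.05 | is.na(others$p)))
  expect_true(all(aa_rows$flag %in% c("", "small group (n < 3)")))
})

test_that("group relabeling flips the sign of t", {
  set.seed(55)
  aa <- function() setNames(abs(rnorm(20, 5, 0.5)),
                            mitocompare:::AA_ORDER)
  profs <- lapply(letters[1:6], function(id)
    fake_profile(id, {x <- aa(); 100 * x / sum(x)}))
  g1 <- setNames(rep(c("deep", "shallow"), each = 3), letters[1:6])
  g2 <- setNames(rep(c("shallow", "deep"), each = 3), letters[1:6])
  r1 <- compare_depth_groups(profs, g1)
  r2 <- compare_depth_groups(profs, g2)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("a group with one genome yields flagged rows, not an error", {
  aa <- setNames(rep(5, 20), mitocompare:::AA_ORDER)
  profs <- lapply(c("a", "b", "c"), fake_profile, aa_percent = aa)
  grouping <- c(a = "deep", b = "shallow", c = "shallow")
  expect_warning(res <- compare_depth_groups(profs, grouping),
                 "fewer than 2")
  expect_true(all(is.na(res$t)))
  expect_true(all(grepl("untestable", res$flag)))
})
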