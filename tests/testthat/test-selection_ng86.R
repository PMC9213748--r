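test_that("site counts enumerate single-base changes, stops excluded", {
  # AAA under table 4: third position AAG synonymous, AAC/AAT not;
  # first position TAA is a stop and leaves CAA/GAA (both nonsyn);
  # second position fully nonsynonymous -> S = 1/3
  sc <- ng_site_counts("AAA")
  expect_equal(unname(sc["S"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(sc["N"]), 8 / 3, tolerance = 1e-12)

  # additivity over identical codons
  sc5 <- ng_site_counts(strrep("AAA", 5))
  expect_equal(unname(sc5["S"]), 5 / 3, tolerance = 1e-12)

  # direct independent enumeration for every sense codon
  code <- genetic_code(4)
  tabs <- ng86_tables(code)
  bases <- c("A", "C", "G", "T")
  for (cd in sample(names(code$map)[code$map != "*"], 12)) {
    S <- 0
    b0 <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      s <- 0; n <- 0
      for (alt in setdiff(bases, b0[pos])) {
        b <- b0; b[pos] <- alt
        aa <- code$map[paste(b, collapse = "")]
        if (aa == "*") next
        if (aa == code$map[cd]) s <- s + 1 else n <- n + 1
      }
      if (s + n > 0) S <- S + s / (s + n)
    }
    expect_equal(unname(tabs$syn_sites[cd]), S, tolerance = 1e-12)
  }
})

test_that("S + N equals 3 x codons for random stop-free sequences", {
  set.seed(23)
  code <- genetic_code(4)
  sense <- names(code$map)[code$map != "*"]
  for (k in 1:10) {
    cods <- sample(sense, sample(5:50, 1), replace = TRUE)
    sc <- ng_site_counts(cods)
    expect_equal(unname(sc["S"] + sc["N"]), 3 * length(cods),
                 tolerance = 1e-9)
  }
})

test_that("internal stops error; terminal stops are dropped", {
  expect_error(ng_site_counts("ATGTAAGGG"), "internal stop")
  sc <- ng_site_counts("ATGGGGTAA")
  expect_equal(attr(sc, "codons_counted"), 2)
})

test_that("difference counts average over stop-free pathways", {
  expect_equal(as.numeric(ng_difference_counts("AAA", "AAA")), c(0, 0))
  # AAA -> AAG is one synonymous change (Lys -> Lys)
  expect_equal(as.numeric(ng_difference_counts("AAA", "AAG")), c(1, 0))
  # brute-force oracle over random codon pairs incl. 2 and 3 differences
  set.seed(29)
  code <- genetic_code(4)
  sense <- names(code$map)[code$map != "*"]
  checked <- 0
  while (checked < 60) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    oracle <- bf_ng_diff(c1, c2, code$map)
    d <- suppressWarnings(ng_difference_counts(c1, c2))
    if (is.null(oracle)) {
      tabs <- ng86_tables(code)
      expect_true(tabs$fallback[c1, c2])
    } else {
      expect_equal(as.numeric(d), oracle, tolerance = 1e-12,
                   info = paste(c1, c2))
    }
    checked <- checked + 1
  }
})

test_that("pathway counts match brute force on random 30-codon pairs", {
  set.seed(57)
  code <- genetic_code(4)
  sense <- names(code$map)[code$map != "*"]
  tabs <- ng86_tables(code)
  for (k in 1:5) {
    a <- sample(sense, 30, replace = TRUE)
    b <- a
    mut <- sample(30, 8)
    b[mut] <- sample(sense, 8, replace = TRUE)
    keep <- !tabs$fallback[cbind(a, b)]
    d <- suppressWarnings(ng_difference_counts(a[keep], b[keep]))
    oracle <- Reduce(`+`, Map(function(x, y) bf_ng_diff(x, y, code$map),
                              a[keep], b[keep]))
    expect_equal(as.numeric(d), oracle, tolerance = 1e-10)
  }
})

test_that("pairwise omega is symmetric with the documented flags", {
  set.seed(61)
  code <- genetic_code(4)
  sense <- names(code$map)[code$map != "*"]
  a <- paste(sample(sense, 200, replace = TRUE), collapse = "")
  bv <- split_codons(a)
  bv[sample(200, 20)] <- sample(sense, 20, replace = TRUE)
  b <- paste(bv, collapse = "")
  r1 <- suppressWarnings(pairwise_omega(a, b))
  r2 <- suppressWarnings(pairwise_omega(b, a))
  expect_equal(r1$dN, r2$dN)
  expect_equal(r1$dS, r2$dS)
  expect_equal(r1$omega, r2$omega)
  expect_equal(r1$S + r1$N, 3 * r1$codons_compared, tolerance = 1e-9)
  expect_equal(r1$method, "NG86-pairwise")

  # identical sequences: dN = dS = 0, omega undefined
  ri <- pairwise_omega(a, a)
  expect_equal(c(ri$dN, ri$dS), c(0, 0))
  expect_true(is.na(ri$omega))
  expect_equal(ri$flag, "identical")

  # synonymous-only divergence: omega = 0
  av <- split_codons(a)
  bs <- av
  bs[av == "AAA"] <- "AAG"
  if (!any(av == "AAA")) bs[1] <- av[1]
  rs <- pairwise_omega(paste(av, collapse = ""),
                       paste(bs, collapse = ""))
  expect_equal(rs$omega, 0)
})

test_that("Jukes-Cantor correction is monotone and flags saturation", {
  ps <- seq(0, 0.7, by = 0.05)
  ds <- vapply(ps, mitocompare:::.jc_correct, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds[-1] > ps[-1]))     # correction inflates p
  expect_true(is.na(mitocompare:::.jc_correct(0.76)))
  # a saturated pair is flagged, never clamped
  a <- strrep("GGG", 50)
  b <- strrep("GAT", 50)
  r <- suppressWarnings(pairwise_omega(a, b))
  expect_equal(r$flag, "saturated")
  expect_true(is.na(r$omega))
})

test_that("the group contrast separates foreground and background", {
  tips <- data.frame(id = c("d1", "d2", "s1", "s2", "s3"),
                     branch_length = 0.08,
                     omega = c(0.05, 0.05, 0.3, 0.3, 0.3),
                     depth_class = c("deep", "deep", rep("shallow", 3)),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 71, tips = tips)
  fam <- evolve_family(generate_ancestor(cfg)$genome, cfg)
  cds <- lapply(fam$genomes, concat_genes, drop_terminal_stops = TRUE)
  grouping <- setNames(tips$depth_class, tips$id)
  ct <- group_omega_contrast(cds, grouping)
  expect_equal(ct$foreground_kind, "deep_pairs")
  expect_lt(ct$omega_foreground, ct$omega_background)
  expect_gt(ct$fold_ratio, 1)
  expect_equal(nrow(ct$pairs), choose(5, 2))

  # single deep genome: foreground falls back to deep-vs-shallow pairs
  ct1 <- group_omega_contrast(cds[c("d1", "s1", "s2", "s3")],
                              grouping)
  expect_equal(ct1$foreground_kind, "deep_vs_shallow_pairs")
})

test_that("synonymous-only families give zero omegas, ratio undefined", {
  code <- genetic_code(4)
  set.seed(83)
  sense <- names(code$map)[code$map != "*"]
  base <- sample(sense, 300, replace = TRUE)
  syn_mutate <- function(cods, k) {
    # single-step synonymous substitutions only: same amino acid and the
    # same first two bases, so no nonsynonymous pathway steps arise
    for (i in sample(seq_along(cods), k)) {
      fam <- sense[code$map[sense] == code$map[cods[i]] &
                     substr(sense, 1, 2) == substr(cods[i], 1, 2)]
      cods[i] <- sample(fam, 1)
    }
    cods
  }
  cds <- list(a = paste(base, collapse = ""),
              b = paste(syn_mutate(base, 30), collapse = ""),
              c = paste(syn_mutate(base, 30), collapse = ""),
              d = paste(syn_mutate(base, 30), collapse = ""))
  grouping <- c(a = "deep", b = "deep", c = "shallow", d = "shallow")
  ct <- group_omega_contrast(cds, grouping)
  expect_equal(ct$omega_foreground, 0)
  expect_equal(ct$omega_background, 0)
  expect_true(is.na(ct$fold_ratio))
})
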