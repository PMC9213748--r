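# Codon counting, RSCU, start/stop auditing and amino-acid usage profiles
# under a configurable NCBI genetic code (default: table 4, the
# mold/protozoan/coelenterate mitochondrial code, in which TGA encodes
# tryptophan and the stops are TAA/TAG).

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residue classes used for the depth-group contrasts
AA_CLASSES <- c(
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
  W = "nonpolar",
  S = "polar_uncharged", T = "polar_uncharged", C = "polar_uncharged",
  Y = "polar_uncharged", N = "polar_uncharged", Q = "polar_uncharged",
  D = "charged", E = "charged", K = "charged", R = "charged",
  H = "charged")

#' Genetic code table
#'
#' Wraps an NCBI translation table from Biostrings. The default, table 4,
#' is the mold/protozoan/coelenterate mitochondrial code used for anthozoan
#' mitogenomes (stops TAA/TAG; TGA = Trp).
#'
#' @param table_id NCBI translation table id (default 4).
#' @return object of class `genetic_code`: `table_id`, the 64-entry
#'   `map` (stops as `"*"`), `stops`, and the `starts` set (ATG plus the
#'   table's alternative initiators).
#' @export
genetic_code <- function(table_id = 4L) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  starts <- unique(c("ATG", attr(map, "alt_init_codons")))
  structure(list(table_id = as.integer(table_id),
                 map = stats::setNames(as.character(map), names(map)),
                 stops = names(map)[map == "*"],
                 starts = starts),
            class = "genetic_code")
}

#' Translate a codon vector
#' @param codons character vector of codons (A/C/G/T only).
#' @param code a [genetic_code()].
#' @return amino-acid characters (`"*"` for stops, `NA` for codons
#'   containing N).
#' @export
translate_codons <- function(codons, code = genetic_code()) {
  unname(code$map[codons])
}

#' Split a CDS into codons
#' @param cds nucleotide string, length divisible by 3.
#' @return character vector of codons.
#' @export
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " not divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Audit start and stop codons of all CDS in a genome
#'
#' @param genome a [mito_genome()] object.
#' @param code a [genetic_code()].
#' @return data.frame `gene start_codon stop_codon start_ok stop_ok
#'   frame_ok`; `start_ok` is TRUE only for ATG, `stop_ok` for a stop codon
#'   of the code. A CDS whose length is not divisible by 3 gets a flagged
#'   row (`frame_ok = FALSE`) with NA codons.
#' @export
audit_start_stop <- function(genome, code = genetic_code()) {
  f <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  rows <- lapply(seq_len(nrow(f)), function(i) {
    s <- extract_feature_sequence(genome, f[i, ])
    if (nchar(s) %% 3L != 0L)
      return(data.frame(gene = f$name[i], start_codon = NA_character_,
                        stop_codon = NA_character_, start_ok = FALSE,
                        stop_ok = FALSE, frame_ok = FALSE,
                        stringsAsFactors = FALSE))
    cods <- split_codons(s)
    data.frame(gene = f$name[i], start_codon = cods[1],
               stop_codon = cods[length(cods)],
               start_ok = cods[1] == "ATG",
               stop_ok = cods[length(cods)] %in% code$stops,
               frame_ok = TRUE, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene = character(), start_codon = character(),
                      stop_codon = character(), start_ok = logical(),
                      stop_ok = logical(), frame_ok = logical()))
  do.call(rbind, rows)
}

#' Count codon usage over a set of CDS
#'
#' Codon counts are pooled over all sequences. Codons mapping to a stop are
#' tallied separately and excluded from the usage statistics; codons
#' containing an N are skipped and counted in `n_skipped`.
#'
#' @param cds_sequences character vector or list of CDS nucleotide strings,
#'   each of length divisible by 3.
#' @param code a [genetic_code()].
#' @return object of class `codon_usage`: `counts` (64-entry named vector,
#'   stop codons zeroed), `stop_counts`, `total_codons` (non-stop),
#'   `n_skipped`, `code`, and `rscu` (NULL until [compute_rscu()]).
#' @export
count_codons <- function(cds_sequences, code = genetic_code()) {
  cods <- unlist(lapply(cds_sequences, split_codons), use.names = FALSE)
  has_n <- grepl("N", cods, fixed = TRUE)
  n_skipped <- sum(has_n)
  if (n_skipped)
    message(n_skipped, " codon(s) containing N skipped")
  cods <- cods[!has_n]
  all64 <- names(code$map)
  tab <- table(factor(cods, levels = all64))
  counts <- stats::setNames(as.integer(tab), all64)
  stop_counts <- counts[code$stops]
  counts[code$stops] <- 0L
  structure(list(counts = counts, stop_counts = stop_counts,
                 total_codons = sum(counts), n_skipped = n_skipped,
                 code = code, rscu = NULL),
            class = "codon_usage")
}

#' Compute relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its count divided by the mean count over its
#' synonymous family (the codons encoding the same amino acid, stops
#' excluded). A family with zero total usage gets `NA` RSCU, not 0.
#'
#' @param table a [count_codons()] result.
#' @return the same object with `rscu` filled (named vector over the sense
#'   codons).
#' @export
compute_rscu <- function(table) {
  code <- table$code
  sense <- names(code$map)[code$map != "*"]
  rscu <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (aa in unique(code$map[sense])) {
    fam <- sense[code$map[sense] == aa]
    tot <- sum(table$counts[fam])
    if (tot > 0) rscu[fam] <- table$counts[fam] / (tot / length(fam))
  }
  table$rscu <- rscu
  table
}

#' Tidy RSCU table
#' @param table a [compute_rscu()] result.
#' @return data.frame `codon amino_acid count rscu`, codons in fixed
#'   alphabetical family order.
#' @export
rscu_table <- function(table) {
  if (is.null(table$rscu)) table <- compute_rscu(table)
  sense <- names(table$rscu)
  out <- data.frame(codon = sense,
                    amino_acid = unname(table$code$map[sense]),
                    count = unname(table$counts[sense]),
                    rscu = unname(table$rscu), stringsAsFactors = FALSE)
  out[order(out$amino_acid, out$codon), , drop = FALSE]
}

#' Amino-acid usage profile of a codon usage table
#'
#' Per-amino-acid usage percentages (of all non-stop codons) and the
#' nonpolar / polar-uncharged / charged class percentages.
#'
#' @param table a [count_codons()] result.
#' @param genome_id identifier attached to the profile.
#' @return object of class `aa_profile`: `genome`, `aa_percent` (named,
#'   20 values summing to 100), `class_percent` (3 values summing to 100),
#'   `aa_count`, `total_codons`.
#' @export
amino_acid_profile <- function(table, genome_id = "genome") {
  code <- table$code
  sense <- names(code$map)[code$map != "*"]
  aa_count <- stats::setNames(numeric(length(AA_ORDER)), AA_ORDER)
  for (aa in AA_ORDER)
    aa_count[aa] <- sum(table$counts[sense[code$map[sense] == aa]])
  tot <- sum(aa_count)
  aa_percent <- if (tot > 0) 100 * aa_count / tot else aa_count * NA_real_
  cls <- stats::setNames(numeric(3),
                         c("nonpolar", "polar_uncharged", "charged"))
  for (k in names(cls))
    cls[k] <- sum(aa_percent[names(AA_CLASSES)[AA_CLASSES == k]])
  structure(list(genome = genome_id, aa_percent = aa_percent,
                 class_percent = cls, aa_count = aa_count,
                 total_codons = tot),
            class = "aa_profile")
}

.welch_row <- function(label, deep, shallow) {
  n1 <- length(deep); n2 <- length(shallow)
  m1 <- mean(deep); m2 <- mean(shallow)
  s1 <- stats::sd(deep); s2 <- stats::sd(shallow)
  flag <- ""
  if (n1 < 2 || n2 < 2) {
    t <- NA_real_; p <- NA_real_; flag <- "untestable: group n < 2"
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) {
      if (m1 == m2) { t <- 0; p <- 1 }
      else { t <- sign(m1 - m2) * Inf; p <- 0; flag <- "zero variance" }
    } else {
      tt <- stats::t.test(deep, shallow, var.equal = FALSE)
      t <- unname(tt$statistic); p <- tt$p.value
    }
    if (min(n1, n2) < 3 && !nzchar(flag)) flag <- "small group (n < 3)"
  }
  data.frame(label = label, mean_deep = m1, sd_deep = s1,
             mean_shallow = m2, sd_shallow = s2,
             n_deep = n1, n_shallow = n2, t = t, p = p,
             flag = flag, stringsAsFactors = FALSE)
}

#' Compare amino-acid usage between depth groups
#'
#' Welch two-sided t-tests of deep-group vs shallow-group usage
#' percentages, per amino acid (20 tests) and per residue class (3 tests).
#' No multiple-testing correction is applied to the reported p values; a
#' Bonferroni column (within the amino-acid block and within the class
#' block) is added for transparency.
#'
#' @param profiles list of [amino_acid_profile()] objects.
#' @param grouping named character vector mapping genome id to `"deep"` or
#'   `"shallow"`.
#' @return data.frame `label mean_deep sd_deep mean_shallow sd_shallow
#'   n_deep n_shallow t p p_bonferroni flag`.
#' @export
compare_depth_groups <- function(profiles, grouping) {
  ids <- vapply(profiles, `[[`, character(1), "genome")
  grp <- grouping[ids]
  if (any(is.na(grp)))
    stop("no depth group for: ", paste(ids[is.na(grp)], collapse = ", "),
         call. = FALSE)
  deep_i <- which(grp == "deep"); shal_i <- which(grp == "shallow")
  if (min(length(deep_i), length(shal_i)) < 2)
    warning("a depth group has fewer than 2 genomes; t statistics flagged",
            call. = FALSE)
  aa_mat <- vapply(profiles, `[[`, numeric(length(AA_ORDER)), "aa_percent")
  cls_mat <- vapply(profiles, `[[`, numeric(3), "class_percent")
  aa_rows <- do.call(rbind, lapply(AA_ORDER, function(aa)
    .welch_row(aa, aa_mat[aa, deep_i], aa_mat[aa, shal_i])))
  cls_rows <- do.call(rbind, lapply(rownames(cls_mat), function(k)
    .welch_row(k, cls_mat[k, deep_i], cls_mat[k, shal_i])))
  aa_rows$p_bonferroni <- stats::p.adjust(aa_rows$p, "bonferroni")
  cls_rows$p_bonferroni <- stats::p.adjust(cls_rows$p, "bonferroni")
  out <- rbind(aa_rows, cls_rows)
  out[, c("label", "mean_deep", "sd_deep", "mean_shallow", "sd_shallow",
          "n_deep", "n_shallow", "t", "p", "p_bonferroni", "flag")]
}
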