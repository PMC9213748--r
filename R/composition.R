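# Base composition, AT/GC skew, intergenic-region accounting and the
# control-region-like G(A)nT motif scan.
#
# Skews follow the standard definitions AT skew = (A - T)/(A + T) and
# GC skew = (G - C)/(G + C). N bases are excluded from all denominators
# (the statistics are defined on the four unambiguous bases); the N count
# is reported separately.

#' Count bases of a nucleotide string
#'
#' @param seq nucleotide string over A/C/G/T/N.
#' @return object of class `base_composition`: counts of A, T, G, C, N,
#'   total `length`, and `at_percent`/`gc_percent` computed over
#'   A+T+G+C only (`NA` and `undefined = TRUE` when no unambiguous base is
#'   present).
#' @export
count_bases <- function(seq) {
  seq <- toupper(seq)
  .check_alphabet(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  tab <- table(factor(chars, levels = names(n)))
  n[names(tab)] <- as.integer(tab)
  acgt <- sum(n[c("A", "C", "G", "T")])
  structure(list(
    A = unname(n["A"]), T = unname(n["T"]), G = unname(n["G"]),
    C = unname(n["C"]), N = unname(n["N"]), length = nchar(seq),
    at_percent = if (acgt) 100 * (n[["A"]] + n[["T"]]) / acgt else NA_real_,
    gc_percent = if (acgt) 100 * (n[["G"]] + n[["C"]]) / acgt else NA_real_,
    undefined = acgt == 0L), class = "base_composition")
}

#' Add two base compositions
#' @param e1,e2 `base_composition` objects.
#' @return their sum (composition of the concatenated sequences).
#' @export
`+.base_composition` <- function(e1, e2) {
  n <- lapply(c("A", "T", "G", "C", "N", "length"),
              function(k) e1[[k]] + e2[[k]])
  names(n) <- c("A", "T", "G", "C", "N", "length")
  acgt <- n$A + n$T + n$G + n$C
  structure(c(n, list(
    at_percent = if (acgt) 100 * (n$A + n$T) / acgt else NA_real_,
    gc_percent = if (acgt) 100 * (n$G + n$C) / acgt else NA_real_,
    undefined = acgt == 0L)), class = "base_composition")
}

#' Compute AT and GC skew
#'
#' AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C). A zero denominator
#' yields `NA` with the corresponding `*_undefined` flag set, never an
#' error.
#'
#' @param x a `base_composition` (from [count_bases()]) or a nucleotide
#'   string.
#' @param scope optional label (e.g. `"whole_genome"`, `"gene:atp8"`).
#' @return object of class `skew_record` with `at_skew`, `gc_skew`, the
#'   undefined flags and the scope label.
#' @export
compute_skew <- function(x, scope = NA_character_) {
  comp <- if (inherits(x, "base_composition")) x else count_bases(x)
  at <- comp$A + comp$T
  gc <- comp$G + comp$C
  structure(list(
    scope = scope,
    at_skew = if (at) (comp$A - comp$T) / at else NA_real_,
    gc_skew = if (gc) (comp$G - comp$C) / gc else NA_real_,
    at_undefined = at == 0L, gc_undefined = gc == 0L),
    class = "skew_record")
}

.comp_skew_row <- function(genome_id, scope, seq) {
  comp <- count_bases(seq)
  sk <- compute_skew(comp, scope)
  data.frame(genome = genome_id, scope = scope,
             A = comp$A, T = comp$T, G = comp$G, C = comp$C, N = comp$N,
             at_percent = comp$at_percent, gc_percent = comp$gc_percent,
             at_skew = sk$at_skew, gc_skew = sk$gc_skew,
             missing = FALSE, stringsAsFactors = FALSE)
}

.missing_row <- function(genome_id, scope) {
  data.frame(genome = genome_id, scope = scope,
             A = NA_integer_, T = NA_integer_, G = NA_integer_,
             C = NA_integer_, N = NA_integer_,
             at_percent = NA_real_, gc_percent = NA_real_,
             at_skew = NA_real_, gc_skew = NA_real_,
             missing = TRUE, stringsAsFactors = FALSE)
}

#' Per-gene and aggregate skew table for a set of genomes
#'
#' One row per genome and canonical PCG (`scope = "gene:<name>"`, skew
#' measured on the coding/extracted strand) plus three aggregate scopes per
#' genome: the whole genome, the 13 PCGs concatenated in canonical order
#' (stop codons included) and the two rRNAs concatenated. Genomes missing a
#' canonical gene get a flagged row for it.
#'
#' @param genomes list of [mito_genome()] objects.
#' @return data.frame with columns
#'   `genome scope A T G C N at_percent gc_percent at_skew gc_skew missing`.
#' @export
per_gene_skew_table <- function(genomes) {
  rows <- list()
  for (g in genomes) {
    rows[[length(rows) + 1]] <-
      .comp_skew_row(g$id, "whole_genome", g$sequence)
    pcg <- canonical_pcgs()
    present <- pcg[pcg %in% g$features$name]
    if (length(present))
      rows[[length(rows) + 1]] <- .comp_skew_row(
        g$id, "PCGs_concatenated",
        paste(vapply(present, function(x) extract_feature_sequence(g, x),
                     character(1)), collapse = ""))
    rr <- c("s-rRNA", "l-rRNA")
    rpresent <- rr[rr %in% g$features$name]
    if (length(rpresent))
      rows[[length(rows) + 1]] <- .comp_skew_row(
        g$id, "rRNAs_concatenated",
        paste(vapply(rpresent, function(x) extract_feature_sequence(g, x),
                     character(1)), collapse = ""))
    for (gene in pcg) {
      rows[[length(rows) + 1]] <- if (gene %in% g$features$name)
        .comp_skew_row(g$id, paste0("gene:", gene),
                       extract_feature_sequence(g, gene))
      else .missing_row(g$id, paste0("gene:", gene))
    }
  }
  do.call(rbind, rows)
}

#' Extract intergenic regions of a circular genome
#'
#' Returns the complement of the union of annotated feature spans on the
#' circle, split into maximal uncovered runs, each with its flanking gene
#' labels. A region crossing the origin is reported with `end > genome
#' length`. Overlapping features are tolerated (the overlap is simply
#' covered) with a warning.
#'
#' @param genome a [mito_genome()] object.
#' @return data.frame `start end length flank_up flank_down` (0-based
#'   half-open coordinates), ordered by start.
#' @export
extract_intergenic <- function(genome) {
  f <- genome$features
  L <- nchar(genome$sequence)
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), flank_up = character(),
                      flank_down = character(), stringsAsFactors = FALSE)
  if (!nrow(f))
    return(data.frame(start = 0L, end = L, length = L,
                      flank_up = NA_character_, flank_down = NA_character_,
                      stringsAsFactors = FALSE))
  covered <- logical(L)
  multi <- 0L
  for (i in seq_len(nrow(f))) {
    pos <- .feature_positions(f[i, ], L) + 1L
    multi <- multi + sum(covered[pos])
    covered[pos] <- TRUE
  }
  if (multi > 0)
    warning("overlapping features in '", genome$id, "' (", multi,
            " bp); overlap trimmed from intergenic accounting",
            call. = FALSE)
  if (all(covered)) return(empty)
  # runs of uncovered positions, joining across the origin on a circle
  uncov <- which(!covered) - 1L           # 0-based
  breaks <- which(diff(uncov) > 1L)
  starts <- uncov[c(1L, breaks + 1L)]
  ends <- uncov[c(breaks, length(uncov))] + 1L
  if (genome$circular && length(starts) > 1 &&
      starts[1] == 0L && ends[length(ends)] == L) {
    starts <- c(starts[-1])
    ends[length(ends)] <- L + ends[1]
    ends <- ends[-1]
  }
  # flanking genes: feature ending at run start / starting at run end (mod L)
  fend <- f$end %% L
  fstart <- f$start %% L
  flank_up <- vapply(starts, function(s) {
    i <- which(fend == (s %% L))
    if (length(i)) f$name[i[1]] else NA_character_
  }, character(1))
  flank_down <- vapply(ends, function(e) {
    i <- which(fstart == (e %% L))
    if (length(i)) f$name[i[1]] else NA_character_
  }, character(1))
  data.frame(start = starts, end = ends, length = ends - starts,
             flank_up = flank_up, flank_down = flank_down,
             stringsAsFactors = FALSE)
}

#' Scan for the control-region-like G(A)nT motif
#'
#' Finds non-overlapping, left-to-right maximal matches of `G A{min_run,} T`
#' — a G, then at least `min_run` A's (taken maximally), then a T. On
#' circular scans the match may cross the origin.
#'
#' @param seq nucleotide string.
#' @param min_run minimum number of A's (default 3).
#' @param circular scan across the origin.
#' @return data.frame `start run_length` with 0-based match starts.
#' @export
find_cr_motif <- function(seq, min_run = 3L, circular = FALSE) {
  stopifnot(min_run >= 1)
  seq <- toupper(seq)
  .check_alphabet(seq)
  n <- nchar(seq)
  scan <- if (circular && n > 1) paste0(seq, substr(seq, 1L, n - 1L)) else seq
  pat <- sprintf("GA{%d,}T", min_run)
  m <- gregexpr(pat, scan)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), run_length = integer()))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length") - 2L
  keep <- starts < n
  data.frame(start = starts[keep], run_length = lens[keep])
}
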