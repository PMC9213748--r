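# Nucleotide diversity (Pi): average pairwise proportion of differing
# sites over an alignment, whole-gene and in sliding windows (default
# 100 bp window, 25 bp step, matching the common DnaSP setting). Raw
# (uncorrected) Pi; no Jukes-Cantor correction is applied.

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

.clean_cols <- function(mat) {
  # complete deletion: keep sites where every sequence has an unambiguous base
  apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
}

.pi_from_matrix <- function(mat, deletion) {
  n <- nrow(mat)
  pairs <- utils::combn(n, 2)
  if (deletion == "complete") {
    ok <- .clean_cols(mat)
    S <- sum(ok)
    if (S == 0) return(structure(NA_real_, n_sites = 0L))
    sub <- mat[, ok, drop = FALSE]
    d <- mean(apply(pairs, 2, function(p)
      sum(sub[p[1], ] != sub[p[2], ]) / S))
    structure(d, n_sites = S)
  } else {
    vals <- apply(pairs, 2, function(p) {
      ok <- mat[p[1], ] %in% c("A", "C", "G", "T") &
        mat[p[2], ] %in% c("A", "C", "G", "T")
      if (!any(ok)) return(NA_real_)
      sum(mat[p[1], ok] != mat[p[2], ok]) / sum(ok)
    })
    structure(mean(vals, na.rm = TRUE), n_sites = NA_integer_)
  }
}

#' Average pairwise nucleotide diversity of an alignment
#'
#' Pi = mean over all n(n-1)/2 sequence pairs of the per-site difference
#' proportion. Under the default complete deletion, any site with a gap or
#' N in any sequence is excluded from numerator and denominator for every
#' pair.
#'
#' @param aln a [mito_alignment()].
#' @param deletion `"complete"` (default, DnaSP-style) or `"pairwise"`.
#' @return numeric Pi in `[0, 1]` with attribute `n_sites` (analyzed
#'   sites); `NA` (flagged by `n_sites = 0`) when no site is analyzable.
#' @export
pairwise_pi <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  .pi_from_matrix(.aln_matrix(aln), deletion)
}

#' Sliding-window nucleotide diversity
#'
#' Windows `[k*step, k*step + window)` fully contained in the alignment
#' (trailing partial windows are dropped); per-window Pi is [pairwise_pi()]
#' restricted to the window's columns. Coordinates are alignment
#' coordinates, 0-based half-open; `midpoint` is reported for plotting.
#'
#' @param aln a [mito_alignment()].
#' @param window window width in bp (default 100).
#' @param step step size in bp (default 25).
#' @param deletion see [pairwise_pi()].
#' @return object of class `pi_track`: `gene`, `pi_total`, `n_sites`,
#'   `n_seqs`, `window`, `step` and a `windows` data.frame
#'   `start end midpoint pi n_sites`.
#' @export
sliding_window_pi <- function(aln, window = 100L, step = 25L,
                              deletion = "complete") {
  stopifnot(window >= step, step >= 1)
  mat <- .aln_matrix(aln)
  L <- ncol(mat)
  total <- .pi_from_matrix(mat, deletion)
  if (L < window) {
    warning("alignment '", aln$gene, "' (", L,
            " bp) shorter than window; per-gene Pi only", call. = FALSE)
    wins <- data.frame(start = integer(), end = integer(),
                       midpoint = numeric(), pi = numeric(),
                       n_sites = integer())
  } else {
    starts <- seq.int(0L, L - window, by = step)
    wins <- do.call(rbind, lapply(starts, function(s) {
      w <- .pi_from_matrix(mat[, (s + 1):(s + window), drop = FALSE],
                           deletion)
      data.frame(start = s, end = s + window,
                 midpoint = s + window / 2, pi = as.numeric(w),
                 n_sites = attr(w, "n_sites"))
    }))
  }
  structure(list(gene = aln$gene, pi_total = as.numeric(total),
                 n_sites = attr(total, "n_sites"), n_seqs = nrow(mat),
                 window = window, step = step, windows = wins),
            class = "pi_track")
}

#' Per-gene Pi over a set of gene alignments
#'
#' Runs [sliding_window_pi()] per gene and assembles a ranked per-gene
#' table plus a concatenated window track laid out in canonical gene order
#' for plotting. Ranking is by decreasing Pi with ties broken by canonical
#' gene order.
#'
#' @param alignments list of [mito_alignment()] objects (one per gene).
#' @param window,step,deletion passed to [sliding_window_pi()].
#' @return list with `per_gene` (data.frame
#'   `gene pi n_sites n_seqs rank`), `tracks` (named list of `pi_track`)
#'   and `concatenated` (window table with a cumulative `offset` column).
#' @export
multi_gene_pi <- function(alignments, window = 100L, step = 25L,
                          deletion = "complete") {
  tracks <- lapply(alignments, sliding_window_pi, window = window,
                   step = step, deletion = deletion)
  names(tracks) <- vapply(tracks, `[[`, character(1), "gene")
  canon <- canonical_gene_order()
  ord_key <- match(names(tracks), canon)
  ord_key[is.na(ord_key)] <- length(canon) + seq_len(sum(is.na(ord_key)))
  per_gene <- data.frame(
    gene = names(tracks),
    pi = vapply(tracks, `[[`, numeric(1), "pi_total"),
    n_sites = vapply(tracks, function(t) as.integer(t$n_sites), integer(1)),
    n_seqs = vapply(tracks, `[[`, integer(1), "n_seqs"),
    stringsAsFactors = FALSE)
  o <- order(-per_gene$pi, ord_key)
  per_gene$rank <- NA_integer_
  per_gene$rank[o] <- seq_len(nrow(per_gene))
  # concatenated track in canonical order for plotting
  lay <- order(ord_key)
  offset <- 0L
  concat <- list()
  for (i in lay) {
    t <- tracks[[i]]
    w <- t$windows
    if (nrow(w)) {
      w$gene <- t$gene
      w$offset <- w$start + offset
      concat[[length(concat) + 1]] <- w
    }
    offset <- offset + nchar(alignments[[i]]$seqs[1])
  }
  concat <- if (length(concat)) do.call(rbind, concat) else
    data.frame(start = integer(), end = integer(), midpoint = numeric(),
               pi = numeric(), n_sites = integer(), gene = character(),
               offset = integer())
  list(per_gene = per_gene[order(per_gene$rank), , drop = FALSE],
       tracks = tracks, concatenated = concat)
}
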