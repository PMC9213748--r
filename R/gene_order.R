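# Circular signed gene orders and breakpoint distances. An order is the
# circular sequence of gene labels with strand signs; two orders are
# compared by their sets of signed, directed circular adjacencies after
# restriction to the shared gene set. Rotation is a no-op; reflection
# (reading the molecule from the other strand) is NOT normalized away,
# matching how mitogenome gene-order maps display strand explicitly.

#' Extract the circular gene order of a genome
#'
#' Features sorted by start coordinate; light-strand genes carry sign -1
#' (rendered with a minus prefix).
#'
#' @param genome a [mito_genome()] object.
#' @return object of class `gene_order`: `id`, `genes` (labels), `strands`
#'   (+1/-1).
#' @export
extract_gene_order <- function(genome) {
  f <- genome$features
  if (!nrow(f)) stop("genome has no features", call. = FALSE)
  dup <- unique(f$name[duplicated(f$name)])
  if (length(dup))
    stop("duplicate gene labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  f <- f[order(f$start), , drop = FALSE]
  gene_order(genome$id, f$name, f$strand)
}

#' Construct a gene order
#' @param id genome id.
#' @param genes character vector of unique gene labels in circular order.
#' @param strands +1/-1 per gene (default all +1).
#' @return object of class `gene_order`.
#' @export
gene_order <- function(id, genes, strands = rep(1L, length(genes))) {
  stopifnot(length(genes) >= 1, length(strands) == length(genes),
            all(strands %in% c(1L, -1L)), !anyDuplicated(genes))
  structure(list(id = id, genes = genes, strands = as.integer(strands)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("gene_order '%s': %s\n", x$id,
              paste(signed_labels(x), collapse = " ")))
  invisible(x)
}

#' Signed gene labels of an order
#' @param ord a [gene_order()].
#' @return character vector, minus-prefixed for strand -1.
#' @export
signed_labels <- function(ord) {
  paste0(ifelse(ord$strands == -1L, "-", ""), ord$genes)
}

.restrict_order <- function(ord, keep) {
  i <- which(ord$genes %in% keep)
  gene_order(ord$id, ord$genes[i], ord$strands[i])
}

.adjacency_set <- function(ord) {
  n <- length(ord$genes)
  lab <- signed_labels(ord)
  if (n == 1) return(character())
  nxt <- c(seq(2, n), 1)
  paste(lab, lab[nxt], sep = ">")
}

#' Breakpoint distance between two circular signed gene orders
#'
#' Both orders are restricted to their shared gene set, then the number of
#' signed directed circular adjacencies present in `a` but not in `b` is
#' counted. The distance is 0 iff the restricted orders are identical as
#' signed circular sequences up to rotation; it is symmetric and
#' rotation-invariant.
#'
#' @param a,b [gene_order()] objects.
#' @return object of class `breakpoint_result`: `id_a`, `id_b`,
#'   `shared_genes`, `breakpoints`, `identical`.
#' @export
breakpoint_distance <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  if (length(shared) < 2)
    stop("shared gene set has fewer than 2 genes", call. = FALSE)
  ra <- .restrict_order(a, shared)
  rb <- .restrict_order(b, shared)
  bp <- length(setdiff(.adjacency_set(ra), .adjacency_set(rb)))
  structure(list(id_a = a$id, id_b = b$id,
                 shared_genes = length(shared), breakpoints = bp,
                 identical = bp == 0L),
            class = "breakpoint_result")
}

#' Pairwise breakpoint table for a set of orders
#' @param orders list of [gene_order()] objects.
#' @return data.frame `genome_a genome_b shared_genes breakpoints
#'   identical`.
#' @export
breakpoint_table <- function(orders) {
  n <- length(orders)
  rows <- list()
  for (i in seq_len(max(n - 1, 0)))
    for (j in seq(i + 1, n)) {
      r <- breakpoint_distance(orders[[i]], orders[[j]])
      rows[[length(rows) + 1]] <- data.frame(
        genome_a = r$id_a, genome_b = r$id_b,
        shared_genes = r$shared_genes, breakpoints = r$breakpoints,
        identical = r$identical, stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(genome_a = character(), genome_b = character(),
                      shared_genes = integer(), breakpoints = integer(),
                      identical = logical()))
  do.call(rbind, rows)
}

#' Linear gene-order map for rendering
#'
#' Rotates every order to start at an anchor gene (default ND5, the
#' conventional first gene of the actiniarian order) and lays the signed
#' labels out as one row per genome.
#'
#' @param orders list of [gene_order()] objects.
#' @param anchor anchor gene label; orders lacking it fall back to their
#'   first gene with a warning.
#' @return data.frame, first column `genome`, then `pos1`, `pos2`, ...
#'   (NA-padded for shorter orders).
#' @export
order_map <- function(orders, anchor = "ND5") {
  width <- max(vapply(orders, function(o) length(o$genes), integer(1)))
  rows <- lapply(orders, function(o) {
    i <- match(anchor, o$genes)
    if (is.na(i)) {
      warning("anchor '", anchor, "' absent from '", o$id,
              "'; using first gene", call. = FALSE)
      i <- 1L
    }
    lab <- signed_labels(o)
    n <- length(lab)
    rot <- lab[((seq_len(n) + i - 2L) %% n) + 1L]
    c(o$id, rot, rep(NA_character_, width - n))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("genome", paste0("pos", seq_len(width)))
  out
}
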