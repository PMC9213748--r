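# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's own algorithms: the motif oracle checks
# substrings directly, the Pi oracle recounts differences per pair, the
# NG86 oracle enumerates change orderings recursively, and the breakpoint
# oracle scans the doubled signed-label vector for 2-grams.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_genome <- function(seq, feats = NULL, id = "toy", circular = TRUE) {
  if (is.null(feats)) feats <- empty_features()
  mito_genome(id, seq, feats, circular = circular)
}

feat_row <- function(name, start, end, strand = 1L, kind = "CDS") {
  data.frame(name = name, kind = kind, start = start, end = end,
             strand = strand, frame_warning = FALSE,
             stringsAsFactors = FALSE)
}

# motif: leftmost non-overlapping maximal G A^{>=min_run} T matches
bf_motif_scan <- function(seq, min_run) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- data.frame(start = integer(), run_length = integer())
  i <- 1
  while (i <= n) {
    if (chars[i] == "G") {
      j <- i + 1
      while (j <= n && chars[j] == "A") j <- j + 1
      run <- j - i - 1
      if (run >= min_run && j <= n && chars[j] == "T") {
        hits <- rbind(hits, data.frame(start = i - 1L, run_length = run))
        i <- j + 1
        next
      }
    }
    i <- i + 1
  }
  hits
}

# Pi: direct recount, complete deletion
bf_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(ok)) return(NA_real_)
  mat <- mat[, ok, drop = FALSE]
  n <- nrow(mat)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(mat[i, ] != mat[j, ]) / ncol(mat)
    np <- np + 1
  }
  tot / np
}

bf_window_pi <- function(seqs, window, step) {
  L <- nchar(seqs[1])
  starts <- seq(0, L - window, by = step)
  vapply(starts, function(s)
    bf_pi(substr(seqs, s + 1, s + window)), numeric(1))
}

# NG86 differences: recursive enumeration of orderings
bf_ng_diff <- function(c1, c2, map) {
  walk <- function(cur, target) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(diffs)) return(list(c(0, 0)))
    out <- list()
    for (pos in diffs) {
      b <- strsplit(cur, "")[[1]]
      b[pos] <- strsplit(target, "")[[1]][pos]
      nxt <- paste(b, collapse = "")
      if (map[nxt] == "*") next
      step <- if (map[cur] == map[nxt]) c(1, 0) else c(0, 1)
      for (tail in walk(nxt, target))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  paths <- walk(c1, c2)
  if (!length(paths)) return(NULL)   # no stop-free ordering
  Reduce(`+`, paths) / length(paths)
}

# breakpoints: count adjacencies of a absent from b by 2-gram scan of
# b's doubled signed-label sequence
bf_breakpoints <- function(genes_a, strands_a, genes_b, strands_b) {
  lab <- function(g, s) paste0(ifelse(s == -1L, "-", ""), g)
  la <- lab(genes_a, strands_a)
  lb <- lab(genes_b, strands_b)
  doubled <- c(lb, lb)
  grams_b <- vapply(seq_along(lb), function(i)
    paste(doubled[i], doubled[i + 1], sep = "\r"), character(1))
  na <- length(la)
  nxt <- c(seq(2, na), 1)
  grams_a <- paste(la, la[nxt], sep = "\r")
  sum(!grams_a %in% grams_b)
}
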