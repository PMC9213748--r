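# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
#
# Site counting: each of a codon's three positions contributes the
# fraction of its single-nucleotide changes that are synonymous, with
# changes creating a stop codon excluded from the possible-change set;
# S + N == 3 x codons by construction. Difference counting: for a codon
# pair differing at d positions, the d! orderings of the changes are
# enumerated, orderings passing through a stop codon are discarded, and
# synonymous/nonsynonymous step counts are averaged over the remaining
# orderings with equal weight. Distances use the Jukes-Cantor correction
# d = -(3/4) ln(1 - (4/3) p); p >= 3/4 yields a flagged undefined
# distance, never a clamped number.
#
# This pairwise counting estimator is NOT a likelihood branch model; all
# outputs are labelled "NG86-pairwise".

.ng_cache <- new.env(parent = emptyenv())

.ng_pathways <- function(c1, c2, map) {
  # average (syn, nonsyn) step counts over valid orderings c1 -> c2
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffs <- which(b1 != b2)
  d <- length(diffs)
  if (d == 0) return(c(0, 0, 0))       # syn, nonsyn, fallback flag
  perms <- if (d == 1) list(diffs) else {
    if (d == 2) list(diffs, rev(diffs)) else {
      out <- list()
      for (i in 1:3) for (j in 1:3) if (i != j)
        out[[length(out) + 1]] <- diffs[c(i, j, 6 - i - j)]
      out
    }
  }
  acc <- c(0, 0); valid <- 0L
  for (p in perms) {
    cur <- b1; s <- 0; n <- 0; ok <- TRUE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- b2[pos]
      a_cur <- map[paste(cur, collapse = "")]
      a_nxt <- map[paste(nxt, collapse = "")]
      if (a_nxt == "*") { ok <- FALSE; break }
      if (a_cur == a_nxt) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(s, n); valid <- valid + 1L }
  }
  if (valid > 0) return(c(acc / valid, 0))
  # no stop-free ordering: classify each differing position directly
  s <- 0; n <- 0
  for (pos in diffs) {
    alt <- b1; alt[pos] <- b2[pos]
    if (map[c1] == map[paste(alt, collapse = "")]) s <- s + 1 else n <- n + 1
  }
  c(s, n, 1)
}

#' NG86 lookup tables for a genetic code
#'
#' Precomputes, once per translation table, the per-codon synonymous site
#' counts and the 64x64 pathway-averaged synonymous/nonsynonymous
#' difference counts. Stop codons get NA entries.
#'
#' @param code a [genetic_code()].
#' @return list `syn_sites` (named numeric 64), `Sd`, `Nd` (64x64
#'   matrices), `fallback` (64x64 logical: no stop-free ordering existed,
#'   direct per-position classification used).
#' @export
ng86_tables <- function(code = genetic_code()) {
  key <- as.character(code$table_id)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  map <- code$map
  codons <- names(map)
  bases <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(rep(NA_real_, 64), codons)
  for (cd in codons) {
    if (map[cd] == "*") next
    b <- strsplit(cd, "")[[1]]
    S <- 0
    for (pos in 1:3) {
      s <- 0; n <- 0
      for (alt in setdiff(bases, b[pos])) {
        nb <- b; nb[pos] <- alt
        aa <- map[paste(nb, collapse = "")]
        if (aa == "*") next                 # excluded from possible changes
        if (aa == map[cd]) s <- s + 1 else n <- n + 1
      }
      S <- S + if (s + n > 0) s / (s + n) else 0
    }
    syn_sites[cd] <- S
  }
  Sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  Nd <- Sd
  fb <- matrix(FALSE, 64, 64, dimnames = list(codons, codons))
  for (i in seq_along(codons)) for (j in seq_along(codons)) {
    if (map[i] == "*" || map[j] == "*") next
    r <- .ng_pathways(codons[i], codons[j], map)
    Sd[i, j] <- r[1]; Nd[i, j] <- r[2]; fb[i, j] <- r[3] > 0
  }
  tabs <- list(syn_sites = syn_sites, Sd = Sd, Nd = Nd, fallback = fb)
  .ng_cache[[key]] <- tabs
  tabs
}

.prep_codons <- function(cds, code, label = "sequence") {
  cods <- if (length(cds) > 1 || nchar(cds[1]) == 3) as.character(cds)
  else split_codons(cds)
  k <- length(cods)
  if (k && code$map[cods[k]] %in% "*") cods <- cods[-k]  # terminal stop
  cods
}

.check_internal_stops <- function(cods, code, label) {
  clean <- !grepl("N", cods, fixed = TRUE)
  st <- which(clean & code$map[cods] == "*")
  if (length(st))
    stop("internal stop codon in ", label, " at codon index ",
         st[1], " (", cods[st[1]], ")", call. = FALSE)
  invisible(cods)
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' @param cds a CDS nucleotide string (length divisible by 3) or a codon
#'   vector. A terminal stop codon is dropped; any other stop is an error.
#'   Codons containing N are skipped.
#' @param code a [genetic_code()].
#' @return named numeric `c(S =, N =)` with attribute `codons_counted`;
#'   `S + N == 3 * codons_counted`.
#' @export
ng_site_counts <- function(cds, code = genetic_code()) {
  tabs <- ng86_tables(code)
  cods <- .prep_codons(cds, code)
  .check_internal_stops(cods, code, "cds")
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  S <- sum(tabs$syn_sites[cods])
  structure(c(S = S, N = 3 * length(cods) - S),
            codons_counted = length(cods))
}

#' NG86 pathway-averaged difference counts for a sequence pair
#'
#' @param a,b equal-length CDS strings or codon vectors (terminal stops
#'   dropped; internal stops are an error; codon pairs with N skipped).
#' @param code a [genetic_code()].
#' @return named numeric `c(Sd =, Nd =)` with attributes
#'   `codons_compared` and `n_fallback` (codon pairs where every ordering
#'   passed through a stop and direct per-position classification was
#'   used; a warning is emitted when > 0).
#' @export
ng_difference_counts <- function(a, b, code = genetic_code()) {
  tabs <- ng86_tables(code)
  ca <- .prep_codons(a, code); cb <- .prep_codons(b, code)
  if (length(ca) != length(cb))
    stop("sequences differ in codon count (", length(ca), " vs ",
         length(cb), ")", call. = FALSE)
  .check_internal_stops(ca, code, "sequence a")
  .check_internal_stops(cb, code, "sequence b")
  keep <- !grepl("N", ca, fixed = TRUE) & !grepl("N", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  idx <- cbind(match(ca, rownames(tabs$Sd)), match(cb, colnames(tabs$Sd)))
  n_fb <- sum(tabs$fallback[idx])
  if (n_fb > 0)
    warning(n_fb, " codon pair(s) had no stop-free pathway; ",
            "direct per-position classification used", call. = FALSE)
  structure(c(Sd = sum(tabs$Sd[idx]), Nd = sum(tabs$Nd[idx])),
            codons_compared = length(ca), n_fallback = n_fb)
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise NG86 dN/dS
#'
#' Site counts are averaged over the two sequences; proportions pS = Sd/S
#' and pN = Nd/N are Jukes-Cantor corrected to dS and dN; omega = dN/dS.
#'
#' @param a,b equal-length CDS strings or codon vectors.
#' @param code a [genetic_code()].
#' @param id_a,id_b sequence identifiers carried into the result.
#' @return object of class `pairwise_omega`: `S N Sd Nd pS pN dS dN omega`
#'   plus `flag` (`""`, `"identical"`, `"saturated"`, `"dS_zero"`) and
#'   `method = "NG86-pairwise"`.
#' @export
pairwise_omega <- function(a, b, code = genetic_code(),
                           id_a = "a", id_b = "b") {
  sa <- ng_site_counts(a, code)
  sb <- ng_site_counts(b, code)
  d <- ng_difference_counts(a, b, code)
  S <- (sa["S"] + sb["S"]) / 2
  N <- (sa["N"] + sb["N"]) / 2
  pS <- if (S > 0) unname(d["Sd"] / S) else NA_real_
  pN <- if (N > 0) unname(d["Nd"] / N) else NA_real_
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  flag <- ""
  omega <- NA_real_
  if (!is.na(pS) && !is.na(pN) && pS == 0 && pN == 0) {
    dS <- 0; dN <- 0; flag <- "identical"
  } else if (is.na(dS) || is.na(dN)) {
    flag <- "saturated"
  } else if (dS == 0) {
    flag <- "dS_zero"
  } else {
    omega <- dN / dS
  }
  structure(list(id_a = id_a, id_b = id_b,
                 S = unname(S), N = unname(N),
                 Sd = unname(d["Sd"]), Nd = unname(d["Nd"]),
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 codons_compared = attr(d, "codons_compared"),
                 flag = flag, method = "NG86-pairwise"),
            class = "pairwise_omega")
}

#' @export
print.pairwise_omega <- function(x, ...) {
  cat(sprintf(
    "NG86-pairwise %s vs %s: dN = %.5f, dS = %.5f, omega = %s%s\n",
    x$id_a, x$id_b, x$dN, x$dS,
    if (is.na(x$omega)) "undefined" else sprintf("%.5f", x$omega),
    if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Tidy table of pairwise omegas
#' @param omegas list of [pairwise_omega()] results.
#' @return data.frame `id_a id_b S N Sd Nd pS pN dS dN omega flag method`.
#' @export
omega_table <- function(omegas) {
  do.call(rbind, lapply(omegas, function(x)
    data.frame(id_a = x$id_a, id_b = x$id_b, S = x$S, N = x$N,
               Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
               dS = x$dS, dN = x$dN, omega = x$omega, flag = x$flag,
               method = x$method, stringsAsFactors = FALSE)))
}

#' Deep-vs-shallow group omega contrast
#'
#' A pairwise-mean stand-in for a branch-model foreground/background
#' contrast: the foreground omega is the mean pairwise NG86 omega among
#' deep-group genomes (or of deep-vs-shallow pairs when only one deep
#' genome is supplied, and labelled as such), the background omega the
#' mean among shallow-only pairs, and the fold ratio is
#' background/foreground.
#'
#' @param cds_set named list of equal-length coding sequences (typically
#'   the concatenated 13-PCG alignment rows), one per genome.
#' @param grouping named character vector id -> `"deep"`/`"shallow"`.
#' @param code a [genetic_code()].
#' @return object of class `group_omega_contrast`: `omega_foreground`,
#'   `omega_background`, `fold_ratio`, `foreground_kind`
#'   (`"deep_pairs"` or `"deep_vs_shallow_pairs"`), `n_dropped`
#'   (undefined pairwise omegas), `pairs` (full [omega_table()]),
#'   `method`.
#' @export
group_omega_contrast <- function(cds_set, grouping,
                                 code = genetic_code()) {
  ids <- names(cds_set)
  grp <- grouping[ids]
  if (any(is.na(grp)))
    stop("no depth group for: ", paste(ids[is.na(grp)], collapse = ", "),
         call. = FALSE)
  deep <- ids[grp == "deep"]; shal <- ids[grp == "shallow"]
  if (length(deep) < 1 || length(shal) < 2)
    stop("need >= 1 deep and >= 2 shallow genomes", call. = FALSE)
  pairs <- utils::combn(ids, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k)
    pairwise_omega(cds_set[[pairs[1, k]]], cds_set[[pairs[2, k]]], code,
                   id_a = pairs[1, k], id_b = pairs[2, k]))
  tab <- omega_table(res)
  kind_of <- function(r) paste(sort(grp[c(r[["id_a"]], r[["id_b"]])]),
                               collapse = "-")
  tab$pair_kind <- apply(tab, 1, kind_of)
  n_drop <- sum(is.na(tab$omega))
  if (n_drop)
    warning(n_drop, " pair(s) with undefined omega dropped from means",
            call. = FALSE)
  fg_kind <- if (length(deep) >= 2) "deep_pairs" else
    "deep_vs_shallow_pairs"
  fg_rows <- if (fg_kind == "deep_pairs") tab$pair_kind == "deep-deep"
  else tab$pair_kind == "deep-shallow"
  bg_rows <- tab$pair_kind == "shallow-shallow"
  fg <- mean(tab$omega[fg_rows], na.rm = TRUE)
  bg <- mean(tab$omega[bg_rows], na.rm = TRUE)
  structure(list(omega_foreground = fg, omega_background = bg,
                 fold_ratio = if (is.finite(fg) && fg > 0) bg / fg
                 else NA_real_,
                 foreground_kind = fg_kind, n_dropped = n_drop,
                 pairs = tab, method = "NG86-pairwise"),
            class = "group_omega_contrast")
}

#' @export
print.group_omega_contrast <- function(x, ...) {
  cat(sprintf(
    paste0("NG86-pairwise group contrast (%s foreground):\n",
           "  omega foreground = %.5f\n  omega background = %.5f\n",
           "  fold ratio (background/foreground) = %.3f\n"),
    x$foreground_kind, x$omega_foreground, x$omega_background,
    x$fold_ratio))
  invisible(x)
}
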