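# Internal coordinate contract: 0-based half-open [start, end); `end` may
# exceed the genome length to represent a feature wrapping the origin of a
# circular molecule. All file formats use 1-based inclusive coordinates.

#' Canonical actiniarian mitochondrial gene order
#'
#' The 17-gene order shared by most sea anemone (Actiniaria) mitogenomes:
#' 13 energy-pathway protein-coding genes, two tRNAs (trnW, trnM) and the
#' two rRNAs, all on the heavy strand.
#'
#' @param pcg_only logical; return only the 13 protein-coding genes.
#' @return character vector of canonical gene labels in circular order.
#' @export
canonical_gene_order <- function(pcg_only = FALSE) {
  ord <- c("ND5", "ND1", "ND3", "trnW", "ND2", "s-rRNA", "cox2", "ND4",
           "ND6", "cob", "trnM", "l-rRNA", "cox3", "cox1", "ND4L",
           "atp8", "atp6")
  if (pcg_only) ord[!ord %in% c("trnW", "trnM", "s-rRNA", "l-rRNA")] else ord
}

#' The 13 canonical mitochondrial protein-coding gene labels
#' @return character vector in canonical circular order.
#' @export
canonical_pcgs <- function() canonical_gene_order(pcg_only = TRUE)

.synonym_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "gene_synonyms.tsv",
                          package = "mitocompare", mustWork = TRUE)
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$canonical, tolower(tab$alias))
    }
    cache
  }
})

#' Normalize gene names to canonical labels
#'
#' Maps the common aliases found in GenBank records (COI, rrnS, NAD4L, ...)
#' onto the canonical labels used throughout the package. Unknown names pass
#' through unchanged.
#'
#' @param x character vector of gene names.
#' @return character vector of canonical labels.
#' @export
normalize_gene_name <- function(x) {
  map <- .synonym_map()
  hit <- map[tolower(x)]
  unname(ifelse(is.na(hit), x, hit))
}

.check_alphabet <- function(seq, what = "sequence") {
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, " contains characters outside A/C/G/T/N: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  invisible(seq)
}

#' Construct an annotated mitochondrial genome
#'
#' @param id genome identifier.
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param features data.frame with columns `name`, `kind` (CDS/rRNA/tRNA/
#'   other), `start` (0-based inclusive), `end` (0-based exclusive; may
#'   exceed the genome length for origin-wrapping features on a circular
#'   molecule) and `strand` (+1/-1).
#' @param circular logical; is the molecule circular.
#' @param depth_class one of `"deep"`, `"shallow"`, `"unknown"` — habitat
#'   depth group used by the comparative analyses (deep = hadal/abyssal).
#' @return object of class `MitoGenome`.
#' @export
mito_genome <- function(id, sequence, features = empty_features(),
                        circular = TRUE, depth_class = "unknown") {
  sequence <- toupper(sequence)
  .check_alphabet(sequence, paste0("genome '", id, "' sequence"))
  stopifnot(nchar(sequence) > 0L)
  depth_class <- match.arg(depth_class, c("deep", "shallow", "unknown"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  L <- nchar(sequence)
  if (nrow(features)) {
    needed <- c("name", "kind", "start", "end", "strand")
    stopifnot(all(needed %in% names(features)))
    if (!"frame_warning" %in% names(features))
      features$frame_warning <- FALSE
    stopifnot(all(features$end > features$start),
              all(features$end - features$start <= L),
              all(features$start >= 0), all(features$start < L),
              all(features$strand %in% c(1L, -1L)))
    if (any(features$end > L) && !circular)
      stop("origin-wrapping feature on a non-circular genome", call. = FALSE)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
    bad <- features$kind == "CDS" & (features$end - features$start) %% 3L != 0L
    if (any(bad)) {
      warning("CDS length not divisible by 3 for: ",
              paste(features$name[bad], collapse = ", "), call. = FALSE)
      features$frame_warning[bad] <- TRUE
    }
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features, depth_class = depth_class),
            class = "MitoGenome")
}

#' Empty feature table
#' @return zero-row feature data.frame with the canonical columns.
#' @export
empty_features <- function() {
  data.frame(name = character(), kind = character(),
             start = integer(), end = integer(), strand = integer(),
             frame_warning = logical(), stringsAsFactors = FALSE)
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome '%s': %s bp, %s, %d features, depth class %s\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), x$depth_class))
  if (nrow(x$features))
    print(utils::head(x$features, 20))
  invisible(x)
}

# --- GenBank flat file ------------------------------------------------------

.parse_gb_location <- function(loc, L, line_no) {
  loc <- gsub("[<>]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    spans <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
      if (length(m) != 3)
        stop("malformed GenBank location at line ", line_no, ": ", p,
             call. = FALSE)
      as.integer(m[2:3])
    })
    # join across the origin: last segment ends at L, next starts at 1
    if (length(spans) == 2 && spans[[1]][2] == L && spans[[2]][1] == 1)
      return(list(start = spans[[1]][1] - 1L,
                  end = L + spans[[2]][2], strand = strand))
    stop("unsupported join() location at line ", line_no, ": ", loc,
         call. = FALSE)
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3)
    return(list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]),
                strand = strand))
  if (grepl("^\\d+$", loc))
    return(list(start = as.integer(loc) - 1L, end = as.integer(loc),
                strand = strand))
  stop("malformed GenBank location at line ", line_no, ": ", loc,
       call. = FALSE)
}

#' Read a GenBank flat file
#'
#' Minimal parser for annotated mitogenome records: LOCUS (length,
#' circular/linear), the FEATURES table (CDS, rRNA, tRNA; gene names taken
#' from `/gene=` or `/product=` and normalized via [normalize_gene_name()]),
#' and the ORIGIN sequence block. GenBank 1-based inclusive locations are
#' converted to 0-based half-open; `complement(...)` gives strand -1;
#' two-segment `join(...)` across the record origin becomes a wrapping span.
#'
#' @param path path to a GenBank flat file.
#' @param depth_class depth group to attach (see [mito_genome()]).
#' @return a [mito_genome()] object.
#' @export
read_genbank <- function(path, depth_class = "unknown") {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("no LOCUS line in ", path, call. = FALSE)
  locus <- lines[locus_i[1]]
  L <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus))
  circular <- grepl("circular", locus, ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus)), "\\s+")[[1]][1]

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i)) stop("no ORIGIN block in ", path, call. = FALSE)

  # sequence
  seq_lines <- lines[(origin_i[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  .check_alphabet(seq, paste0("record '", id, "' sequence"))
  if (!is.na(L) && nchar(seq) != L)
    stop("ORIGIN sequence length ", nchar(seq),
         " != LOCUS length ", L, " in ", path, call. = FALSE)
  L <- nchar(seq)

  feats <- empty_features()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1):(origin_i[1] - 1)]
    # feature headers start at column 6; qualifiers at column 22
    hdr <- grepl("^ {5}\\S", block)
    idx <- which(hdr)
    for (k in seq_along(idx)) {
      i0 <- idx[k]
      i1 <- if (k < length(idx)) idx[k + 1] - 1 else length(block)
      fields <- strsplit(trimws(block[i0]), "\\s+")[[1]]
      key <- fields[1]
      if (!key %in% c("CDS", "rRNA", "tRNA", "D-loop", "misc_feature"))
        next
      loc <- .parse_gb_location(fields[2], L, feat_i[1] + i0)
      quals <- paste(trimws(block[seq(i0, i1)][-1]), collapse = " ")
      name <- NA_character_
      for (q in c("gene", "product")) {
        m <- regmatches(quals,
                        regexec(sprintf('/%s="([^"]+)"', q), quals))[[1]]
        if (length(m) == 2) { name <- m[2]; break }
      }
      if (is.na(name)) name <- key
      kind <- if (key %in% c("CDS", "rRNA", "tRNA")) key else "other"
      name <- normalize_gene_name(name)
      feats <- rbind(feats, data.frame(
        name = name, kind = kind, start = loc$start, end = loc$end,
        strand = loc$strand, frame_warning = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  feats$kind[!feats$kind %in% c("CDS", "rRNA", "tRNA")] <- "other"
  mito_genome(id, seq, feats, circular = circular,
              depth_class = depth_class)
}

# --- FASTA + feature table --------------------------------------------------

#' Read a genome from FASTA plus a feature table
#'
#' The feature table is a TSV with columns `name kind start end strand`
#' using 1-based inclusive coordinates and strand `+`/`-` (or +1/-1). A row
#' with `end < start` on a circular genome denotes an origin-wrapping
#' feature.
#'
#' @param fasta path to a single-record FASTA file.
#' @param table path to the feature TSV (may have zero rows).
#' @param circular logical.
#' @param depth_class depth group to attach.
#' @return a [mito_genome()] object.
#' @export
read_feature_table <- function(fasta, table, circular = TRUE,
                               depth_class = "unknown") {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1)
    stop("expected exactly one FASTA record in ", fasta, call. = FALSE)
  seq <- as.character(ss[[1]])
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  L <- nchar(seq)
  tab <- utils::read.delim(table, stringsAsFactors = FALSE,
                           colClasses = c(start = "integer",
                                          end = "integer"))
  if (!nrow(tab))
    return(mito_genome(id, seq, empty_features(), circular, depth_class))
  strand <- ifelse(tab$strand %in% c("-", "-1"), -1L, 1L)
  start0 <- tab$start - 1L
  end0 <- tab$end
  wrap <- end0 <= start0
  if (any(wrap)) {
    if (!circular)
      stop("end < start on a linear genome for: ",
           paste(tab$name[wrap], collapse = ", "), call. = FALSE)
    end0[wrap] <- end0[wrap] + L
  }
  feats <- data.frame(name = normalize_gene_name(tab$name), kind = tab$kind,
                      start = start0, end = end0, strand = strand,
                      frame_warning = FALSE, stringsAsFactors = FALSE)
  g <- mito_genome(id, seq, feats, circular, depth_class)
  ov <- .overlap_pairs(g)
  if (nrow(ov))
    warning("overlapping features in '", id, "': ",
            paste(ov$a, ov$b, sep = "/", collapse = ", "), call. = FALSE)
  g
}

.feature_positions <- function(feature, L) {
  # 0-based positions on the circle covered by a (possibly wrapping) span
  (seq.int(feature$start, feature$end - 1L)) %% L
}

.overlap_pairs <- function(genome) {
  f <- genome$features
  L <- nchar(genome$sequence)
  out <- data.frame(a = character(), b = character())
  if (nrow(f) < 2) return(out)
  cov <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) cov[[i]] <- .feature_positions(f[i, ], L)
  for (i in seq_len(nrow(f) - 1))
    for (j in seq(i + 1, nrow(f)))
      if (length(intersect(cov[[i]], cov[[j]])))
        out <- rbind(out, data.frame(a = f$name[i], b = f$name[j]))
  out
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a feature's sequence from a genome
#'
#' Returns the coding-strand sequence: strand -1 features are
#' reverse-complemented; origin-wrapping spans concatenate the tail and head
#' of the circle.
#'
#' @param genome a [mito_genome()] object.
#' @param feature a feature name, a row index, or a one-row feature
#'   data.frame.
#' @return nucleotide string of length `end - start`.
#' @export
extract_feature_sequence <- function(genome, feature) {
  f <- genome$features
  if (is.character(feature)) {
    i <- which(f$name == feature)
    if (length(i) != 1)
      stop("feature '", feature, "' matches ", length(i), " rows",
           call. = FALSE)
    feature <- f[i, ]
  } else if (is.numeric(feature)) {
    feature <- f[feature, ]
  }
  L <- nchar(genome$sequence)
  if (feature$end > L && !genome$circular)
    stop("wrapping span on a non-circular genome", call. = FALSE)
  s <- if (feature$end <= L) {
    substr(genome$sequence, feature$start + 1L, feature$end)
  } else {
    paste0(substr(genome$sequence, feature$start + 1L, L),
           substr(genome$sequence, 1L, feature$end - L))
  }
  if (feature$strand == -1L) revcomp(s) else s
}

#' Concatenate canonical PCG sequences of a genome
#'
#' With `drop_terminal_stops = TRUE` each gene's final codon is removed
#' when it is a stop under `code` — the convention for building the
#' concatenated coding dataset used by the selection analysis, where
#' internal stops are not allowed.
#'
#' @param genome a [mito_genome()] object.
#' @param genes gene labels to concatenate, in order; defaults to the 13
#'   canonical PCGs in canonical order.
#' @param drop_terminal_stops strip each gene's terminal stop codon.
#' @param code a [genetic_code()] (used only to recognize stops).
#' @return single nucleotide string (missing genes are skipped with a
#'   warning).
#' @export
concat_genes <- function(genome, genes = canonical_pcgs(),
                         drop_terminal_stops = FALSE,
                         code = genetic_code()) {
  present <- genes[genes %in% genome$features$name]
  if (length(present) < length(genes))
    warning("genome '", genome$id, "' missing: ",
            paste(setdiff(genes, present), collapse = ", "), call. = FALSE)
  parts <- vapply(present, function(g) {
    s <- extract_feature_sequence(genome, g)
    if (drop_terminal_stops && nchar(s) %% 3L == 0L && nchar(s) >= 3L) {
      last <- substr(s, nchar(s) - 2L, nchar(s))
      if (!is.na(code$map[last]) && code$map[last] == "*")
        s <- substr(s, 1L, nchar(s) - 3L)
    }
    s
  }, character(1))
  paste(parts, collapse = "")
}

# --- alignments -------------------------------------------------------------

#' Construct a gene alignment
#' @param gene gene label.
#' @param seqs character vector of aligned sequences (equal length, alphabet
#'   A/C/G/T/N/-).
#' @param ids sequence identifiers.
#' @return object of class `mito_alignment`.
#' @export
mito_alignment <- function(gene, seqs, ids = names(seqs)) {
  seqs <- toupper(unname(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (length(seqs) < 2) stop("alignment needs >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length", call. = FALSE)
  bad <- gsub("[ACGTN-]", "", paste(seqs, collapse = ""))
  if (nzchar(bad))
    stop("alignment contains invalid characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  structure(list(gene = gene, ids = ids, seqs = seqs),
            class = "mito_alignment")
}

#' Read an aligned multi-FASTA as a gene alignment
#' @param path FASTA path.
#' @param gene gene label; defaults to the file name without extension.
#' @return a [mito_alignment()] object.
#' @export
read_alignment_fasta <- function(path, gene = NULL) {
  if (is.null(gene))
    gene <- sub("\\.(fa|fasta|fna)$", "", basename(path), ignore.case = TRUE)
  ss <- Biostrings::readDNAStringSet(path)
  mito_alignment(gene, as.character(ss),
                 vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1))
}

# --- report tables ----------------------------------------------------------

#' Write result tables as TSV with a JSON mirror
#'
#' @param results a data.frame or a named list of data.frames.
#' @param dir output directory (created if needed).
#' @param name base file name used when `results` is a single data.frame.
#' @param digits decimal places for numeric columns in the TSV
#'   (round-half-even via [round()]); `NULL` writes full precision.
#' @return invisibly, the paths written.
#' @export
write_report_tables <- function(results, dir, name = "results",
                                digits = NULL) {
  if (is.data.frame(results)) results <- stats::setNames(list(results), name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(results)) {
    tab <- as.data.frame(results[[nm]], stringsAsFactors = FALSE)
    if (!is.null(digits))
      for (j in seq_along(tab))
        if (is.double(tab[[j]])) tab[[j]] <- round(tab[[j]], digits)
    tsv <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsn <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(tab, jsn, dataframe = "rows", na = "null",
                         digits = NA)
    paths <- c(paths, tsv, jsn)
  }
  invisible(paths)
}
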