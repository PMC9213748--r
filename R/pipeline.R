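# Orchestration: a per-genome summary table and a full multi-stage run
# (composition -> codon usage -> diversity -> gene order -> selection)
# with deterministic TSV/JSON outputs and a run manifest. Every number in
# the written tables comes from exactly one module operation; the only
# report-side arithmetic is the documented background/foreground fold
# ratio inside the selection stage.

.rrna_stat <- function(genome, gene) {
  if (!gene %in% genome$features$name) return(c(NA_real_, NA_real_))
  s <- extract_feature_sequence(genome, gene)
  c(nchar(s), count_bases(s)$at_percent)
}

#' Per-genome summary table
#'
#' For each genome: length, feature counts by kind, rRNA lengths and AT%,
#' intergenic totals (count, bp, longest region), whole-genome skews and
#' the number of start/stop-codon anomalies among the CDS.
#'
#' @param genomes list of [mito_genome()] objects.
#' @param code a [genetic_code()].
#' @return data.frame, one row per genome.
#' @export
run_summary <- function(genomes, code = genetic_code()) {
  rows <- lapply(genomes, function(g) {
    sk <- compute_skew(g$sequence, "whole_genome")
    ign <- extract_intergenic(g)
    aud <- audit_start_stop(g, code)
    sr <- .rrna_stat(g, "s-rRNA"); lr <- .rrna_stat(g, "l-rRNA")
    data.frame(
      genome = g$id, length = nchar(g$sequence),
      n_cds = sum(g$features$kind == "CDS"),
      n_trna = sum(g$features$kind == "tRNA"),
      n_rrna = sum(g$features$kind == "rRNA"),
      srrna_length = sr[1], srrna_at_percent = sr[2],
      lrrna_length = lr[1], lrrna_at_percent = lr[2],
      ign_total = sum(ign$length), ign_count = nrow(ign),
      ign_max = if (nrow(ign)) max(ign$length) else 0L,
      at_skew = sk$at_skew, gc_skew = sk$gc_skew,
      nonstandard_start = sum(!aud$start_ok),
      nonstandard_stop = sum(!aud$stop_ok),
      depth_class = g$depth_class, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    warning("no genomes supplied; header-only summary", call. = FALSE)
    return(data.frame(genome = character(), length = integer(),
                      n_cds = integer(), n_trna = integer(),
                      n_rrna = integer())[0, ])
  }
  do.call(rbind, rows)
}

#' Run the full comparative analysis
#'
#' Stages: genome summary and composition/skew tables, intergenic and
#' motif scan, codon usage/RSCU/amino-acid profiles (with the depth-group
#' contrast when a grouping is given), sliding-window nucleotide diversity
#' (when alignments are given), gene-order breakpoints, and the NG86
#' pairwise omega contrast (when a grouping is given and >= 3 genomes
#' share the 13 PCGs). All tables are written under `out_dir` via
#' [write_report_tables()] together with a `manifest.json`.
#'
#' @param genomes list of [mito_genome()] objects.
#' @param out_dir output directory.
#' @param alignments optional named list of [mito_alignment()] objects for
#'   the diversity stage (skipped with a warning when absent).
#' @param grouping optional named vector id -> `"deep"`/`"shallow"`; when
#'   absent the group contrast stages are skipped.
#' @param code_id NCBI translation table id.
#' @param window,step sliding-window parameters (bp).
#' @param min_run minimum A-run of the G(A)nT motif scan.
#' @param seed recorded in the manifest (the analysis stages themselves
#'   are deterministic).
#' @param digits decimal places in the written TSVs.
#' @return invisibly, a named list of the result objects.
#' @export
run_all <- function(genomes, out_dir, alignments = NULL, grouping = NULL,
                    code_id = 4L, window = 100L, step = 25L,
                    min_run = 3L, seed = NA_integer_, digits = 4L) {
  stopifnot(length(genomes) >= 1)
  code <- genetic_code(code_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  results$summary <- run_summary(genomes, code)
  results$skew <- per_gene_skew_table(genomes)
  results$intergenic <- do.call(rbind, lapply(genomes, function(g) {
    ign <- extract_intergenic(g)
    if (nrow(ign)) cbind(genome = g$id, ign) else NULL
  }))
  results$motifs <- do.call(rbind, lapply(genomes, function(g) {
    hits <- find_cr_motif(g$sequence, min_run = min_run,
                          circular = g$circular)
    if (nrow(hits)) cbind(genome = g$id, hits) else NULL
  }))
  results$start_stop <- do.call(rbind, lapply(genomes, function(g) {
    aud <- audit_start_stop(g, code)
    if (nrow(aud)) cbind(genome = g$id, aud) else NULL
  }))

  profiles <- list()
  rscu_rows <- list()
  for (g in genomes) {
    pcg <- canonical_pcgs()
    present <- pcg[pcg %in% g$features$name]
    if (!length(present)) next
    cds <- lapply(present, function(x) extract_feature_sequence(g, x))
    cu <- compute_rscu(count_codons(cds, code))
    rscu_rows[[g$id]] <- cbind(genome = g$id, rscu_table(cu))
    profiles[[g$id]] <- amino_acid_profile(cu, g$id)
  }
  results$rscu <- do.call(rbind, rscu_rows)
  results$aa_profile <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome = p$genome, aa = names(p$aa_percent),
               percent = unname(p$aa_percent),
               class = unname(AA_CLASSES[names(p$aa_percent)]),
               stringsAsFactors = FALSE)))

  if (!is.null(grouping) && length(profiles) >= 3) {
    results$depth_contrast <- compare_depth_groups(profiles, grouping)
  }

  if (!is.null(alignments) && length(alignments)) {
    pi_res <- multi_gene_pi(alignments, window = window, step = step)
    results$pi_per_gene <- pi_res$per_gene
    results$pi_windows <- pi_res$concatenated
  } else {
    warning("no alignments supplied; diversity stage skipped",
            call. = FALSE)
  }

  with_feats <- Filter(function(g) nrow(g$features) > 0, genomes)
  if (length(with_feats) >= 1) {
    orders <- lapply(with_feats, extract_gene_order)
    results$gene_order_map <- order_map(orders)
    if (length(orders) >= 2)
      results$breakpoints <- breakpoint_table(orders)
  }

  if (!is.null(grouping) && length(genomes) >= 3) {
    cds_set <- lapply(genomes, concat_genes, drop_terminal_stops = TRUE,
                      code = code)
    names(cds_set) <- vapply(genomes, `[[`, character(1), "id")
    lens <- nchar(unlist(cds_set))
    if (length(unique(lens)) == 1 &&
        sum(grouping[names(cds_set)] == "deep", na.rm = TRUE) >= 1 &&
        sum(grouping[names(cds_set)] == "shallow", na.rm = TRUE) >= 2) {
      contrast <- group_omega_contrast(cds_set, grouping,
                                      code = code)
      results$omega_pairs <- contrast$pairs
      results$omega_contrast <- data.frame(
        omega_foreground = contrast$omega_foreground,
        omega_background = contrast$omega_background,
        fold_ratio = contrast$fold_ratio,
        foreground_kind = contrast$foreground_kind,
        method = contrast$method, stringsAsFactors = FALSE)
    } else {
      warning("selection stage skipped: concatenated PCGs unequal in ",
              "length or depth groups too small", call. = FALSE)
    }
  }

  tables <- Filter(Negate(is.null), results)
  write_report_tables(tables, out_dir, digits = digits)
  manifest <- list(
    package = "mitocompare",
    version = as.character(utils::packageVersion("mitocompare")),
    genomes = vapply(genomes, `[[`, character(1), "id"),
    n_alignments = length(alignments),
    code_id = code_id, window = window, step = step, min_run = min_run,
    seed = seed, tables = names(tables))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
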