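# Seeded generator of annotated circular mitogenomes and evolved genome
# families with known ground truth, emulating a compact actiniarian
# mitogenome: ~16.6 kb, 13 PCGs + 2 tRNAs + 2 rRNAs in the canonical
# order, all features on the heavy strand, AT-rich with negative AT skew
# and positive GC skew, 17 intergenic spacers including a 147 bp
# control-region-like spacer (with an embedded G(A)nT motif) between
# s-rRNA and cox2 and a 223 bp spacer between ND5 and ND1.

#' Default gene plan
#'
#' The canonical 17-gene actiniarian layout with realistic lengths; CDS
#' lengths sum to 12,105 bp. ND3 is assigned stop codon TAG, all other
#' PCGs TAA.
#'
#' @return data.frame `name kind length strand stop_codon`.
#' @export
default_gene_plan <- function() {
  plan <- data.frame(
    name = canonical_gene_order(),
    kind = c("CDS", "CDS", "CDS", "tRNA", "CDS", "rRNA", "CDS", "CDS",
             "CDS", "CDS", "tRNA", "rRNA", "CDS", "CDS", "CDS", "CDS",
             "CDS"),
    length = c(1836L, 984L, 351L, 71L, 1200L, 1055L, 741L, 1479L, 660L,
               1194L, 70L, 2162L, 864L, 1575L, 300L, 216L, 705L),
    strand = 1L, stringsAsFactors = FALSE)
  plan$stop_codon <- ifelse(plan$kind == "CDS",
                            ifelse(plan$name == "ND3", "TAG", "TAA"),
                            NA_character_)
  plan
}

#' Default spacer plan
#'
#' One spacer after each gene (17 junctions on the circle), totalling
#' 1,112 bp: 223 bp after ND5 (the longest, before ND1), 147 bp after
#' s-rRNA (before cox2) carrying the embedded G(A)nT motif, and the
#' remaining 742 bp split near-evenly over the other 15 junctions.
#'
#' @return data.frame `after length motif`.
#' @export
default_spacer_plan <- function() {
  genes <- canonical_gene_order()
  len <- rep(49L, length(genes))
  special <- c("ND5", "s-rRNA")
  rest <- which(!genes %in% special)
  # 742 bp over 15 plain spacers: seven of 50, eight of 49
  len[rest] <- 49L
  len[rest[seq_len(7)]] <- 50L
  len[genes == "ND5"] <- 223L
  len[genes == "s-rRNA"] <- 147L
  data.frame(after = genes, length = len, motif = genes == "s-rRNA",
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @param gene_plan see [default_gene_plan()].
#' @param spacer_plan see [default_spacer_plan()].
#' @param at_percent target A+T percentage (default 62.4, typical of
#'   actiniarian PCG regions).
#' @param at_skew,gc_skew target skews (defaults -0.12 / +0.12: T over A,
#'   G over C).
#' @param rna_at named vector of AT% overrides for non-CDS features
#'   (defaults: s-rRNA 54.9, l-rRNA 58.9).
#' @param codon_bias optional named multiplier on codon weights (e.g.
#'   `c(GTT = 3)` to inflate valine usage).
#' @param motif_run number of A's in the embedded G(A)nT motif.
#' @param tips data.frame `id branch_length omega depth_class` describing
#'   a star tree of descendants (branch_length in expected candidate
#'   substitutions per site).
#' @param gene_rates named per-gene rate multipliers (unnamed genes get 1).
#' @param code_id NCBI translation table (default 4).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       gene_plan = default_gene_plan(),
                       spacer_plan = default_spacer_plan(),
                       at_percent = 62.4, at_skew = -0.12, gc_skew = 0.12,
                       rna_at = c("s-rRNA" = 54.9, "l-rRNA" = 58.9),
                       codon_bias = NULL, motif_run = 6L,
                       tips = NULL, gene_rates = NULL, code_id = 4L) {
  stopifnot(abs(at_skew) <= 1, abs(gc_skew) <= 1,
            at_percent > 0, at_percent < 100)
  if (any(gene_plan$length[gene_plan$kind == "CDS"] %% 3L != 0L))
    stop("CDS lengths must be divisible by 3", call. = FALSE)
  if (is.null(tips))
    tips <- data.frame(id = paste0("tip", 1:4),
                       branch_length = 0.02, omega = 0.1,
                       depth_class = c("deep", "deep", "shallow",
                                       "shallow"),
                       stringsAsFactors = FALSE)
  stopifnot(all(tips$branch_length >= 0), all(tips$omega >= 0))
  structure(list(seed = as.integer(seed), gene_plan = gene_plan,
                 spacer_plan = spacer_plan, at_percent = at_percent,
                 at_skew = at_skew, gc_skew = gc_skew, rna_at = rna_at,
                 codon_bias = codon_bias, motif_run = as.integer(motif_run),
                 tips = tips, gene_rates = gene_rates,
                 code_id = as.integer(code_id)),
            class = "sim_config")
}

.base_probs <- function(at_percent, at_skew, gc_skew) {
  at <- at_percent / 100
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, T = at * (1 - at_skew) / 2,
    G = gc * (1 + gc_skew) / 2, C = gc * (1 - gc_skew) / 2)
}

.quota_counts <- function(n, probs) {
  # largest-remainder apportionment: realized counts hit the target
  # distribution to within one unit per category
  cnt <- floor(n * probs)
  r <- n - sum(cnt)
  if (r > 0) {
    frac <- n * probs - cnt
    cnt[order(-frac)[seq_len(r)]] <- cnt[order(-frac)[seq_len(r)]] + 1
  }
  cnt
}

.sample_bases <- function(n, probs) {
  cnt <- .quota_counts(n, probs / sum(probs))
  paste(sample(rep(names(probs), cnt)), collapse = "")
}

.codon_base_content <- function(codons) {
  t(vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    c(A = sum(b == "A"), C = sum(b == "C"),
      G = sum(b == "G"), T = sum(b == "T"))
  }, numeric(4)))
}

.codon_weights <- function(cfg, code) {
  # Codon weights whose implied base composition matches the configured
  # targets. Excluding stop codons (and any codon-bias override) shifts
  # the pool's base content, so the underlying base probabilities are
  # calibrated by fixed-point iteration until the expected composition of
  # the sense-codon distribution hits the target.
  target <- .base_probs(cfg$at_percent, cfg$at_skew, cfg$gc_skew)
  codons <- names(code$map)
  content <- .codon_base_content(codons)[, names(target)]
  probs <- target
  w <- NULL
  for (it in 1:100) {
    w <- exp(content %*% log(pmax(probs, 1e-12)))[, 1]
    w[code$map == "*"] <- 0
    if (!is.null(cfg$codon_bias))
      w[names(cfg$codon_bias)] <- w[names(cfg$codon_bias)] * cfg$codon_bias
    w <- w / sum(w)
    e <- colSums(w * content) / 3
    if (max(abs(e - target)) < 1e-10) break
    probs <- probs * target / e
    probs <- probs / sum(probs)
  }
  w
}

#' Generate a synthetic ancestral mitogenome
#'
#' Lays genes and spacers out in the configured circular order; CDS are
#' built codon-by-codon as a seeded shuffle of quota-apportioned codons
#' drawn from composition-calibrated weights, with an ATG start and the
#' planned stop (TAA, TAG for ND3), so they contain no internal stops and
#' hit the composition targets to within one codon per type; rRNA/tRNA
#' genes and spacers are seeded shuffles of quota-apportioned bases at the
#' target composition; the motif spacer carries an explicit G(A)nT at its
#' midpoint.
#'
#' @param cfg a [sim_config()].
#' @return list `genome` (a [mito_genome()]) and `truth` (configured
#'   targets plus realized per-gene composition, motif position, and
#'   layout).
#' @export
generate_ancestor <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  code <- genetic_code(cfg$code_id)
  cw <- .codon_weights(cfg, code)
  codons <- names(cw)
  pieces <- character()
  feats <- list()
  pos <- 0L
  motif_at <- NA_integer_
  for (i in seq_len(nrow(cfg$gene_plan))) {
    g <- cfg$gene_plan[i, ]
    if (g$kind == "CDS") {
      k <- g$length / 3L
      cnt <- .quota_counts(k - 2L, cw)
      body <- sample(rep(codons, cnt))
      s <- paste0("ATG", paste(body, collapse = ""), g$stop_codon)
    } else {
      at <- if (g$name %in% names(cfg$rna_at)) cfg$rna_at[[g$name]]
      else cfg$at_percent
      s <- .sample_bases(g$length,
                         .base_probs(at, cfg$at_skew, cfg$gc_skew))
    }
    feats[[i]] <- data.frame(name = g$name, kind = g$kind, start = pos,
                             end = pos + g$length, strand = 1L,
                             frame_warning = FALSE,
                             stringsAsFactors = FALSE)
    pieces <- c(pieces, s)
    pos <- pos + g$length
    sp <- cfg$spacer_plan[cfg$spacer_plan$after == g$name, ]
    if (nrow(sp) == 1 && sp$length > 0) {
      spc <- .sample_bases(sp$length,
                           .base_probs(cfg$at_percent, cfg$at_skew,
                                       cfg$gc_skew))
      if (isTRUE(sp$motif)) {
        motif <- paste0("G", strrep("A", cfg$motif_run), "T")
        off <- max(0L, (sp$length - nchar(motif)) %/% 2L)
        spc <- paste0(substr(spc, 1, off), motif,
                      substr(spc, off + nchar(motif) + 1L, sp$length))
        motif_at <- pos + off
      }
      pieces <- c(pieces, spc)
      pos <- pos + sp$length
    }
  }
  genome <- mito_genome("ancestor", paste(pieces, collapse = ""),
                        do.call(rbind, feats), circular = TRUE)
  pcg <- cfg$gene_plan$name[cfg$gene_plan$kind == "CDS"]
  realized <- per_gene_skew_table(list(genome))
  truth <- list(
    seed = cfg$seed,
    targets = list(at_percent = cfg$at_percent, at_skew = cfg$at_skew,
                   gc_skew = cfg$gc_skew),
    gene_plan = cfg$gene_plan,
    pcg_total_length = sum(cfg$gene_plan$length[cfg$gene_plan$kind ==
                                                  "CDS"]),
    genome_length = nchar(genome$sequence),
    motif_start = motif_at, motif_run = cfg$motif_run,
    realized_composition = realized)
  list(genome = genome, truth = truth)
}

.evolve_cds <- function(cods, p, omega, map) {
  bases <- c("A", "C", "G", "T")
  L <- 3L * length(cods)
  hit <- which(stats::runif(L) < p)
  for (idx in hit) {
    ci <- (idx - 1L) %/% 3L + 1L
    pp <- (idx - 1L) %% 3L + 1L
    if (map[cods[ci]] == "*") next      # the stop codon itself is frozen
    b <- strsplit(cods[ci], "")[[1]]
    alt <- sample(setdiff(bases, b[pp]), 1L)
    nb <- b; nb[pp] <- alt
    new <- paste(nb, collapse = "")
    if (map[new] == "*") next                       # stops never introduced
    if (map[new] == map[cods[ci]] ||
        stats::runif(1) < omega) cods[ci] <- new
  }
  cods
}

.evolve_neutral <- function(chars, p) {
  bases <- c("A", "C", "G", "T")
  hit <- which(stats::runif(length(chars)) < p & chars %in% bases)
  for (idx in hit)
    chars[idx] <- sample(setdiff(bases, chars[idx]), 1L)
  chars
}

#' Evolve a family of genomes from an ancestor
#'
#' Star-tree descent: each tip accumulates candidate substitutions at
#' `branch_length x gene rate multiplier` expected events per site.
#' Within CDS, a candidate change is classified under the genetic code;
#' synonymous changes are always accepted, nonsynonymous changes with
#' probability the tip's `omega`, and changes creating a stop codon never.
#' rRNA/tRNA genes and spacers evolve neutrally. Annotations carry over
#' unchanged (no indels are simulated, so per-gene alignments are trivial).
#' Deeper topologies can be composed by evolving a tip again as a new
#' ancestor.
#'
#' @param ancestor a [mito_genome()] (typically from
#'   [generate_ancestor()]); features must be on strand +1.
#' @param cfg a [sim_config()] supplying `tips`, `gene_rates` and the
#'   genetic code.
#' @param seed RNG seed for the evolution stage (default `cfg$seed + 1`).
#' @return list `genomes` (named list of tip [mito_genome()]s) and
#'   `truth` (per-tip omega, branch lengths, per-gene expected divergence
#'   between tip pairs).
#' @export
evolve_family <- function(ancestor, cfg = sim_config(),
                          seed = cfg$seed + 1L) {
  set.seed(seed)
  stopifnot(all(ancestor$features$strand == 1L))
  code <- genetic_code(cfg$code_id)
  map <- code$map
  rate_of <- function(g) {
    if (!is.null(cfg$gene_rates) && g %in% names(cfg$gene_rates))
      cfg$gene_rates[[g]] else 1
  }
  f <- ancestor$features
  L <- nchar(ancestor$sequence)
  genomes <- list()
  for (t in seq_len(nrow(cfg$tips))) {
    tip <- cfg$tips[t, ]
    chars <- strsplit(ancestor$sequence, "", fixed = TRUE)[[1]]
    covered <- logical(L)
    for (i in seq_len(nrow(f))) {
      span <- (f$start[i] + 1L):f$end[i]
      covered[span] <- TRUE
      p <- tip$branch_length * rate_of(f$name[i])
      if (p <= 0) next
      if (f$kind[i] == "CDS") {
        cods <- split_codons(paste(chars[span], collapse = ""))
        cods <- .evolve_cds(cods, p, tip$omega, map)
        chars[span] <- strsplit(paste(cods, collapse = ""), "")[[1]]
      } else {
        chars[span] <- .evolve_neutral(chars[span], p)
      }
    }
    ig <- which(!covered)
    if (length(ig) && tip$branch_length > 0)
      chars[ig] <- .evolve_neutral(chars[ig], tip$branch_length)
    genomes[[tip$id]] <- mito_genome(tip$id,
                                     paste(chars, collapse = ""), f,
                                     circular = ancestor$circular,
                                     depth_class = tip$depth_class)
  }
  genes <- f$name
  exp_div <- vapply(genes, function(g) 2 * rate_of(g), numeric(1))
  truth <- list(seed = seed, tips = cfg$tips,
                gene_rates = stats::setNames(
                  vapply(genes, rate_of, numeric(1)), genes),
                expected_pairwise_divergence_per_branch_unit = exp_div)
  list(genomes = genomes, truth = truth)
}

#' Per-gene family alignments
#'
#' Extracts each gene across a family of genomes with identical
#' annotations; since the simulator introduces no indels these extracted
#' sequences are already aligned.
#'
#' @param genomes named list of [mito_genome()] objects.
#' @param genes gene labels (default: all features of the first genome).
#' @return named list of [mito_alignment()] objects.
#' @export
build_family_alignments <- function(genomes,
                                    genes = genomes[[1]]$features$name) {
  stats::setNames(lapply(genes, function(g) {
    seqs <- vapply(genomes, function(gm) extract_feature_sequence(gm, g),
                   character(1))
    mito_alignment(g, seqs, names(genomes))
  }), genes)
}

#' Write a simulated family to disk
#'
#' Emits, per genome, a FASTA and a 1-based feature table TSV (the
#' [read_feature_table()] dialect); per gene, an aligned multi-FASTA for
#' the family; and `truth.json`.
#'
#' @param family result of [evolve_family()] (or a
#'   `list(genomes = , truth = )`).
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
emit_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(family$genomes)) {
    g <- family$genomes[[id]]
    ss <- Biostrings::DNAStringSet(stats::setNames(g$sequence, g$id))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(id, ".fasta")))
    f <- g$features
    utils::write.table(
      data.frame(name = f$name, kind = f$kind, start = f$start + 1L,
                 end = ifelse(f$end > nchar(g$sequence),
                              f$end - nchar(g$sequence), f$end),
                 strand = ifelse(f$strand == 1L, "+", "-")),
      file.path(dir, paste0(id, ".features.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  alns <- build_family_alignments(family$genomes)
  for (g in names(alns)) {
    a <- alns[[g]]
    ss <- Biostrings::DNAStringSet(stats::setNames(a$seqs, a$ids))
    Biostrings::writeXStringSet(
      ss, file.path(dir, paste0("aln_", gsub("[^A-Za-z0-9_-]", "_", g),
                                ".fasta")))
  }
  jsonlite::write_json(family$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(dir)
}
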