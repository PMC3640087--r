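## cli_report: stage orchestration behind a single configuration object,
## with a consolidated machine-readable report.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package's parsers) or the
#' corresponding in-memory objects.  Holds every tunable constant of the
#' pipeline: the 2-Mb QTL window, the Ks epoch thresholds 0.3/1.5, the
#' divergence-ratio bin edges (1, 2, 10) implied by the bin rules, the
#' detection threshold, linkage and fate thresholds.
#'
#' @param annotation path or [genome_annotation()].
#' @param pairs path or pairs data.frame.
#' @param collinearity path or list of `collinear_block`.
#' @param qtl path or `qtl_loci`.
#' @param counts path or [count_matrix()]; when a path, `library_sizes`
#'   must be a path to the sample/library-size TSV.
#' @param library_sizes path to a TSV with columns `sample`,
#'   `library_size` (ignored when `counts` is a `count_matrix`).
#' @param divergence_pairs optional path or data.frame of paralog pairs
#'   for the divergence stage (defaults to `pairs`).
#' @param reference_gene_ids reference genes for relative expression
#'   (required for the expression stage).
#' @param window_bp,seed_keywords,tau,proximal_max_rank_gap,ks_thresholds,min_block_pairs,max_block_gaps,linkage,silence_frac,div_frac,seed_samples
#'   stage parameters (see the stage functions).
#' @param stages character subset of
#'   `c("annotation","duplication","qtl","expression","fates")`.
#' @param outdir optional directory for per-stage TSVs and the JSON report.
#' @param rng_seed recorded in the report.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, pairs = NULL, collinearity = NULL,
                            qtl = NULL, counts = NULL, library_sizes = NULL,
                            divergence_pairs = NULL,
                            reference_gene_ids = NULL,
                            window_bp = 2e6,
                            seed_keywords = default_seed_keywords(),
                            tau = 0, proximal_max_rank_gap = 10,
                            ks_thresholds = c(0.3, 1.5),
                            min_block_pairs = 5, max_block_gaps = 20,
                            linkage = "average",
                            silence_frac = 0.8, div_frac = 0.5,
                            seed_samples = seed_tissue_labels(),
                            stages = c("annotation", "duplication", "qtl",
                                       "expression", "fates"),
                            outdir = NULL, rng_seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(window_bp > 0, tau >= 0, proximal_max_rank_gap >= 1,
            ks_thresholds[1L] < ks_thresholds[2L], ks_thresholds[1L] > 0)
  if ("expression" %in% stages && is.null(counts))
    stop("expression stage requested but no counts input configured")
  if ("fates" %in% stages && !"expression" %in% stages)
    stop("fates stage requires the expression stage")
  if ("qtl" %in% stages && is.null(qtl))
    stop("qtl stage requested but no QTL input configured")
  structure(as.list(environment()), class = "pipeline_config")
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the pipeline
#'
#' Executes the configured stages in order (annotation, duplication
#' classification + block dating, QTL co-localization, expression
#' normalization + tissue bias + clustering, paralog fates) and collects
#' every summary count into a single report.  When `outdir` is set,
#' per-stage TSVs and the consolidated `report.json` are written there.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `famfates_report`: a list of stage results and
#'   a `summary` list of named counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  summ <- list(rng_seed = config$rng_seed)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()

  t0 <- tic()
  ann <- load_input(config$annotation, read_annotation)
  res$annotation <- ann
  summ$n_genes <- nrow(ann$genes)
  summ$n_chromosomes <- length(unique(ann$genes$chromosome))
  timings["annotation"] <- tic() - t0

  if ("duplication" %in% config$stages) {
    t0 <- tic()
    pairs <- load_input(config$pairs, read_pairs)
    blocks <- if (is.null(config$collinearity)) list()
              else load_input(config$collinearity, read_collinearity)
    blocks <- validate_blocks(blocks, ann, config$min_block_pairs,
                              config$max_block_gaps)
    blocks <- date_blocks(blocks, thresholds = config$ks_thresholds)
    calls <- classify_duplication_modes(ann, pairs, blocks,
                                        config$proximal_max_rank_gap)
    res$pairs <- pairs
    res$blocks <- blocks
    res$duplication_calls <- calls
    summ$mode_counts <- as.list(table(factor(calls$mode, levels = DUP_MODES)))
    bt <- blocks_table(blocks)
    if (!is.null(bt)) {
      summ$n_blocks <- nrow(bt)
      summ$n_valid_blocks <- sum(bt$valid, na.rm = TRUE)
      summ$epoch_counts <- as.list(table(factor(bt$epoch[bt$valid %in% TRUE],
                                                levels = EPOCH_LEVELS)))
    }
    timings["duplication"] <- tic() - t0
  }

  if ("qtl" %in% config$stages) {
    t0 <- tic()
    loci <- load_input(config$qtl, read_qtl_table)
    assoc <- window_associate(ann, loci, config$window_bp, config$seed_keywords)
    res$qtl_loci <- loci
    res$associations <- assoc
    summ$colocalization <- summarize_colocalization(assoc, loci,
                                                    config$seed_keywords)
    timings["qtl"] <- tic() - t0
  }

  if ("expression" %in% config$stages) {
    t0 <- tic()
    cm <- if (inherits(config$counts, "count_matrix")) config$counts
    else {
      tab <- utils::read.delim(config$counts, check.names = FALSE)
      counts <- as.matrix(tab[, -1L, drop = FALSE])
      rownames(counts) <- tab[[1L]]
      libs <- utils::read.delim(config$library_sizes)
      count_matrix(counts,
                   stats::setNames(libs$library_size, libs$sample),
                   stats::setNames(ann$genes$exon_total_length,
                                   ann$genes$gene_id))
    }
    rpkm <- compute_rpkm(cm)
    rel <- if (is.null(config$reference_gene_ids)) rpkm
           else relative_expression(rpkm, config$reference_gene_ids)
    flags <- detection_flags(rel, config$tau)
    bias <- tissue_bias_category(flags, config$seed_samples)
    res$rpkm <- rpkm
    res$relative <- rel
    res$detection <- flags
    res$tissue_bias <- bias
    res$seed_expressed <- seed_expressed_set(flags, config$seed_samples)
    summ$tissue_bias_counts <- as.list(table(factor(bias,
      levels = c("UNDETECTED_ALL", "SEED_ONLY", "NONSEED_ONLY", "UNBIASED"))))
    summ$n_seed_expressed <- length(res$seed_expressed)
    ## cluster the detected genes on z-scored profiles
    keep <- names(bias)[bias != "UNDETECTED_ALL"]
    if (length(keep) >= 2L) {
      z <- suppressMessages(genewise_normalize(rel[keep, , drop = FALSE]))
      if (nrow(z) >= 2L) {
        res$clustering <- hierarchical_cluster(z, config$linkage)
        summ$n_clustered_genes <- nrow(z)
      }
    }
    if ("qtl" %in% config$stages) {
      res$seed_candidates <- seed_candidate_genes(res$associations,
                                                  res$seed_expressed)
      summ$n_seed_candidates <- length(res$seed_candidates)
    }
    timings["expression"] <- tic() - t0
  }

  if ("fates" %in% config$stages) {
    t0 <- tic()
    dpairs <- load_input(config$divergence_pairs %||% config$pairs, read_pairs)
    if (is.null(dpairs)) stop("fates stage requires divergence_pairs or pairs")
    div <- divergence_table(dpairs, res$relative, config$tau)
    fates <- classify_fate(dpairs, res$relative, config$tau,
                           config$silence_frac, config$div_frac)
    res$divergence <- div
    res$fates <- fates
    summ$divergence_counts <- as.list(div$counts)
    summ$divergence_percent <- as.list(stats::setNames(div$percentages,
                                                       BIN_LEVELS))
    summ$fate_counts <- as.list(table(factor(fates$fate, levels = FATE_LEVELS)))
    timings["fates"] <- tic() - t0
  }

  summ$timings_sec <- as.list(round(timings, 3))
  res$summary <- summ
  out <- structure(res, class = "famfates_report")
  if (!is.null(config$outdir)) write_report(out, config$outdir)
  out
}

#' Write a pipeline report bundle
#'
#' Per-stage TSVs plus `report.json` with every summary count.
#'
#' @param report a `famfates_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  if (!is.null(report$duplication_calls))
    w(report$duplication_calls, "duplication_modes.tsv")
  if (!is.null(report$blocks)) w(blocks_table(report$blocks), "blocks.tsv")
  if (!is.null(report$associations)) w(report$associations, "associations.tsv")
  if (!is.null(report$relative))
    write_expression(report$relative, file.path(dir, "relative_expression.tsv"))
  if (!is.null(report$tissue_bias))
    w(data.frame(gene_id = names(report$tissue_bias),
                 category = report$tissue_bias), "tissue_bias.tsv")
  if (!is.null(report$clustering))
    write_tree_newick(report$clustering$tree, file.path(dir, "cluster_tree.nwk"))
  if (!is.null(report$fates)) w(report$fates, "pair_fates.tsv")
  summ <- report$summary
  summ$timings_sec <- NULL   # wall-clock noise; keep report.json reproducible
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.famfates_report <- function(x, ...) {
  s <- x$summary
  cat("famfates pipeline report\n")
  cat("  genes:", s$n_genes, "on", s$n_chromosomes, "chromosomes\n")
  if (!is.null(s$mode_counts))
    cat("  duplication modes:",
        paste(sprintf("%s=%d", names(s$mode_counts),
                      unlist(s$mode_counts)), collapse = ", "), "\n")
  if (!is.null(s$colocalization))
    cat(sprintf("  QTL co-localization: %d genes near %d loci (seed: %d genes, %d loci)\n",
                s$colocalization$n_genes_any, s$colocalization$n_loci_any,
                s$colocalization$n_genes_seed, s$colocalization$n_loci_seed))
  if (!is.null(s$tissue_bias_counts))
    cat("  tissue bias:",
        paste(sprintf("%s=%d", names(s$tissue_bias_counts),
                      unlist(s$tissue_bias_counts)), collapse = ", "), "\n")
  if (!is.null(s$n_seed_candidates))
    cat("  seed candidate genes:", s$n_seed_candidates, "\n")
  if (!is.null(s$divergence_counts))
    cat("  divergence bins:",
        paste(sprintf("%s=%d", names(s$divergence_counts),
                      unlist(s$divergence_counts)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.famfates_report <- function(object, ...) object$summary

#' Reproduce the printed summary counts from supplementary-style tables
#'
#' Consumes TSV exports of a study's supplementary tables: `gene_table.tsv`
#' (gene info in the tabular annotation dialect), `paralog_pairs.tsv`
#' (`gene_a`, `gene_b`), `qtl.tsv` (marker/QTL table) and
#' `expression.tsv` (relative expression, genes x 17 tissues, written as
#' by [write_expression()]), and recomputes the headline counts: the
#' divergence-bin table over pairs x tissues, the co-localization summary,
#' tissue-bias counts and the seed-candidate intersection.
#'
#' @param dir directory holding the four TSVs.
#' @param window_bp,tau,seed_samples,seed_keywords stage parameters.
#' @return List with `divergence`, `colocalization`, `tissue_bias_counts`,
#'   `n_seed_expressed`, `n_seed_candidates`.
#' @export
reproduce_study_counts <- function(dir, window_bp = 2e6, tau = 0,
                                   seed_samples = seed_tissue_labels(),
                                   seed_keywords = default_seed_keywords()) {
  need <- file.path(dir, c("gene_table.tsv", "paralog_pairs.tsv", "qtl.tsv",
                           "expression.tsv"))
  absent <- need[!file.exists(need)]
  if (length(absent))
    stop("supplementary table export(s) not found: ",
         paste(basename(absent), collapse = ", "))
  ann <- read_annotation(need[1L], "table")
  pairs <- utils::read.delim(need[2L], check.names = FALSE)
  loci <- read_qtl_table(need[3L])
  rel <- read_expression(need[4L])
  assoc <- window_associate(ann, loci, window_bp, seed_keywords)
  flags <- detection_flags(rel, tau)
  bias <- tissue_bias_category(flags, seed_samples)
  seed_expr <- seed_expressed_set(flags, seed_samples)
  list(divergence = divergence_table(pairs, rel, tau),
       colocalization = summarize_colocalization(assoc, loci, seed_keywords),
       tissue_bias_counts = as.list(table(factor(bias,
         levels = c("UNDETECTED_ALL", "SEED_ONLY", "NONSEED_ONLY", "UNBIASED")))),
       n_seed_expressed = length(seed_expr),
       n_seed_candidates = length(seed_candidate_genes(assoc, seed_expr)))
}
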