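## expression: RPKM, reference-gene-relative normalization, detection and
## tissue bias, gene-wise z-scores and hierarchical clustering.

#' Construct a count matrix container
#'
#' @param counts genes x samples matrix of non-negative integer read
#'   counts with row and column names.
#' @param library_sizes named vector of total mapped reads per sample.
#' @param exon_lengths named vector of total exon length (bp) per gene.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_sizes, exon_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (any(counts < 0)) stop("negative counts")
  bad <- setdiff(colnames(counts), names(library_sizes))
  if (length(bad)) stop("missing library size for sample: ", bad[1L])
  bad <- setdiff(rownames(counts), names(exon_lengths))
  if (length(bad)) stop("missing exon length for gene: ", bad[1L])
  library_sizes <- library_sizes[colnames(counts)]
  exon_lengths <- exon_lengths[rownames(counts)]
  if (any(library_sizes <= 0))
    stop("non-positive library size for sample: ",
         colnames(counts)[which(library_sizes <= 0)[1L]])
  if (any(exon_lengths <= 0))
    stop("non-positive exon length for gene: ",
         rownames(counts)[which(exon_lengths <= 0)[1L]])
  structure(list(counts = counts, library_sizes = library_sizes,
                 exon_lengths = exon_lengths), class = "count_matrix")
}

expression_matrix <- function(m, stage) {
  structure(m, stage = stage, class = c("expression_matrix", class(m)))
}

#' Normalization stage of an expression matrix
#' @param m an `expression_matrix`.
#' @return `"RPKM"`, `"RELATIVE"` or `"ZSCORE"`.
#' @export
expression_stage <- function(m) attr(m, "stage")

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              attr(x, "stage"), nrow(x), ncol(x)))
  invisible(x)
}

#' RPKM normalization
#'
#' Corrects for total gene exon size and library depth:
#' `RPKM[g, s] = 1e9 * C[g, s] / (N[s] * L[g])` with `C` read counts, `N`
#' total mapped reads of the sample and `L` the gene's total exon length
#' in bp.
#'
#' @param counts a [count_matrix()].
#' @return genes x samples `expression_matrix` at stage `"RPKM"`.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- 1e9 * sweep(sweep(counts$counts, 2, counts$library_sizes, "/"),
                   1, counts$exon_lengths, "/")
  expression_matrix(m, "RPKM")
}

#' Reference-gene-relative expression
#'
#' The reference value of a sample is the geometric mean of the reference
#' genes' RPKM in that sample; relative expression is the ratio of each
#' gene's RPKM to it.  A reference gene with zero RPKM in any sample is an
#' error unless a positive `pseudo` floor is supplied.
#'
#' @param rpkm an `expression_matrix` at stage `"RPKM"`.
#' @param reference_gene_ids character vector of reference genes (rows of
#'   `rpkm`).
#' @param pseudo optional floor added to reference RPKM values (opt-in;
#'   default 0 = fail loudly on zeros).
#' @return `expression_matrix` at stage `"RELATIVE"`, with the per-sample
#'   reference values in attribute `"reference_value"`.
#' @export
relative_expression <- function(rpkm, reference_gene_ids, pseudo = 0) {
  miss <- setdiff(reference_gene_ids, rownames(rpkm))
  if (length(miss)) stop("reference gene(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  if (length(reference_gene_ids) == 0L) stop("need at least one reference gene")
  ref <- unclass(rpkm)[reference_gene_ids, , drop = FALSE] + pseudo
  if (any(ref <= 0))
    stop("reference gene with zero RPKM in some sample; ",
         "supply a positive `pseudo` floor to override")
  refval <- exp(colMeans(log(ref)))
  out <- sweep(unclass(rpkm), 2, refval, "/")
  out <- expression_matrix(out, "RELATIVE")
  attr(out, "reference_value") <- refval
  attr(out, "reference_genes") <- reference_gene_ids
  out
}

#' Detection flags
#'
#' A gene is detected in a sample when its value exceeds `tau`.  The
#' default `tau = 0` treats any nonzero signal as detected.
#'
#' @param m expression matrix (RPKM or RELATIVE stage).
#' @param tau detection threshold.
#' @return Logical genes x samples matrix.
#' @export
detection_flags <- function(m, tau = 0) {
  f <- unclass(m) > tau
  storage.mode(f) <- "logical"
  f
}

#' Tissue-bias category per gene
#'
#' `UNDETECTED_ALL` when no sample is detected; `SEED_ONLY` when every
#' detected sample is a seed sample; `NONSEED_ONLY` when every detected
#' sample is a non-seed sample; `UNBIASED` otherwise.
#'
#' @param flags logical genes x samples matrix from [detection_flags()].
#' @param seed_samples seed-sample labels (nonempty strict subset of the
#'   columns; default [seed_tissue_labels()]).
#' @return Named character vector, one category per gene.
#' @export
tissue_bias_category <- function(flags, seed_samples = seed_tissue_labels()) {
  seed_samples <- intersect(colnames(flags), seed_samples)
  if (length(seed_samples) == 0L || length(seed_samples) == ncol(flags))
    stop("seed_samples must be a nonempty strict subset of the samples")
  in_seed <- colnames(flags) %in% seed_samples
  apply(flags, 1L, function(f) {
    if (!any(f)) "UNDETECTED_ALL"
    else if (all(in_seed[f])) "SEED_ONLY"
    else if (!any(in_seed[f])) "NONSEED_ONLY"
    else "UNBIASED"
  })
}

#' Genes detected in at least one seed sample
#' @inheritParams tissue_bias_category
#' @return Character vector of gene ids.
#' @export
seed_expressed_set <- function(flags, seed_samples = seed_tissue_labels()) {
  seed_samples <- intersect(colnames(flags), seed_samples)
  rownames(flags)[rowSums(flags[, seed_samples, drop = FALSE]) > 0]
}

#' Gene-wise z-score normalization
#'
#' Each retained row is centred and scaled to mean 0, sd 1, using the
#' population standard deviation (denominator n).  Constant rows cannot be
#' scaled and are excluded; their ids are reported in the `"excluded"`
#' attribute and via a message.
#'
#' @param m expression matrix.
#' @return `expression_matrix` at stage `"ZSCORE"`.
#' @export
genewise_normalize <- function(m) {
  if (ncol(m) < 2L) stop("cannot normalize a single-sample matrix")
  x <- unclass(m)
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  keep <- sdev > 0
  if (any(!keep))
    message("excluding ", sum(!keep), " constant row(s) from normalization")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  out <- expression_matrix(z, "ZSCORE")
  attr(out, "excluded") <- rownames(x)[!keep]
  out
}

#' Pearson correlation distance
#'
#' `d = 1 - r(x, y)`, in `[0, 2]`.
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return Distance in `[0, 2]`.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  1 - stats::cor(x, y)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of matrix rows on Pearson correlation distance
#' (`1 - r`).  Average linkage (UPGMA) is the default, matching common
#' expression-clustering practice; ties are resolved deterministically by
#' row order through the underlying [stats::hclust()].
#'
#' @param m numeric matrix (rows = genes), at least 2 non-constant rows.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @param k optional number of clusters for the returned labels.
#' @param h optional cut height (used when `k` is missing).
#' @return List with `tree` (an [stats::hclust] object) and `labels`
#'   (named integer cluster labels, or `NULL` when no cut was requested).
#' @export
hierarchical_cluster <- function(m, linkage = c("average", "single", "complete"),
                                 k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  m <- unclass(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  sdev <- apply(m, 1L, stats::sd)
  if (any(sdev == 0))
    stop("constant row(s) cannot be clustered on correlation distance: ",
         paste(utils::head(rownames(m)[sdev == 0], 3L), collapse = ", "))
  if (!is.null(k) && k > nrow(m)) stop("k exceeds the number of rows")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  tree <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k)) stats::cutree(tree, k = k)
  else if (!is.null(h)) stats::cutree(tree, h = h)
  list(tree = tree, labels = labels)
}

#' Export a clustering merge tree as Newick
#' @param tree an [stats::hclust] object.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write an expression matrix as TSV with a stage header
#' @param m an `expression_matrix`.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", attr(m, "stage")), con)
  utils::write.table(data.frame(gene_id = rownames(m), unclass(m),
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#' @param path TSV file with a `# stage:` header line.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- if (grepl("^# stage:", first)) sub("^# stage:\\s*", "", first) else "RELATIVE"
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  expression_matrix(m, stage)
}
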