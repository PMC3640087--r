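## genome_model: annotation loading, gene order (ranks) and nearest-feature
## queries.  Internal coordinates are 1-based inclusive (GFF3 convention);
## BED input is converted at the boundary by the rtracklayer importer.

#' Construct a genome annotation
#'
#' Builds the package's central annotation container from a gene table and
#' an optional exon table.  Gene ranks (0-based position in coordinate
#' order, ties broken by `gene_id`) are computed per chromosome.
#'
#' @param genes data.frame with columns `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` and optionally `family`, `subfamily`,
#'   `exon_total_length`, `exon_count`.
#' @param exons optional data.frame with columns `gene_id`, `start`, `end`
#'   (1-based inclusive).  When present, exon totals are recomputed from it.
#' @param chromosomes optional named numeric vector of chromosome lengths
#'   (bp); defaults to the maximum gene end per chromosome.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (with `rank` and `exon_total_length` columns), `exons`, and
#'   `chromosomes`.
#' @export
genome_annotation <- function(genes, exons = NULL, chromosomes = NULL) {
  need <- c("gene_id", "chromosome", "strand", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(genes) == 0L) stop("no gene records")
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (is.null(genes$family)) genes$family <- "none"
  if (is.null(genes$subfamily)) genes$subfamily <- "none"

  if (!is.null(exons) && nrow(exons)) {
    exons$gene_id <- as.character(exons$gene_id)
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    bad <- setdiff(exons$gene_id, genes$gene_id)
    if (length(bad)) stop("exon references unknown gene: ", bad[1L])
    len <- tapply(exons$end - exons$start + 1L, exons$gene_id, sum)
    genes$exon_total_length <- as.numeric(len[genes$gene_id])
  }
  noex <- is.na(genes$exon_total_length %||% rep(NA_real_, nrow(genes)))
  if (is.null(genes$exon_total_length)) noex <- rep(TRUE, nrow(genes))
  if (any(noex)) {
    warning(sum(noex), " gene(s) without exons; using the gene span as a single exon")
    span <- genes$end - genes$start + 1L
    if (is.null(genes$exon_total_length)) genes$exon_total_length <- span
    genes$exon_total_length[noex] <- span[noex]
    add <- data.frame(gene_id = genes$gene_id[noex],
                      start = genes$start[noex], end = genes$end[noex])
    exons <- if (is.null(exons)) add else
      rbind(exons[, c("gene_id", "start", "end")], add)
  }
  if (any(genes$exon_total_length <= 0)) stop("gene with non-positive exon length")
  if (is.null(genes$exon_count)) {
    cnt <- table(exons$gene_id)
    genes$exon_count <- as.integer(cnt[genes$gene_id])
  }

  ## 0-based rank within chromosome, by start then gene_id (total order)
  genes$rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    i <- which(genes$chromosome == chr)
    genes$rank[i[order(genes$start[i], genes$gene_id[i])]] <- seq_along(i) - 1L
  }

  if (is.null(chromosomes)) {
    chromosomes <- tapply(genes$end, genes$chromosome, max)
    chromosomes <- stats::setNames(as.numeric(chromosomes), names(chromosomes))
  }
  if (!all(genes$chromosome %in% names(chromosomes)))
    stop("gene on a chromosome absent from the chromosome length map")

  structure(list(genes = genes, exons = exons, chromosomes = chromosomes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chromosome)), "chromosome(s)\n")
  fam <- table(x$genes$family)
  cat("  families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}

#' Read a genome annotation from GFF3 or a gene-table TSV
#'
#' The GFF3 dialect expects `gene` records with exons attached through the
#' `Parent` attribute; optional `family=`/`subfamily=` attributes are
#' carried into the annotation.  The tabular dialect is a TSV with columns
#' `gene_id`, `chromosome`, `strand`, `start`, `end`, `exon_count`,
#' `exon_total_length`, `family`, `subfamily` (the shape of a gene-info
#' supplementary table).
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"table"`.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "table"
  if (dialect == "gff3") read_annotation_gff3(path) else read_annotation_table(path)
}

read_annotation_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0L) stop("no gene records in ", path)
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  if (!any(is_gene)) stop("no gene records in ", path)
  g <- gr[is_gene]
  gmd <- S4Vectors::mcols(g)
  pick <- function(col, default) {
    if (col %in% names(gmd)) {
      v <- as.character(gmd[[col]])
      ifelse(is.na(v) | v == "", default, v)
    } else rep(default, length(g))
  }
  ids <- pick("ID", NA_character_)
  if (anyNA(ids)) stop("gene record without ID attribute in ", path)
  genes <- data.frame(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    family = pick("family", "none"),
    subfamily = pick("subfamily", "none"),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  exons <- NULL
  is_exon <- md$type == "exon"
  if (any(is_exon)) {
    e <- gr[is_exon]
    par <- S4Vectors::mcols(e)$Parent
    par <- vapply(as.list(par), function(p) if (length(p)) as.character(p[1L]) else NA_character_,
                  character(1))
    keep <- !is.na(par) & par %in% genes$gene_id
    exons <- data.frame(gene_id = par[keep],
                        start = GenomicRanges::start(e)[keep],
                        end = GenomicRanges::end(e)[keep])
  }
  ## chromosome lengths from ##sequence-region pragmas (covers gene-free
  ## chromosomes); genes' max end as fallback for unlisted ones
  pragmas <- grep("^##sequence-region\\s", readLines(path, warn = FALSE),
                  value = TRUE)
  chromosomes <- NULL
  if (length(pragmas)) {
    f <- strsplit(trimws(pragmas), "\\s+")
    chromosomes <- stats::setNames(vapply(f, function(x) as.numeric(x[4L]), 0),
                                   vapply(f, `[`, "", 2L))
    fallback <- tapply(genes$end, genes$chromosome, max)
    extra <- setdiff(names(fallback), names(chromosomes))
    chromosomes[extra] <- as.numeric(fallback[extra])
  }
  suppressWarnings(genome_annotation(genes, exons, chromosomes))
}

read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("no gene records in ", path)
  genome_annotation(tab)
}

#' Write a genome annotation
#'
#' Round-trips with [read_annotation()]: gene count, coordinates and exon
#' totals are preserved by either dialect.
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @param dialect `"gff3"` or `"table"`.
#' @export
write_annotation <- function(annotation, path, dialect = c("gff3", "table")) {
  dialect <- match.arg(dialect)
  g <- annotation$genes
  if (dialect == "table") {
    utils::write.table(
      g[, c("gene_id", "chromosome", "strand", "start", "end",
            "exon_count", "exon_total_length", "family", "subfamily")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  e <- annotation$exons
  gr_g <- GenomicRanges::GRanges(
    g$chromosome, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, family = g$family, subfamily = g$subfamily,
    seqinfo = si <- GenomeInfoDb::Seqinfo(names(annotation$chromosomes),
                                          unname(annotation$chromosomes)))
  st <- stats::setNames(g$strand, g$gene_id)
  gr_e <- GenomicRanges::GRanges(
    stats::setNames(g$chromosome, g$gene_id)[e$gene_id],
    IRanges::IRanges(e$start, e$end), strand = st[e$gene_id],
    type = "exon", ID = paste0(e$gene_id, ".e", seq_len(nrow(e))),
    Parent = e$gene_id, seqinfo = si)
  rtracklayer::export(c(gr_g, gr_e), path, format = "gff3")
  ## rtracklayer does not emit ##sequence-region pragmas; add them so
  ## gene-free chromosomes survive the round trip
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d",
                    names(annotation$chromosomes),
                    as.integer(annotation$chromosomes))
  first_feat <- which(!grepl("^#", lines))[1L]
  writeLines(c(lines[seq_len(first_feat - 1L)], pragma,
               lines[first_feat:length(lines)]), path)
  invisible(path)
}

#' Read genomic feature intervals (e.g. transposable elements)
#'
#' BED6 input is converted from 0-based half-open to 1-based inclusive
#' coordinates by the importer.
#'
#' @param path BED file path.
#' @param kind feature kind label stored on every interval.
#' @return data.frame with columns `feature_id`, `chromosome`, `start`,
#'   `end`, `kind`.
#' @export
read_features <- function(path, kind = "transposable_element") {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("feat", seq_along(gr))
  data.frame(feature_id = as.character(nm),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             kind = kind, stringsAsFactors = FALSE)
}

#' Interval gap distance (bp strictly between two intervals; 0 on overlap)
#' @noRd
interval_gap <- function(s1, e1, s2, e2) {
  ifelse(e1 < s2, s2 - e1 - 1, ifelse(e2 < s1, s1 - e2 - 1, 0))
}

#' Nearest feature to a gene
#'
#' Considers only features on the gene's chromosome.  Distance is the
#' number of bases strictly between the closest boundaries (0 if the
#' intervals overlap); ties are broken by the smaller feature start.
#'
#' @param gene one row of `annotation$genes` (or any list with
#'   `chromosome`, `start`, `end`).
#' @param features feature data.frame as from [read_features()].
#' @return `NULL` if no feature shares the chromosome, else a list with
#'   elements `feature` (one-row data.frame) and `distance` (bp).
#' @export
nearest_feature <- function(gene, features) {
  f <- features[features$chromosome == gene$chromosome, , drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  d <- interval_gap(gene$start, gene$end, f$start, f$end)
  i <- order(d, f$start)[1L]
  list(feature = f[i, , drop = FALSE], distance = unname(d[i]))
}

#' Gene ranks on one chromosome
#' @param annotation a [genome_annotation()].
#' @param chromosome chromosome name.
#' @return Named integer vector (gene_id -> 0-based rank), in rank order.
#' @export
gene_ranks <- function(annotation, chromosome) {
  g <- annotation$genes[annotation$genes$chromosome == chromosome, ]
  stats::setNames(g$rank, g$gene_id)[order(g$rank)]
}
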