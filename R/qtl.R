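## qtl_coloc: gene-QTL co-localization through a genomic window around
## marker positions.  QTL physical locations are uncertain, so loci are
## marker points, not confidence intervals.

#' Read a marker/QTL table into loci
#'
#' Rows sharing a (chromosome, position) are merged into one locus;
#' duplicate (qtl_id, trait) entries per locus are de-duplicated.  Rows
#' with a non-numeric position are skipped with a warning.
#'
#' @param path TSV with columns `marker_id`, `chromosome`, `position`,
#'   `qtl_id`, `trait`.
#' @return Object of class `qtl_loci`: list with `loci` (data.frame
#'   `locus_id`, `marker_id`, `chromosome`, `position`) and `qtls`
#'   (data.frame `locus_id`, `qtl_id`, `trait`).
#' @export
read_qtl_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker_id", "chromosome", "position", "qtl_id", "trait")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("QTL table is missing column(s): ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(tab$position))
  if (anyNA(pos)) {
    warning("skipping ", sum(is.na(pos)), " row(s) with non-numeric position")
    tab <- tab[!is.na(pos), , drop = FALSE]
    pos <- pos[!is.na(pos)]
  }
  tab$position <- pos
  qtl_loci(tab)
}

#' Build a `qtl_loci` object from a marker/QTL data.frame
#' @param tab data.frame with `marker_id`, `chromosome`, `position`,
#'   `qtl_id`, `trait`.
#' @return A `qtl_loci` object (see [read_qtl_table()]).
#' @export
qtl_loci <- function(tab) {
  if (nrow(tab) == 0L)
    return(structure(list(
      loci = data.frame(locus_id = character(), marker_id = character(),
                        chromosome = character(), position = numeric()),
      qtls = data.frame(locus_id = character(), qtl_id = character(),
                        trait = character())), class = "qtl_loci"))
  if (any(tab$position < 1)) stop("marker position must be >= 1")
  key <- paste(tab$chromosome, tab$position, sep = ":")
  ukey <- unique(key)
  lid <- stats::setNames(sprintf("L%03d", seq_along(ukey)), ukey)
  loci <- tab[!duplicated(key), c("marker_id", "chromosome", "position")]
  loci <- cbind(locus_id = unname(lid[key[!duplicated(key)]]), loci)
  qtls <- data.frame(locus_id = unname(lid[key]),
                     qtl_id = as.character(tab$qtl_id),
                     trait = as.character(tab$trait))
  qtls <- qtls[!duplicated(qtls[, c("locus_id", "qtl_id", "trait")]), ]
  rownames(loci) <- rownames(qtls) <- NULL
  structure(list(loci = loci, qtls = qtls), class = "qtl_loci")
}

#' @export
print.qtl_loci <- function(x, ...) {
  cat("qtl_loci:", nrow(x$loci), "loci,", length(unique(x$qtls$qtl_id)),
      "QTLs,", length(unique(x$qtls$trait)), "traits\n")
  invisible(x)
}

#' Categorize trait names as seed-relative or not
#'
#' A trait is `SEED` when its name contains any keyword (case-insensitive
#' substring match).
#'
#' @param trait_name character vector of trait names.
#' @param seed_keywords keyword list (default [default_seed_keywords()]).
#' @return Character vector of `"SEED"`/`"NON_SEED"`.
#' @export
categorize_trait <- function(trait_name, seed_keywords = default_seed_keywords()) {
  low <- tolower(trait_name)
  hit <- Reduce(`|`, lapply(tolower(seed_keywords),
                            function(k) grepl(k, low, fixed = TRUE)))
  ifelse(hit, "SEED", "NON_SEED")
}

#' Associate genes with QTL loci by genomic window
#'
#' A gene is associated with a locus when both are on the same chromosome
#' and the distance between the gene span and the marker point (bases
#' strictly between; 0 when the marker lies inside the span) is at most
#' `window_bp`.  Each (gene, locus) appears at most once.
#'
#' @param annotation a [genome_annotation()].
#' @param loci a `qtl_loci` object.
#' @param window_bp flanking window on each side of the marker
#'   (default 2 Mb).
#' @param seed_keywords keywords used for each locus's `seed_flag` (locus
#'   carries at least one seed-relative trait).
#' @return data.frame with columns `gene_id`, `locus_id`, `distance`,
#'   `seed_flag`.
#' @export
window_associate <- function(annotation, loci, window_bp = 2e6,
                             seed_keywords = default_seed_keywords()) {
  stopifnot(window_bp > 0)
  g <- annotation$genes
  L <- loci$loci
  seed_by_locus <- tapply(categorize_trait(loci$qtls$trait, seed_keywords) == "SEED",
                          loci$qtls$locus_id, any)
  unknown <- !(L$chromosome %in% names(annotation$chromosomes))
  if (any(unknown)) {
    warning("ignoring ", sum(unknown),
            " locus/loci on chromosome(s) absent from the annotation")
    L <- L[!unknown, , drop = FALSE]
  }
  out <- vector("list", nrow(L))
  for (i in seq_len(nrow(L))) {
    gi <- g[g$chromosome == L$chromosome[i], , drop = FALSE]
    if (nrow(gi) == 0L) next
    d <- interval_gap(gi$start, gi$end, L$position[i], L$position[i])
    keep <- d <= window_bp
    if (!any(keep)) next
    out[[i]] <- data.frame(gene_id = gi$gene_id[keep],
                           locus_id = L$locus_id[i],
                           distance = d[keep],
                           seed_flag = isTRUE(seed_by_locus[[L$locus_id[i]]]))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), locus_id = character(),
                      distance = numeric(), seed_flag = logical())
  rownames(out) <- NULL
  out
}

#' Summary counts of gene-QTL co-localization
#'
#' Distinct genes, loci, QTLs and traits with at least one association,
#' overall and restricted to seed-relative loci/QTLs.
#'
#' @param associations output of [window_associate()].
#' @param loci the `qtl_loci` object the associations were computed from.
#' @param seed_keywords keywords classifying traits (must match those used
#'   for the associations).
#' @return Named list of eight counts: `n_genes_any`, `n_loci_any`,
#'   `n_qtls_any`, `n_traits_any`, and the `_seed` counterparts.
#' @export
summarize_colocalization <- function(associations, loci,
                                     seed_keywords = default_seed_keywords()) {
  q <- loci$qtls
  q$cat <- categorize_trait(q$trait, seed_keywords)
  assoc_loci <- unique(associations$locus_id)
  q_any <- q[q$locus_id %in% assoc_loci, , drop = FALSE]
  q_seed <- q_any[q_any$cat == "SEED", , drop = FALSE]
  seed_loci <- unique(q_seed$locus_id)
  list(
    n_genes_any = length(unique(associations$gene_id)),
    n_loci_any = length(assoc_loci),
    n_qtls_any = length(unique(q_any$qtl_id)),
    n_traits_any = length(unique(q_any$trait)),
    n_genes_seed = length(unique(associations$gene_id[associations$seed_flag])),
    n_loci_seed = length(intersect(assoc_loci, seed_loci)),
    n_qtls_seed = length(unique(q_seed$qtl_id)),
    n_traits_seed = length(unique(q_seed$trait)))
}

#' Candidate genes for seed development
#'
#' Genes that are expressed in seed tissues *and* lie within the window of
#' at least one seed-relative locus.
#'
#' @param associations output of [window_associate()].
#' @param seed_expressed_gene_set character vector of seed-expressed genes
#'   (see [seed_expressed_set()]).
#' @return Character vector of candidate gene ids.
#' @export
seed_candidate_genes <- function(associations, seed_expressed_gene_set) {
  near_seed <- unique(associations$gene_id[associations$seed_flag])
  sort(intersect(seed_expressed_gene_set, near_seed))
}
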