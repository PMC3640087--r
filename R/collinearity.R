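## Collinearity-block I/O and validity checks.  Blocks are *inputs* (from
## an MCScanX-style scan); the package parses, validates and classifies
## them but does not detect collinearity itself.

#' Read homolog pairs from a TSV
#'
#' Columns `gene_a`, `gene_b`, `evalue` and optionally `ks`.  Pairs above
#' the e-value threshold are dropped with a message.
#'
#' @param path TSV path.
#' @param max_evalue BLASTP e-value threshold (default 1e-10).
#' @return data.frame with columns `gene_a`, `gene_b`, `evalue`, `ks`.
#' @export
read_pairs <- function(path, max_evalue = 1e-10) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(tab)))
    stop("pairs table must have columns gene_a and gene_b")
  if (is.null(tab$evalue)) tab$evalue <- 0
  if (is.null(tab$ks)) tab$ks <- NA_real_
  if (any(tab$gene_a == tab$gene_b)) stop("self-pair in pairs table")
  drop <- tab$evalue > max_evalue
  if (any(drop)) {
    message("dropping ", sum(drop), " pair(s) above e-value threshold ", max_evalue)
    tab <- tab[!drop, , drop = FALSE]
  }
  tab[, c("gene_a", "gene_b", "evalue", "ks")]
}

new_block <- function(block_id, species_a, species_b, chr_a, chr_b, anchors) {
  structure(list(block_id = as.character(block_id),
                 species_a = species_a, species_b = species_b,
                 chr_a = chr_a, chr_b = chr_b,
                 anchors = anchors, mean_ks = NA_real_,
                 epoch = NA_character_, valid = NA, invalid_reason = NA_character_),
            class = "collinear_block")
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("collinear_block %s: %s(%s) vs %s(%s), %d anchors, mean Ks %s, epoch %s%s\n",
              x$block_id, x$species_a, x$chr_a, x$species_b, x$chr_b,
              nrow(x$anchors),
              ifelse(is.na(x$mean_ks), "NA", format(x$mean_ks, digits = 3)),
              x$epoch,
              if (isFALSE(x$valid)) paste0(" [invalid: ", x$invalid_reason, "]") else ""))
  invisible(x)
}

#' Read collinearity blocks
#'
#' Two dialects: the MCScanX `.collinearity` text format (block headers
#' `## Alignment k: score=... e_value=... N=... chrA&chrB orient`, anchor
#' lines `k-i: geneA geneB evalue`) and a plain TSV with columns
#' `block_id`, `gene_a`, `gene_b`, `evalue` and optionally `ks`,
#' `species_a`, `species_b`, `chr_a`, `chr_b`.
#'
#' Blocks are returned in file order with anchors in file order; validity
#' against the minimum-anchor/maximum-gap rule is checked separately by
#' [validate_blocks()], so short blocks are parsed, not dropped.
#'
#' @param path file path.
#' @param dialect `"auto"`, `"mcscanx"` or `"tsv"`.
#' @param species_a,species_b genome labels applied to MCScanX blocks
#'   (the format itself does not carry them).
#' @return List of `collinear_block` objects (empty list for an empty file).
#' @export
read_collinearity <- function(path, dialect = c("auto", "mcscanx", "tsv"),
                              species_a = "genome", species_b = "genome") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("collinearity file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (any(grepl("^## Alignment", lines)) ||
                   any(grepl("^#+ Parameters", lines)) ||
                   grepl("\\.collinearity$", path)) "mcscanx" else "tsv"
  if (dialect == "tsv") return(read_collinearity_tsv(path))

  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur$anchors))
      blocks[[length(blocks) + 1L]] <<- new_block(cur$id, species_a, species_b,
                                                  cur$chr_a, cur$chr_b, cur$anchors)
  }
  for (ln in seq_along(lines)) {
    l <- lines[[ln]]
    if (grepl("^#{2,} ", l) && !grepl("^## Alignment", l)) next  # parameter banner
    if (l == "" || grepl("^#[^#]", l)) next
    if (grepl("^## Alignment", l)) {
      m <- regmatches(l, regexec(
        "^## Alignment ([^:]+):.*N=[0-9]+ +(\\S+)&(\\S+)", l))[[1L]]
      if (length(m) != 4L)
        stop("unreadable block header at line ", ln, ": ", l)
      flush()
      cur <- list(id = m[2L], chr_a = m[3L], chr_b = m[4L],
                  anchors = data.frame(gene_a = character(), gene_b = character(),
                                       evalue = numeric(), ks = numeric()))
    } else if (grepl("^\\s*[A-Za-z0-9_.]+-\\s*[0-9]+:", l)) {
      if (is.null(cur)) stop("anchor line before any block header at line ", ln)
      fields <- strsplit(sub("^\\s*[A-Za-z0-9_.]+-\\s*[0-9]+:\\s*", "", l), "\\s+")[[1L]]
      if (length(fields) < 2L) stop("malformed anchor at line ", ln, ": ", l)
      ev <- if (length(fields) >= 3L) suppressWarnings(as.numeric(fields[3L])) else NA_real_
      ks <- if (length(fields) >= 4L) suppressWarnings(as.numeric(fields[4L])) else NA_real_
      cur$anchors <- rbind(cur$anchors,
                           data.frame(gene_a = fields[1L], gene_b = fields[2L],
                                      evalue = ev, ks = ks))
    } else if (!grepl("^#", l)) {
      stop("malformed line ", ln, " in ", path, ": ", l)
    }
  }
  flush()
  blocks
}

read_collinearity_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) return(list())
  need <- c("block_id", "gene_a", "gene_b")
  if (!all(need %in% names(tab)))
    stop("collinearity TSV must have columns block_id, gene_a, gene_b")
  if (is.null(tab$evalue)) tab$evalue <- NA_real_
  if (is.null(tab$ks)) tab$ks <- NA_real_
  lapply(split(tab, factor(tab$block_id, levels = unique(tab$block_id))), function(b) {
    new_block(b$block_id[1L],
              b$species_a[1L] %||% "genome", b$species_b[1L] %||% "genome",
              b$chr_a[1L] %||% NA_character_, b$chr_b[1L] %||% NA_character_,
              b[, c("gene_a", "gene_b", "evalue", "ks")])
  })
}

#' Write collinearity blocks in the MCScanX text dialect
#'
#' Anchor lines carry an extra fourth column with the pair Ks when present
#' (read back by [read_collinearity()]).
#'
#' @param blocks list of `collinear_block`.
#' @param path output path.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("############### Parameters ###############",
               "# MATCH_SIZE: 5", "# MAX GAPS: 20",
               "############### Statistics ###############"), con)
  for (b in blocks) {
    a <- b$anchors
    writeLines(sprintf("## Alignment %s: score=%.1f e_value=0 N=%d %s&%s plus",
                       b$block_id, 50 * nrow(a), nrow(a), b$chr_a, b$chr_b), con)
    ks <- ifelse(is.na(a$ks), "NA", format(a$ks, digits = 10))
    writeLines(sprintf("%s-%3d: %s %s %s %s", b$block_id, seq_len(nrow(a)) - 1L,
                       a$gene_a, a$gene_b,
                       ifelse(is.na(a$evalue), "0", format(a$evalue)), ks), con)
  }
  invisible(path)
}

#' Validate collinearity blocks against the anchor/gap rule
#'
#' A block is valid when it has at least `min_pairs` anchors and no pair of
#' consecutive anchors is separated by more than `max_gaps` intervening
#' genes (gene ranks from the annotation, checked on both genomes where the
#' genes are annotated).  Anchors referencing genes absent from the
#' annotation are recorded as orphans with a warning and do not fail the
#' gap check.
#'
#' @param blocks list of `collinear_block`.
#' @param annotation a [genome_annotation()] (or `NULL` to skip gap checks).
#' @param min_pairs minimum anchors per block (default 5).
#' @param max_gaps maximum intervening-gene gap between consecutive
#'   anchors (default 20).
#' @return The blocks with `valid`/`invalid_reason` filled in.
#' @export
validate_blocks <- function(blocks, annotation = NULL, min_pairs = 5, max_gaps = 20) {
  rk <- if (!is.null(annotation))
    stats::setNames(annotation$genes$rank, annotation$genes$gene_id)
  orphans <- character()
  out <- lapply(blocks, function(b) {
    b$valid <- TRUE
    b$invalid_reason <- NA_character_
    if (nrow(b$anchors) < min_pairs) {
      b$valid <- FALSE
      b$invalid_reason <- sprintf("fewer than %d anchors", min_pairs)
      return(b)
    }
    if (!is.null(rk)) {
      for (side in c("gene_a", "gene_b")) {
        g <- b$anchors[[side]]
        known <- g %in% names(rk)
        orphans <<- c(orphans, g[!known])
        r <- rk[g[known]]
        if (length(r) >= 2L) {
          gaps <- abs(diff(sort(unname(r)))) - 1L
          if (any(gaps > max_gaps)) {
            b$valid <- FALSE
            b$invalid_reason <- sprintf("anchor gap exceeds %d", max_gaps)
          }
        }
      }
    }
    b
  })
  if (length(orphans))
    warning("anchors reference ", length(unique(orphans)),
            " gene(s) absent from the annotation (orphans): ",
            paste(utils::head(unique(orphans), 3L), collapse = ", "),
            if (length(unique(orphans)) > 3L) ", ..." else "")
  out
}

#' Summary table of a block list
#' @param blocks list of `collinear_block`.
#' @return data.frame with one row per block.
#' @export
blocks_table <- function(blocks) {
  do.call(rbind, lapply(blocks, function(b)
    data.frame(block_id = b$block_id, species_a = b$species_a,
               species_b = b$species_b, n_anchors = nrow(b$anchors),
               mean_ks = b$mean_ks, epoch = b$epoch, valid = b$valid)))
}
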