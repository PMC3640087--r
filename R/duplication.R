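## Duplication-mode classification and WGD/WGT epoch assignment.

#' Classify the duplication mode of every annotated gene
#'
#' Modes follow the usual duplicate-gene taxonomy with the priority
#' `WGD_SEGMENTAL > TANDEM > PROXIMAL > DISPERSED > SINGLETON`:
#' a gene anchored in any *valid* intra-species collinear block is
#' segmental/WGD; otherwise a homolog partner at adjacent gene rank on the
#' same chromosome makes it tandem (chains of consecutive homologs are all
#' tandem); a partner within `proximal_max_rank_gap` ranks makes it
#' proximal; any remaining partner makes it dispersed; a gene with no
#' partner at all is a singleton.
#'
#' @param annotation a [genome_annotation()].
#' @param pairs homolog-pair data.frame (see [read_pairs()]); every gene in
#'   it must be annotated.
#' @param blocks list of `collinear_block` with validity filled in by
#'   [validate_blocks()] (invalid blocks are ignored as evidence).
#' @param proximal_max_rank_gap maximum rank difference for a proximal
#'   call (default 10).
#' @return data.frame with columns `gene_id`, `mode`, `evidence`.
#' @export
classify_duplication_modes <- function(annotation, pairs, blocks = list(),
                                       proximal_max_rank_gap = 10) {
  g <- annotation$genes
  known <- g$gene_id
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), known)
  if (length(missing))
    stop("pair gene(s) missing from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "))

  chr <- stats::setNames(g$chromosome, g$gene_id)
  rk <- stats::setNames(g$rank, g$gene_id)

  ## partners per gene (both directions)
  part <- split(c(pairs$gene_b, pairs$gene_a), c(pairs$gene_a, pairs$gene_b))

  ## anchors of valid intra-species blocks, with block ids as evidence
  anchor_ev <- list()
  for (b in blocks) {
    if (!isTRUE(b$valid)) next
    if (!identical(b$species_a, b$species_b)) next
    for (gid in unique(c(b$anchors$gene_a, b$anchors$gene_b)))
      anchor_ev[[gid]] <- c(anchor_ev[[gid]], b$block_id)
  }

  mode <- character(nrow(g))
  evidence <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    gid <- known[i]
    p <- unique(part[[gid]])
    p <- p[p %in% known]
    if (gid %in% names(anchor_ev)) {
      mode[i] <- "WGD_SEGMENTAL"
      evidence[i] <- paste(unique(anchor_ev[[gid]]), collapse = ";")
    } else if (length(p) == 0L) {
      mode[i] <- "SINGLETON"
    } else {
      same <- p[chr[p] == chr[gid]]
      gap <- abs(rk[same] - rk[gid])
      if (any(gap == 1)) {
        mode[i] <- "TANDEM"
        evidence[i] <- paste(same[gap == 1], collapse = ";")
      } else if (any(gap > 1 & gap <= proximal_max_rank_gap)) {
        mode[i] <- "PROXIMAL"
        evidence[i] <- paste(same[gap > 1 & gap <= proximal_max_rank_gap],
                             collapse = ";")
      } else {
        mode[i] <- "DISPERSED"
        evidence[i] <- paste(p, collapse = ";")
      }
    }
  }
  data.frame(gene_id = known, mode = mode, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Fill in the mean Ks of a collinear block
#'
#' The block mean is the arithmetic mean over anchors with a finite Ks.
#' Per-anchor Ks values come from the block's own `ks` column or, when
#' supplied, from `ks_by_pair` (named `"geneA|geneB"`), which takes
#' precedence.
#'
#' @param block a `collinear_block`.
#' @param ks_by_pair optional named numeric vector of pair Ks values.
#' @return The block with `mean_ks` set (`NA` when no anchor has a finite
#'   Ks, in which case the epoch is left unassigned).
#' @export
block_mean_ks <- function(block, ks_by_pair = NULL) {
  ks <- block$anchors$ks
  if (!is.null(ks_by_pair)) {
    key1 <- paste(block$anchors$gene_a, block$anchors$gene_b, sep = "|")
    key2 <- paste(block$anchors$gene_b, block$anchors$gene_a, sep = "|")
    v <- ks_by_pair[key1]
    v[is.na(v)] <- ks_by_pair[key2][is.na(v)]
    ks[!is.na(v)] <- v[!is.na(v)]
  }
  ks <- ks[is.finite(ks)]
  block$mean_ks <- if (length(ks)) mean(ks) else NA_real_
  block
}

#' Date a block to its duplication epoch from the mean Ks
#'
#' Ks below the young threshold dates the divergence after the recent
#' (Glycine) WGD; Ks above the old threshold after the ancient gamma WGT;
#' values in the closed middle interval after the legume WGD.  The
#' boundary values 0.3 and 1.5 fall in the middle interval.
#'
#' @param mean_ks numeric vector of finite, non-negative block mean Ks.
#' @param thresholds `c(young, old)` Ks cut points (default `c(0.3, 1.5)`).
#' @return Character vector of epoch labels.
#' @export
assign_epoch <- function(mean_ks, thresholds = c(0.3, 1.5)) {
  if (any(!is.finite(mean_ks)) || any(mean_ks < 0))
    stop("mean_ks must be finite and non-negative")
  ifelse(mean_ks < thresholds[1L], "GLYCINE_WGD",
         ifelse(mean_ks <= thresholds[2L], "LEGUME_WGD", "GAMMA_WGT"))
}

#' Compute mean Ks and epoch for a list of blocks
#'
#' Convenience wrapper applying [block_mean_ks()] and [assign_epoch()] to
#' every valid block; invalid blocks keep `NA` epochs.
#'
#' @inheritParams block_mean_ks
#' @inheritParams assign_epoch
#' @param blocks list of `collinear_block`.
#' @return The updated block list.
#' @export
date_blocks <- function(blocks, ks_by_pair = NULL, thresholds = c(0.3, 1.5)) {
  lapply(blocks, function(b) {
    b <- block_mean_ks(b, ks_by_pair)
    if (is.finite(b$mean_ks) && !isFALSE(b$valid))
      b$epoch <- assign_epoch(b$mean_ks, thresholds)
    b
  })
}

#' Earliest traceable origin of a subfamily
#'
#' The earliest epoch to which any evidence for the subfamily traces:
#' epochs of valid intra-species blocks anchoring a member, plus
#' `PRE_GAMMA` when a member is anchored in an inter-species block with an
#' outgroup genome that shares only the oldest event (e.g. grape, which
#' shares only the gamma WGT).  A subfamily with no block evidence is
#' `"UNTRACEABLE"`.
#'
#' @param annotation a [genome_annotation()].
#' @param subfamily subfamily label present in the annotation.
#' @param blocks intra-species `collinear_block` list with epochs (see
#'   [date_blocks()]).
#' @param interspecies_blocks inter-species block list (validated).
#' @param outgroup_species genome label(s) treated as sharing only the
#'   oldest event.
#' @return One epoch label, `"PRE_GAMMA"`, or `"UNTRACEABLE"`.
#' @export
infer_subfamily_origin <- function(annotation, subfamily, blocks = list(),
                                   interspecies_blocks = list(),
                                   outgroup_species = "Vvinifera") {
  members <- annotation$genes$gene_id[annotation$genes$subfamily == subfamily]
  if (length(members) == 0L) stop("subfamily has no members: ", subfamily)
  ord <- stats::setNames(seq_along(EPOCH_LEVELS), EPOCH_LEVELS)
  ev <- integer()
  for (b in blocks) {
    if (!isTRUE(b$valid) || is.na(b$epoch)) next
    if (any(c(b$anchors$gene_a, b$anchors$gene_b) %in% members))
      ev <- c(ev, ord[[b$epoch]])
  }
  for (b in interspecies_blocks) {
    if (!isTRUE(b$valid)) next
    if (!(b$species_a %in% outgroup_species || b$species_b %in% outgroup_species)) next
    if (any(c(b$anchors$gene_a, b$anchors$gene_b) %in% members))
      ev <- c(ev, ord[["PRE_GAMMA"]])
  }
  if (length(ev) == 0L) return("UNTRACEABLE")
  EPOCH_LEVELS[max(ev)]
}
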