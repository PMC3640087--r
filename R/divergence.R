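## paralog_divergence: per-tissue expression-divergence bins of paralog
## pairs and duplicate-gene fate calls.

#' Divergence bin of a paralog pair in one tissue
#'
#' With expression values `a`, `b` (relative expression in one tissue) and
#' detection threshold `tau`: both at or below `tau` is
#' `BOTH_UNDETECTED`; exactly one at or below `tau` is `ONE_UNDETECTED`;
#' otherwise the fold ratio `r = max(a, b) / min(a, b)` falls in `LOW`
#' (`r` in `[1, 2]`), `MID` (`(2, 10]`) or `HIGH` (`> 10`).  Boundary
#' ratios 2 and 10 fall in the lower bin (left-open, right-closed).
#'
#' @param a,b numeric vectors (recycled) of non-negative expression values.
#' @param tau detection threshold (default 0).
#' @return Character vector of bins.
#' @export
pair_tissue_bin <- function(a, b, tau = 0) {
  if (any(a < 0) || any(b < 0)) stop("negative expression value")
  det_a <- a > tau
  det_b <- b > tau
  r <- pmax(a, b) / pmin(a, b)
  ifelse(!det_a & !det_b, "BOTH_UNDETECTED",
         ifelse(xor(det_a, det_b), "ONE_UNDETECTED",
                ifelse(r <= 2, "LOW", ifelse(r <= 10, "MID", "HIGH"))))
}

pair_bins_matrix <- function(pairs, relative_matrix, tau = 0) {
  m <- unclass(relative_matrix)
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(m))
  if (length(miss))
    stop("pair gene(s) missing from expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  bins <- matrix(NA_character_, nrow(pairs), ncol(m),
                 dimnames = list(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                                 colnames(m)))
  for (i in seq_len(nrow(pairs)))
    bins[i, ] <- pair_tissue_bin(m[pairs$gene_a[i], ], m[pairs$gene_b[i], ], tau)
  bins
}

#' Divergence-bin table over all pair x tissue combinations
#'
#' Counts each bin over every (pair, tissue) combination; percentages are
#' on the full denominator `n_pairs * n_tissues` (so they sum to 100%,
#' with `BOTH_UNDETECTED` as the usually unprinted remainder).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param relative_matrix genes x samples expression matrix containing all
#'   pair genes.
#' @param tau detection threshold.
#' @return Object of class `divergence_table`: list with `counts`,
#'   `percentages` (1 d.p.), `n_pairs`, `n_tissues`, and the per-pair
#'   `bins` matrix.
#' @export
divergence_table <- function(pairs, relative_matrix, tau = 0) {
  bins <- pair_bins_matrix(pairs, relative_matrix, tau)
  counts <- table(factor(bins, levels = BIN_LEVELS))
  denom <- nrow(pairs) * ncol(bins)
  structure(list(counts = stats::setNames(as.integer(counts), BIN_LEVELS),
                 percentages = round(100 * as.integer(counts) / denom, 1),
                 n_pairs = nrow(pairs), n_tissues = ncol(bins), bins = bins),
            class = "divergence_table")
}

#' @export
print.divergence_table <- function(x, ...) {
  cat(sprintf("divergence_table: %d pairs x %d tissues = %d combinations\n",
              x$n_pairs, x$n_tissues, x$n_pairs * x$n_tissues))
  for (i in seq_along(BIN_LEVELS))
    cat(sprintf("  %-16s %5d (%.1f%%)\n", BIN_LEVELS[i], x$counts[i],
                x$percentages[i]))
  invisible(x)
}

#' Classify the expression fate of paralog pairs
#'
#' Among tissues where at least one member is detected:
#' `NONFUNCTIONALIZATION` when the `ONE_UNDETECTED` fraction is at least
#' `silence_frac` and the silenced member is the same gene in at least
#' `silence_frac` of those tissues; `SUBFUNCTIONALIZATION` when both
#' members are detected somewhere and the diverged fraction (bins `MID`,
#' `HIGH` or `ONE_UNDETECTED`) is at least `div_frac` without one
#' consistently silenced member; `CONSERVED` when the `LOW` fraction
#' exceeds `1 - div_frac`; otherwise `AMBIGUOUS`.  Pairs undetected in
#' every tissue are `AMBIGUOUS`.
#'
#' @inheritParams divergence_table
#' @param silence_frac consistency threshold for nonfunctionalization
#'   (default 0.8).
#' @param div_frac divergence threshold for subfunctionalization
#'   (default 0.5).
#' @return data.frame with columns `gene_a`, `gene_b`, `fate`.
#' @export
classify_fate <- function(pairs, relative_matrix, tau = 0,
                          silence_frac = 0.8, div_frac = 0.5) {
  m <- unclass(relative_matrix)
  bins <- pair_bins_matrix(pairs, relative_matrix, tau)
  fate <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    b <- bins[i, ]
    det <- b != "BOTH_UNDETECTED"
    if (!any(det)) { fate[i] <- "AMBIGUOUS"; next }
    bd <- b[det]
    one <- bd == "ONE_UNDETECTED"
    ## which member is the silenced one in each ONE_UNDETECTED tissue
    a_vals <- m[pairs$gene_a[i], det]
    silenced_a <- one & (a_vals <= tau)
    consistent <- any(one) &&
      (max(sum(silenced_a), sum(one) - sum(silenced_a)) / sum(one)) >= silence_frac
    a_det_somewhere <- any(m[pairs$gene_a[i], ] > tau)
    b_det_somewhere <- any(m[pairs$gene_b[i], ] > tau)
    div_frac_obs <- mean(bd %in% c("MID", "HIGH", "ONE_UNDETECTED"))
    if (mean(one) >= silence_frac && consistent) {
      fate[i] <- "NONFUNCTIONALIZATION"
    } else if (a_det_somewhere && b_det_somewhere && div_frac_obs >= div_frac) {
      fate[i] <- "SUBFUNCTIONALIZATION"
    } else if (mean(bd == "LOW") > 1 - div_frac) {
      fate[i] <- "CONSERVED"
    } else {
      fate[i] <- "AMBIGUOUS"
    }
  }
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, fate = fate,
             stringsAsFactors = FALSE)
}

#' Triangle-style matrix export for divergence heatmaps
#'
#' For each pair, the upper row carries the first member's expression and
#' the lower row the second member's, tissue by tissue, the layout used
#' for paired-expression heatmaps.
#'
#' @inheritParams divergence_table
#' @return Numeric matrix with `2 * n_pairs` rows.
#' @export
pair_triangle_matrix <- function(pairs, relative_matrix) {
  m <- unclass(relative_matrix)
  rows <- as.vector(rbind(pairs$gene_a, pairs$gene_b))
  out <- m[rows, , drop = FALSE]
  rownames(out) <- as.vector(rbind(paste0(pairs$gene_a, "|upper"),
                                   paste0(pairs$gene_b, "|lower")))
  out
}
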