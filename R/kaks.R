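## Ka/Ks by the Nei-Gojobori (1986) counting method with Jukes-Cantor
## multiple-hit correction, for pre-aligned coding sequences.
##
## Conventions (shared with the documentation): single-nucleotide changes
## that create a stop codon count as nonsynonymous when counting sites;
## when counting differences, all mutational pathways between two codons
## are averaged, including pathways passing through stop codons (a step
## between two stop codons is a synonymous step since the "amino acids"
## agree).

BASES <- c("T", "C", "A", "G")

## Standard genetic code, first base slowest, TCAG order.
codon_table <- local({
  aa <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1L]]
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)   # b1 slowest
  stats::setNames(aa, paste0(g$b1, g$b2, g$b3))
})

## Per-codon synonymous site count (sum over the 3 positions of the
## fraction of the 3 possible changes that are synonymous).
syn_sites_table <- local({
  codons <- names(codon_table)
  s <- stats::setNames(numeric(64), codons)
  for (cd in codons) {
    if (codon_table[[cd]] == "*") { s[[cd]] <- NA_real_; next }
    n_syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (codon_table[[mut]] != "*" && codon_table[[mut]] == codon_table[[cd]])
          n_syn <- n_syn + 1
      }
    }
    s[[cd]] <- n_syn / 3
  }
  s
})

## Average synonymous/nonsynonymous differences between two codons over
## all mutational pathways.
codon_path_diffs <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(d)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(d) else
    if (k == 2L) list(d, rev(d)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(p) d[p])
  sd <- nd <- 0
  for (p in perms) {
    x <- c1
    for (pos in p) {
      y <- x
      substr(y, pos, pos) <- substr(c2, pos, pos)
      if (codon_table[[x]] == codon_table[[y]]) sd <- sd + 1 else nd <- nd + 1
      x <- y
    }
  }
  c(sd = sd / length(perms), nd = nd / length(perms))
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NaN, -0.75 * log(1 - 4 * p / 3))
}

#' Ka and Ks between two pre-aligned coding sequences (NG86)
#'
#' Nei-Gojobori (1986) site and difference counting with Jukes-Cantor
#' correction.  Synonymous and nonsynonymous site counts are averaged over
#' the two sequences; differences per codon are averaged over all
#' mutational pathways.  Codons containing a non-ACGT character in either
#' sequence are skipped with a warning.
#'
#' @param cds_a,cds_b character strings of equal length, a multiple of 3,
#'   in frame, without internal stop codons.
#' @return Named numeric vector `c(ka, ks)`; `NaN` when the corrected
#'   proportion is saturated (p >= 3/4) or no synonymous sites remain.
#' @export
estimate_ks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(gsub("U", "T", cds_a))
  cds_b <- toupper(gsub("U", "T", cds_b))
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences differ in length (must be pre-aligned)")
  if (nchar(cds_a) %% 3 != 0) stop("sequence length is not a multiple of 3")
  n_codon <- nchar(cds_a) %/% 3
  if (n_codon == 0L) stop("empty sequence")
  ca <- substring(cds_a, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  cb <- substring(cds_b, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))

  ok_a <- ca %in% names(codon_table)
  ok_b <- cb %in% names(codon_table)
  skip <- !(ok_a & ok_b)
  if (any(skip))
    warning("skipping ", sum(skip), " codon(s) with ambiguous nucleotides")
  ca <- ca[!skip]; cb <- cb[!skip]
  if (length(ca) == 0L) stop("no unambiguous codons")
  if (any(codon_table[ca] == "*") || any(codon_table[cb] == "*"))
    stop("internal stop codon")

  S <- (sum(syn_sites_table[ca]) + sum(syn_sites_table[cb])) / 2
  N <- 3 * length(ca) - S
  sd <- nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    dd <- codon_path_diffs(ca[i], cb[i])
    sd <- sd + dd[["sd"]]
    nd <- nd + dd[["nd"]]
  }
  ks <- if (S > 0) jukes_cantor(sd / S) else NaN
  ka <- if (N > 0) jukes_cantor(nd / N) else NaN
  c(ka = ka, ks = ks)
}
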