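# Independent brute-force oracles.  These deliberately re-derive each
# quantity by naive enumeration, sharing no code with the package paths
# they check.

# --- nearest feature: scan every feature, compute the gap arithmetic ----
oracle_nearest <- function(gene, features) {
  best <- NULL
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$chromosome != gene$chromosome) next
    d <- if (f$end < gene$start) gene$start - f$end - 1
    else if (gene$end < f$start) f$start - gene$end - 1
    else 0
    if (is.null(best) || d < best$distance ||
        (d == best$distance && f$start < best$feature$start))
      best <- list(feature = f, distance = d)
  }
  best
}

# --- duplication modes: evaluate every predicate per gene --------------
oracle_modes <- function(annotation, pairs, blocks, proximal_gap = 10) {
  g <- annotation$genes
  ord <- g[order(g$chromosome, g$start, g$gene_id), ]
  rank <- integer(0)
  for (chr in unique(ord$chromosome)) {
    ids <- ord$gene_id[ord$chromosome == chr]
    rank[ids] <- seq_along(ids) - 1L
  }
  anchor_set <- character(0)
  for (b in blocks)
    if (isTRUE(b$valid) && identical(b$species_a, b$species_b))
      anchor_set <- c(anchor_set, b$anchors$gene_a, b$anchors$gene_b)
  chr_of <- setNames(g$chromosome, g$gene_id)
  out <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    partners <- unique(c(pairs$gene_b[pairs$gene_a == gid],
                         pairs$gene_a[pairs$gene_b == gid]))
    is_wgd <- gid %in% anchor_set
    is_tandem <- is_prox <- FALSE
    for (p in partners) {
      if (chr_of[p] != chr_of[gid]) next
      gap <- abs(rank[p] - rank[gid])
      if (gap == 1) is_tandem <- TRUE
      else if (gap > 1 && gap <= proximal_gap) is_prox <- TRUE
    }
    out[i] <- if (is_wgd) "WGD_SEGMENTAL"
    else if (is_tandem) "TANDEM"
    else if (is_prox) "PROXIMAL"
    else if (length(partners)) "DISPERSED"
    else "SINGLETON"
  }
  setNames(out, g$gene_id)
}

# --- window association: all gene x locus pairs ------------------------
oracle_associations <- function(annotation, loci, window_bp) {
  g <- annotation$genes
  L <- loci$loci
  hits <- list()
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(L))) {
    if (g$chromosome[i] != L$chromosome[j]) next
    pos <- L$position[j]
    d <- if (pos < g$start[i]) g$start[i] - pos - 1
    else if (pos > g$end[i]) pos - g$end[i] - 1
    else 0
    if (d <= window_bp)
      hits[[length(hits) + 1L]] <- data.frame(gene_id = g$gene_id[i],
                                              locus_id = L$locus_id[j],
                                              distance = d)
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(gene_id = character(), locus_id = character(),
                  distance = numeric())
}

# --- NG86 Ka/Ks via genetic-code enumeration ---------------------------
# Site counting enumerates all 9 single-nucleotide mutations per codon
# against the standard genetic code (Biostrings); differences are averaged
# over pathways by recursion.
oracle_translate <- function(cd) unname(Biostrings::GENETIC_CODE[cd])

oracle_syn_sites <- function(cd) {
  n <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
    m <- cd
    substr(m, pos, pos) <- b
    if (oracle_translate(m) != "*" && oracle_translate(m) == oracle_translate(cd))
      n <- n + 1
  }
  n / 3
}

oracle_path_diffs <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(c(sd = 0, nd = 0))
  acc <- c(sd = 0, nd = 0)
  for (pos in d) {
    y <- c1
    substr(y, pos, pos) <- substr(c2, pos, pos)
    step <- if (oracle_translate(c1) == oracle_translate(y)) c(sd = 1, nd = 0)
    else c(sd = 0, nd = 1)
    acc <- acc + step + oracle_path_diffs(y, c2)
  }
  acc / length(d)
}

oracle_ng86 <- function(cds_a, cds_b) {
  n <- nchar(cds_a) / 3
  ca <- substring(cds_a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(cds_b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
          sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * n - S
  diffs <- c(sd = 0, nd = 0)
  for (i in seq_len(n)) diffs <- diffs + oracle_path_diffs(ca[i], cb[i])
  jc <- function(p) if (p >= 0.75) NaN else -0.75 * log(1 - 4 * p / 3)
  c(ka = if (N > 0) jc(diffs[["nd"]] / N) else NaN,
    ks = if (S > 0) jc(diffs[["sd"]] / S) else NaN)
}

random_cds_pair <- function(n_codons = 20, max_changes = 4) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  cod <- sample(setdiff(all_codons, stops), n_codons, replace = TRUE)
  cod_b <- cod
  for (k in seq_len(sample(0:max_changes, 1))) {
    repeat {
      i <- sample(n_codons, 1)
      pos <- sample(3, 1)
      m <- cod_b[i]
      substr(m, pos, pos) <- sample(setdiff(bases, substr(m, pos, pos)), 1)
      if (!m %in% stops) { cod_b[i] <- m; break }
    }
  }
  list(a = paste(cod, collapse = ""), b = paste(cod_b, collapse = ""))
}

# --- UPGMA agglomeration: recompute all average-linkage distances each
# step from the original distance matrix; return the cophenetic matrix --
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) for (j in (i + 1L):length(clusters)) {
      dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
      if (is.null(best) || dist_ij < best$d) best <- list(i = i, j = j, d = dist_ij)
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]])
      coph[a, b] <- coph[b, a] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}
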