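## synthetic_data: truth-labelled fixtures with the statistical structure
## every pipeline stage assumes.  The simulated genome descends from one
## whole-genome triplication (gamma WGT) followed by two whole-genome
## duplications (legume WGD, then the recent Glycine WGD); each event's
## anchor Ks values are drawn from a disjoint uniform range so epoch
## recovery is exact by construction.

#' Simulation parameters
#'
#' Defaults mirror the study conditions the generator emulates: a family
#' of roughly 160 genes after one WGT and two WGDs, tandem/proximal/
#' dispersed duplicates at the proportions observed in large plant
#' transcription-factor families, 17 tissue samples named as in the
#' seed-development RNA-seq design, 46 designated paralog pairs, and
#' negative-binomial counts with stable reference genes.
#'
#' @param n_ancestral_genes ancestral genes before any event.
#' @param retention per-event retention probability of a gene on a *new*
#'   genome copy (`gamma_wgt`, `legume_wgd`, `glycine_wgd`).
#' @param ks_ranges per-event uniform Ks ranges; must be disjoint and
#'   ordered old > young.
#' @param n_tandem,n_proximal,n_dispersed extra single-gene duplicates
#'   inserted after the WGD history.
#' @param proximal_rank_gaps candidate rank gaps for proximal inserts.
#' @param n_loci,seed_trait_fraction,planted_within_window_fraction,window_bp
#'   QTL-map parameters.
#' @param n_pairs designated paralog pairs for the expression stage.
#' @param silenced_pair_fraction fraction of designated pairs with one
#'   member silenced in all tissues (programmed nonfunctionalization).
#' @param nb_dispersion negative-binomial size parameter.
#' @param mean_expression `c(high, low)` NB means for expressed/weak genes.
#' @param reference_gene_count stable reference genes.
#' @param rng_seed integer seed recorded in all outputs.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_ancestral_genes = 20,
                       retention = c(gamma_wgt = 0.7, legume_wgd = 0.75,
                                     glycine_wgd = 0.85),
                       ks_ranges = list(gamma_wgt = c(1.6, 2.5),
                                        legume_wgd = c(0.4, 1.4),
                                        glycine_wgd = c(0.05, 0.28)),
                       n_tandem = 19, n_proximal = 14, n_dispersed = 30,
                       proximal_rank_gaps = 2:8,
                       n_loci = 60, seed_trait_fraction = 0.5,
                       planted_within_window_fraction = 0.7, window_bp = 2e6,
                       n_pairs = 46, silenced_pair_fraction = 0.3,
                       nb_dispersion = 10,
                       mean_expression = c(high = 300, low = 5),
                       reference_gene_count = 3, rng_seed = 1L) {
  stopifnot(n_ancestral_genes >= 2,
            all(retention >= 0 & retention <= 1),
            all(names(ks_ranges) == c("gamma_wgt", "legume_wgd", "glycine_wgd")),
            seed_trait_fraction >= 0, seed_trait_fraction <= 1,
            planted_within_window_fraction >= 0,
            planted_within_window_fraction <= 1,
            silenced_pair_fraction >= 0, silenced_pair_fraction <= 1,
            window_bp > 0, nb_dispersion > 0)
  r <- do.call(rbind, ks_ranges)
  if (any(r[, 1] >= r[, 2])) stop("each ks range must be (lo, hi) with lo < hi")
  ## disjoint, ordered old (gamma) above young (glycine)
  if (!(r["gamma_wgt", 1] > r["legume_wgd", 2] &&
        r["legume_wgd", 1] > r["glycine_wgd", 2]))
    stop("ks_ranges must be pairwise disjoint and ordered gamma > legume > glycine")
  structure(as.list(environment()), class = "sim_params")
}

EVENT_EPOCH <- c(gamma_wgt = "GAMMA_WGT", legume_wgd = "LEGUME_WGD",
                 glycine_wgd = "GLYCINE_WGD")

#' Simulate a genome with a programmed duplication history
#'
#' Lays `n_ancestral_genes` in order on one ancestral chromosome and plays
#' the three events forward: each event duplicates every chromosome, and a
#' gene survives on a new copy with the event's retention probability
#' (the pre-existing copy keeps everything).  The 12 resulting chromosomes
#' yield one collinear block per chromosome pair that shares ancestral
#' genes; anchor Ks values are drawn uniformly from the range of the event
#' at which the two chromosomes diverged.  Tandem, proximal and dispersed
#' single-gene duplicates are then inserted with anchor genes of valid
#' blocks as sources (so source genes keep their segmental truth label and
#' the inserts carry the programmed mode).
#'
#' @param params a [sim_params()].
#' @return List with `annotation` ([genome_annotation()]), `pairs`
#'   (homolog-pair data.frame), `blocks` (list of `collinear_block` with
#'   per-anchor Ks), and `truth` (list with `gene_modes`, `block_events`,
#'   `params`).
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  n_anc <- params$n_ancestral_genes

  ## chromosome tree: gamma (3 copies) -> legume (x2) -> glycine (x2)
  paths <- expand.grid(y = 0:1, l = 0:1, g = 0:2)[, c("g", "l", "y")]
  presence <- matrix(FALSE, n_anc, nrow(paths))
  ## branch retention draws are shared along the tree
  keep_g <- cbind(TRUE, matrix(stats::runif(n_anc * 2) < params$retention[["gamma_wgt"]],
                               n_anc, 2))
  for (j in seq_len(nrow(paths))) {
    p <- paths[j, ]
    presence[, j] <- keep_g[, p$g + 1L]
  }
  ## legume draws: one new-copy draw per (gamma copy) branch
  keep_l <- array(stats::runif(n_anc * 3) < params$retention[["legume_wgd"]],
                  c(n_anc, 3))
  keep_y <- array(stats::runif(n_anc * 6) < params$retention[["glycine_wgd"]],
                  c(n_anc, 3, 2))
  for (j in seq_len(nrow(paths))) {
    p <- paths[j, ]
    if (p$l == 1L) presence[, j] <- presence[, j] & keep_l[, p$g + 1L]
    if (p$y == 1L) presence[, j] <- presence[, j] & keep_y[, p$g + 1L, p$l + 1L]
  }
  chroms <- sprintf("GM%02d", seq_len(nrow(paths)))

  ## per-chromosome ordered gene lists (ancestral order preserved)
  gene_id <- function(chr, anc) sprintf("%sg%03d", chr, anc)
  order_by_chr <- lapply(seq_len(nrow(paths)), function(j)
    gene_id(chroms[j], which(presence[, j])))
  names(order_by_chr) <- chroms
  anc_of <- stats::setNames(
    unlist(lapply(seq_len(nrow(paths)), function(j) which(presence[, j]))),
    unlist(order_by_chr))
  if (length(anc_of) < 2L) stop("retention produced fewer than 2 genes")

  ## divergence event of two chromosomes = earliest differing copy index
  div_event <- function(i, j) {
    if (paths$g[i] != paths$g[j]) "gamma_wgt"
    else if (paths$l[i] != paths$l[j]) "legume_wgd"
    else "glycine_wgd"
  }

  blocks <- list()
  block_events <- character()
  bi <- 0L
  for (i in seq_len(nrow(paths) - 1L)) {
    for (j in (i + 1L):nrow(paths)) {
      shared <- which(presence[, i] & presence[, j])
      if (length(shared) == 0L) next
      ev <- div_event(i, j)
      rng <- params$ks_ranges[[ev]]
      anchors <- data.frame(gene_a = gene_id(chroms[i], shared),
                            gene_b = gene_id(chroms[j], shared),
                            evalue = 1e-50,
                            ks = stats::runif(length(shared), rng[1L], rng[2L]))
      blk <- new_block(sprintf("b%03d", bi), "Gmax", "Gmax",
                       chroms[i], chroms[j], anchors)
      bi <- bi + 1L
      blocks[[length(blocks) + 1L]] <- blk
      block_events[blk$block_id] <- ev
    }
  }
  valid_truth <- vapply(blocks, function(b) nrow(b$anchors) >= 5, logical(1))
  wgd_genes <- unique(unlist(lapply(blocks[valid_truth], function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))

  ## homolog pairs: every pair of surviving copies of one ancestral gene
  pair_list <- list()
  for (a in seq_len(n_anc)) {
    copies <- gene_id(chroms[presence[a, ]], a)
    if (length(copies) >= 2L) {
      cmb <- utils::combn(copies, 2L)
      pair_list[[length(pair_list) + 1L]] <-
        data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ], evalue = 1e-50,
                   ks = NA_real_)
    }
  }
  pairs <- do.call(rbind, pair_list)

  n_copies <- table(factor(anc_of, levels = seq_len(n_anc)))
  truth_mode <- stats::setNames(
    ifelse(names(anc_of) %in% wgd_genes, "WGD_SEGMENTAL",
           ifelse(n_copies[anc_of] >= 2, "DISPERSED", "SINGLETON")),
    names(anc_of))

  ## single-gene duplicate inserts; sources are distinct valid-block
  ## anchors so their own truth stays WGD_SEGMENTAL (mode priority)
  n_ins <- params$n_tandem + params$n_proximal + params$n_dispersed
  if (length(wgd_genes) < n_ins)
    stop("not enough segmental anchor genes to host ", n_ins, " inserts; ",
         "increase n_ancestral_genes or retention")
  sources <- sample(wgd_genes, n_ins)
  src_tan <- sources[seq_len(params$n_tandem)]
  src_pro <- sources[params$n_tandem + seq_len(params$n_proximal)]
  src_dis <- sources[params$n_tandem + params$n_proximal +
                       seq_len(params$n_dispersed)]
  chr_of <- function(gid) sub("g[0-9]+.*$", "", gid)

  add_pair <- function(a, b)
    pairs <<- rbind(pairs, data.frame(gene_a = a, gene_b = b, evalue = 1e-50,
                                      ks = NA_real_))
  insert_at <- function(chr, pos, gid) {
    v <- order_by_chr[[chr]]
    pos <- max(1L, min(pos, length(v) + 1L))
    order_by_chr[[chr]] <<- append(v, gid, after = pos - 1L)
  }

  ## dispersed first, then proximal, then tandem, so the adjacency and the
  ## programmed rank gaps of later inserts are not broken by earlier ones
  for (s in src_dis) {
    gid <- paste0(s, "_d")
    chr <- sample(setdiff(chroms, chr_of(s)), 1L)
    insert_at(chr, sample(length(order_by_chr[[chr]]) + 1L, 1L), gid)
    add_pair(gid, s)
    truth_mode[gid] <- "DISPERSED"
    anc_of[gid] <- anc_of[[s]]
  }
  for (s in src_pro) {
    gid <- paste0(s, "_p")
    chr <- chr_of(s)
    gap <- sample(params$proximal_rank_gaps, 1L)
    idx <- match(s, order_by_chr[[chr]])
    pos <- if (idx + gap <= length(order_by_chr[[chr]]) + 1L) idx + gap
           else idx - gap + 1L
    insert_at(chr, pos, gid)
    add_pair(gid, s)
    truth_mode[gid] <- "PROXIMAL"
    anc_of[gid] <- anc_of[[s]]
  }
  for (s in src_tan) {
    gid <- paste0(s, "_t")
    chr <- chr_of(s)
    insert_at(chr, match(s, order_by_chr[[chr]]) + 1L, gid)
    add_pair(gid, s)
    truth_mode[gid] <- "TANDEM"
    anc_of[gid] <- anc_of[[s]]
  }

  ## subfamily labels: per ancestral gene, inherited by every copy
  fams <- c(MIKCc = 0.50, `MIKC*` = 0.04, Malpha = 0.22, Mbeta = 0.09,
            Mgamma = 0.15)
  subfams <- c("SEP", "AG", "SQUA", "SVP", "AGL6", "AGL17", "DEF/GLO", "SOC",
               "FLC", "ABS", "AGL12", "AGL15")
  anc_family <- sample(names(fams), n_anc, replace = TRUE, prob = fams)
  anc_subfam <- ifelse(anc_family == "MIKCc",
                       sample(subfams, n_anc, replace = TRUE), "none")

  ## coordinates: genes every 10 kb, two 1.2 kb exons each
  gene_rows <- list()
  exon_rows <- list()
  for (chr in chroms) {
    v <- order_by_chr[[chr]]
    if (length(v) == 0L) next
    start <- (seq_along(v) - 1L) * 10000L + 1L
    end <- start + 2999L
    gene_rows[[chr]] <- data.frame(
      gene_id = v, chromosome = chr,
      strand = sample(c("+", "-"), length(v), replace = TRUE),
      start = start, end = end,
      family = anc_family[anc_of[v]], subfamily = anc_subfam[anc_of[v]])
    exon_rows[[chr]] <- data.frame(
      gene_id = rep(v, each = 2L),
      start = as.vector(rbind(start, start + 1800L)),
      end = as.vector(rbind(start + 1199L, end)))
  }
  genes <- do.call(rbind, gene_rows)
  chrom_len <- stats::setNames(
    vapply(chroms, function(chr) (length(order_by_chr[[chr]]) + 5) * 10000,
           numeric(1)), chroms)
  chrom_len["GM00"] <- 1.2e7   # gene-free chromosome for off-target markers
  annotation <- genome_annotation(genes, do.call(rbind, exon_rows), chrom_len)

  list(annotation = annotation, pairs = pairs, blocks = blocks,
       truth = list(
         gene_modes = data.frame(gene_id = names(truth_mode),
                                 mode = unname(truth_mode)),
         block_events = data.frame(block_id = names(block_events),
                                   event = unname(block_events),
                                   epoch = unname(EVENT_EPOCH[block_events]),
                                   valid = valid_truth),
         ancestor = data.frame(gene_id = names(anc_of),
                               ancestral_gene = unname(anc_of)),
         params = unclass(params)))
}

#' Simulate a marker/QTL map with planted gene associations
#'
#' A fraction of loci is planted at a uniform distance in `[0, window_bp)`
#' from a random gene boundary (so the window stage must recover them);
#' the rest are placed on a gene-free chromosome (`GM00`) beyond the reach
#' of any gene.  Each locus carries 1-3 QTLs; a locus is seed-relative
#' with probability `seed_trait_fraction`, in which case at least one of
#' its traits is drawn from the seed-trait pool.
#'
#' @param genome output of [simulate_genome()].
#' @param params a [sim_params()].
#' @return List with `loci` (a `qtl_loci`), `table` (the raw marker/QTL
#'   data.frame), and `truth` (data.frame of planted `marker_id`,
#'   `gene_id`, `distance`, `within`, `seed`).
#' @export
simulate_qtl_map <- function(genome, params = sim_params()) {
  set.seed(params$rng_seed + 1L)
  g <- genome$annotation$genes
  if (nrow(g) == 0L) stop("empty genome")
  seed_pool <- c("Seed protein", "Seed oil", "Seed weight", "Seed length",
                 "Pod maturity date", "R3 beginning pod", "R8 full maturity",
                 "Seed yield")
  nonseed_pool <- c("Plant height", "Root morphology", "Leaf area",
                    "Flower color", "Lodging", "Stem diameter")
  n_within <- round(params$planted_within_window_fraction * params$n_loci)
  rows <- list()
  truth <- list()
  for (i in seq_len(params$n_loci)) {
    within <- i <= n_within
    if (within) {
      gi <- g[sample(nrow(g), 1L), ]
      d <- floor(stats::runif(1L, 0, params$window_bp))
      pos <- if (stats::runif(1L) < 0.5 && gi$start - 1L - d >= 1) {
        gi$start - 1L - d            # d bases strictly between marker and gene
      } else gi$end + 1L + d
      chr <- gi$chromosome
    } else {
      chr <- "GM00"
      pos <- round(stats::runif(1L, 1, 1e7))
      gi <- NULL
      d <- NA_real_
    }
    seed <- stats::runif(1L) < params$seed_trait_fraction
    n_qtl <- sample(1:3, 1L)
    traits <- if (seed)
      c(sample(seed_pool, 1L),
        sample(c(seed_pool, nonseed_pool), n_qtl - 1L, replace = TRUE))
    else sample(nonseed_pool, n_qtl, replace = TRUE)
    marker <- sprintf("Satt%03d", i)
    rows[[i]] <- data.frame(marker_id = marker, chromosome = chr,
                            position = pos,
                            qtl_id = sprintf("cq%03d_%d", i, seq_len(n_qtl)),
                            trait = traits)
    truth[[i]] <- data.frame(marker_id = marker,
                             gene_id = if (within) gi$gene_id else NA_character_,
                             distance = d, within = within, seed = seed)
  }
  tab <- do.call(rbind, rows)
  list(loci = qtl_loci(tab), table = tab, truth = do.call(rbind, truth))
}

#' Simulate a 17-tissue count matrix with programmed expression fates
#'
#' Designated paralog pairs are drawn from the genome's homolog pairs and
#' assigned programmed fates: a `silenced_pair_fraction` of them are
#' nonfunctionalized (one member's counts forced to zero in every tissue,
#' the other broadly expressed); the remainder split evenly between
#' subfunctionalized (members expressed in complementary seed/non-seed
#' tissue domains) and conserved (both members broadly expressed at equal
#' means).  Remaining genes draw a tissue-profile class (seed-biased,
#' non-seed-biased, broad, silent) at proportions mirroring genome-wide
#' family surveys.  Counts are negative binomial; reference genes have
#' equal means in all samples and counts floored at 1 (constitutive
#' expression, so reference RPKM is positive everywhere).
#'
#' @param genome output of [simulate_genome()].
#' @param params a [sim_params()].
#' @return List with `counts` (a [count_matrix()]), `pairs` (designated
#'   pair data.frame), `reference_genes`, and `truth` (per-gene `class`,
#'   per-pair `fate` and `silenced_member`).
#' @export
simulate_counts <- function(genome, params = sim_params()) {
  set.seed(params$rng_seed + 2L)
  tissues <- tissue_labels()
  seed_s <- seed_tissue_labels()
  genes <- genome$annotation$genes$gene_id
  n <- length(genes)
  hi <- params$mean_expression[["high"]]

  ## designated pairs: disjoint genes, sampled from the homolog pairs
  cand <- genome$pairs[sample(nrow(genome$pairs)), ]
  used <- character()
  sel <- integer()
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= params$n_pairs) break
    if (cand$gene_a[i] %in% used || cand$gene_b[i] %in% used) next
    sel <- c(sel, i)
    used <- c(used, cand$gene_a[i], cand$gene_b[i])
  }
  dpairs <- cand[sel, c("gene_a", "gene_b")]
  rownames(dpairs) <- NULL
  n_nonf <- round(params$silenced_pair_fraction * nrow(dpairs))
  n_rest <- nrow(dpairs) - n_nonf
  fate <- sample(c(rep("NONFUNCTIONALIZATION", n_nonf),
                   rep("SUBFUNCTIONALIZATION", ceiling(n_rest / 2)),
                   rep("CONSERVED", floor(n_rest / 2))))

  ## per-gene per-tissue NB means
  mu <- matrix(0, n, length(tissues), dimnames = list(genes, tissues))
  cls <- stats::setNames(rep(NA_character_, n), genes)
  in_seed <- tissues %in% seed_s
  silenced <- stats::setNames(rep(NA_character_, nrow(dpairs)),
                              paste(dpairs$gene_a, dpairs$gene_b, sep = "|"))
  for (i in seq_len(nrow(dpairs))) {
    a <- dpairs$gene_a[i]; b <- dpairs$gene_b[i]
    if (fate[i] == "NONFUNCTIONALIZATION") {
      mu[a, ] <- hi
      mu[b, ] <- 0
      silenced[i] <- b
      cls[a] <- "broad"; cls[b] <- "silent"
    } else if (fate[i] == "SUBFUNCTIONALIZATION") {
      ## complementary expression domains with large fold ratios, both
      ## members still detectable in most tissues
      lo <- params$mean_expression[["low"]]
      mu[a, in_seed] <- hi; mu[a, !in_seed] <- lo
      mu[b, in_seed] <- lo; mu[b, !in_seed] <- hi
      cls[a] <- "seed_shifted"; cls[b] <- "nonseed_shifted"
    } else {
      mu[a, ] <- hi
      mu[b, ] <- hi
      cls[a] <- cls[b] <- "broad"
    }
  }
  free <- genes[is.na(cls)]
  ## proportions mirror observed family-wide tissue-bias fractions
  cls[free] <- sample(c("seed_biased", "nonseed_biased", "broad", "silent"),
                      length(free), replace = TRUE,
                      prob = c(0.18, 0.06, 0.61, 0.15))
  mu[free[cls[free] == "seed_biased"], in_seed] <- hi
  mu[free[cls[free] == "nonseed_biased"], !in_seed] <- hi
  mu[free[cls[free] == "broad"], ] <- hi

  refs <- sample(free[cls[free] == "broad"],
                 min(params$reference_gene_count,
                     sum(cls[free] == "broad")))
  mu[refs, ] <- 500

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = params$nb_dispersion),
                   n, length(tissues), dimnames = dimnames(mu))
  counts[mu == 0] <- 0L
  counts[refs, ] <- pmax(counts[refs, ], 1L)   # constitutive reference genes

  lib <- colSums(counts) + 1e7
  exon_len <- stats::setNames(genome$annotation$genes$exon_total_length, genes)
  cm <- count_matrix(counts, lib, exon_len)
  list(counts = cm, pairs = dpairs, reference_genes = refs,
       truth = list(gene_class = data.frame(gene_id = genes,
                                            class = unname(cls[genes])),
                    pair_fates = data.frame(dpairs, fate = fate,
                                            silenced_member = unname(silenced)),
                    reference_genes = refs))
}

#' Simulate a pre-aligned CDS pair with synonymous-only divergence
#'
#' Generates a random stop-free coding sequence and applies the requested
#' number of synonymous single-nucleotide substitutions (at codon
#' positions where one exists), so the pair has Ka = 0 by construction.
#'
#' @param n_codons sequence length in codons.
#' @param n_syn synonymous substitutions to apply (at distinct codons).
#' @param rng_seed seed.
#' @return List with `cds_a`, `cds_b`, `n_applied`.
#' @export
simulate_cds_pair <- function(n_codons = 100, n_syn = 5, rng_seed = 1L) {
  set.seed(rng_seed)
  non_stop <- names(codon_table)[codon_table != "*"]
  cod <- sample(non_stop, n_codons, replace = TRUE)
  ## codons with at least one synonymous single-nt neighbour
  syn_neighbours <- function(cd) {
    out <- character()
    for (pos in 1:3) for (b in setdiff(BASES, substr(cd, pos, pos))) {
      m <- cd
      substr(m, pos, pos) <- b
      if (codon_table[[m]] != "*" && codon_table[[m]] == codon_table[[cd]])
        out <- c(out, m)
    }
    out
  }
  mutable <- which(vapply(cod, function(cd) length(syn_neighbours(cd)) > 0,
                          logical(1)))
  take <- sample(mutable, min(n_syn, length(mutable)))
  cod_b <- cod
  for (i in take) cod_b[i] <- sample(syn_neighbours(cod[i]), 1L)
  list(cds_a = paste(cod, collapse = ""), cds_b = paste(cod_b, collapse = ""),
       n_applied = length(take))
}

#' Write a complete fixture set to disk
#'
#' Emits the formats the pipeline reads: `genome.gff3`, `pairs.tsv`,
#' `blocks.collinearity` (MCScanX dialect), `qtl.tsv`, `counts.tsv`,
#' `library_sizes.tsv`, `truth.json` and `manifest.json` (seed and
#' parameters).
#'
#' @param dir output directory.
#' @param genome,qtl,expr outputs of the three simulators.
#' @param params the [sim_params()] used.
#' @param force overwrite a non-empty directory.
#' @return Invisibly, the manifest as a named list.
#' @export
write_fixture_set <- function(dir, genome, qtl, expr, params = sim_params(),
                              force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory is not empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genome = "genome.gff3", pairs = "pairs.tsv",
             blocks = "blocks.collinearity", qtl = "qtl.tsv",
             counts = "counts.tsv", library_sizes = "library_sizes.tsv",
             truth = "truth.json", manifest = "manifest.json")
  p <- function(f) file.path(dir, f)
  write_annotation(genome$annotation, p(files["genome"]), "gff3")
  utils::write.table(genome$pairs, p(files["pairs"]), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_collinearity(genome$blocks, p(files["blocks"]))
  utils::write.table(qtl$table, p(files["qtl"]), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- expr$counts
  utils::write.table(data.frame(gene_id = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     p(files["counts"]), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(cm$library_sizes),
                                library_size = cm$library_sizes),
                     p(files["library_sizes"]), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(gene_modes = genome$truth$gene_modes,
                block_events = genome$truth$block_events,
                qtl = qtl$truth,
                gene_class = expr$truth$gene_class,
                pair_fates = expr$truth$pair_fates,
                reference_genes = expr$truth$reference_genes,
                designated_pairs = expr$pairs)
  jsonlite::write_json(truth, p(files["truth"]), dataframe = "columns",
                       na = "null")
  manifest <- list(rng_seed = params$rng_seed, params = unclass(params),
                   files = unname(files))
  jsonlite::write_json(manifest, p(files["manifest"]), auto_unbox = TRUE)
  invisible(manifest)
}
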