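test_that("MCScanX collinearity parsing keeps short blocks, flagged invalid", {
  path <- write_toy_collinearity(withr::local_tempfile(fileext = ".collinearity"))
  blocks <- read_collinearity(path)
  expect_length(blocks, 2L)
  expect_equal(nrow(blocks[[1]]$anchors), 6L)
  expect_equal(blocks[[1]]$anchors$gene_a[1], "a1")
  blocks <- validate_blocks(blocks, annotation = NULL)
  expect_true(blocks[[1]]$valid)
  expect_false(blocks[[2]]$valid)           # 4 anchors < minimum of 5
  expect_match(blocks[[2]]$invalid_reason, "fewer than 5")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_equal(read_collinearity(empty, "mcscanx"), list())
})

test_that("collinearity round-trips through the MCScanX dialect with Ks", {
  p <- sim_params(n_ancestral_genes = 6, n_tandem = 1, n_proximal = 1,
                  n_dispersed = 1, rng_seed = 3L)
  g <- simulate_genome(p)
  path <- withr::local_tempfile(fileext = ".collinearity")
  write_collinearity(g$blocks, path)
  back <- read_collinearity(path)
  expect_length(back, length(g$blocks))
  expect_equal(back[[1]]$anchors$gene_a, g$blocks[[1]]$anchors$gene_a)
  expect_equal(back[[1]]$anchors$ks, g$blocks[[1]]$anchors$ks,
               tolerance = 1e-8)
})

test_that("mode classification follows the rank rules and priority", {
  ## g2..g3 consecutive on GM10 (ranks 1,2): tandem both ways
  ann <- toy_annotation()
  pairs <- data.frame(gene_a = "g02", gene_b = "g03", evalue = 0, ks = NA)
  calls <- classify_duplication_modes(ann, pairs)
  expect_equal(calls$mode[calls$gene_id %in% c("g02", "g03")],
               c("TANDEM", "TANDEM"))

  ## ranks 0 and 5 on GM10: gap 5 <= 10 -> proximal
  pairs2 <- data.frame(gene_a = "g01", gene_b = "g06", evalue = 0, ks = NA)
  calls2 <- classify_duplication_modes(ann, pairs2)
  expect_equal(calls2$mode[calls2$gene_id == "g01"], "PROXIMAL")

  ## different chromosomes, no block -> dispersed; unpaired -> singleton
  pairs3 <- data.frame(gene_a = "g01", gene_b = "g07", evalue = 0, ks = NA)
  calls3 <- classify_duplication_modes(ann, pairs3)
  expect_equal(calls3$mode[calls3$gene_id == "g01"], "DISPERSED")
  expect_equal(calls3$mode[calls3$gene_id == "g05"], "SINGLETON")

  ## a valid block anchor that also has an adjacent homolog: WGD wins
  anchors <- data.frame(gene_a = sprintf("g%02d", 1:5),
                        gene_b = sprintf("g%02d", c(7:10, 6)),
                        evalue = 0, ks = 0.2)
  blk <- validate_blocks(list(famfates:::new_block("b1", "genome", "genome",
                                                   "GM10", "GM02", anchors)),
                         ann)
  calls4 <- classify_duplication_modes(
    ann, data.frame(gene_a = "g02", gene_b = "g03", evalue = 0, ks = NA), blk)
  expect_equal(calls4$mode[calls4$gene_id == "g02"], "WGD_SEGMENTAL")
  expect_equal(calls4$mode[calls4$gene_id == "g03"], "WGD_SEGMENTAL")

  expect_error(
    classify_duplication_modes(ann, data.frame(gene_a = "g01",
                                               gene_b = "nope", evalue = 0)),
    "nope")
})

test_that("proximal calls respect the configurable rank-gap limit", {
  ann <- toy_annotation()
  pairs <- data.frame(gene_a = "g01", gene_b = "g06", evalue = 0, ks = NA)
  calls <- classify_duplication_modes(ann, pairs, proximal_max_rank_gap = 4)
  expect_equal(calls$mode[calls$gene_id == "g01"], "DISPERSED")  # gap 5 > 4
})

test_that("block mean Ks averages finite values and tolerates gaps", {
  mk <- function(ks) famfates:::new_block("b", "genome", "genome", "c1", "c2",
    data.frame(gene_a = paste0("a", seq_along(ks)),
               gene_b = paste0("b", seq_along(ks)), evalue = 0, ks = ks))
  expect_equal(block_mean_ks(mk(c(0.1, 0.2, 0.3)))$mean_ks, 0.2)
  expect_equal(block_mean_ks(mk(c(0.1, NaN, 0.3)))$mean_ks, 0.2)
  expect_true(is.na(block_mean_ks(mk(c(NaN, NA)))$mean_ks))
  ## explicit pair Ks takes precedence over the block column
  b <- block_mean_ks(mk(c(0.1, 0.2)),
                     ks_by_pair = c("a1|b1" = 0.5, "b2|a2" = 0.7))
  expect_equal(b$mean_ks, 0.6)
})

test_that("epoch assignment uses the 0.3/1.5 thresholds, closed middle", {
  expect_equal(assign_epoch(0.2), "GLYCINE_WGD")
  expect_equal(assign_epoch(1.0), "LEGUME_WGD")
  expect_equal(assign_epoch(2.0), "GAMMA_WGT")
  expect_equal(assign_epoch(c(0.3, 1.5)), c("LEGUME_WGD", "LEGUME_WGD"))
  expect_error(assign_epoch(-0.1), "non-negative")
  expect_error(assign_epoch(NaN), "finite")
})

test_that("NG86 Ka/Ks handles identity, frame errors and is symmetric", {
  cds <- strrep("ATGGCTTTAGCT", 15)   # 60 codons, no stops
  expect_equal(unname(estimate_ks_ng86(cds, cds)), c(0, 0))
  expect_error(estimate_ks_ng86("ATG", "ATGA"), "length")
  expect_error(estimate_ks_ng86("ATGA", "ATGA"), "multiple of 3")
  expect_error(estimate_ks_ng86("ATGTAAGCT", "ATGTAAGCT"), "stop")
  expect_warning(ng <- estimate_ks_ng86("ATGNNNGCT", "ATGAAAGCT"), "ambiguous")

  set.seed(99)
  for (i in 1:10) {
    p <- random_cds_pair(12)
    expect_equal(estimate_ks_ng86(p$a, p$b), estimate_ks_ng86(p$b, p$a))
  }
})

test_that("a single synonymous change reproduces the enumeration oracle", {
  cds_a <- strrep("ATGGCTCGTAAA", 25)  # 100 codons
  cds_b <- cds_a
  substr(cds_b, 6, 6) <- "A"           # GCT -> GCA, synonymous (Ala)
  got <- estimate_ks_ng86(cds_a, cds_b)
  want <- oracle_ng86(cds_a, cds_b)
  expect_equal(got[["ks"]], want[["ks"]], tolerance = 1e-12)
  expect_equal(got[["ka"]], 0)
})

test_that("subfamily origin traces to the earliest supported epoch", {
  genes <- data.frame(gene_id = c("s1", "s2", "x1"), chromosome = "c1",
                      strand = "+", start = c(1, 100, 200),
                      end = c(50, 150, 250), exon_total_length = 50,
                      family = "MIKCc", subfamily = c("SEP", "SEP", "AG"))
  ann <- genome_annotation(genes)
  mkblk <- function(id, ks, ga = "s1", gb = "s2") {
    b <- famfates:::new_block(id, "Gmax", "Gmax", "c1", "c1",
      data.frame(gene_a = rep(ga, 5), gene_b = rep(gb, 5), evalue = 0, ks = ks))
    b$valid <- TRUE
    famfates:::date_blocks(list(b))[[1]]
  }
  ## only recent blocks: traceable just to the most recent event
  expect_equal(infer_subfamily_origin(ann, "SEP", list(mkblk("b1", 0.15))),
               "GLYCINE_WGD")
  expect_equal(infer_subfamily_origin(ann, "SEP",
                                      list(mkblk("b1", 0.2), mkblk("b2", 1.1))),
               "LEGUME_WGD")
  ## grape-collinear membership pushes the origin before the gamma WGT
  grape <- famfates:::new_block("ig1", "Gmax", "Vvinifera", "c1", "vv1",
    data.frame(gene_a = rep("s1", 5), gene_b = paste0("VvMADS", 1:5),
               evalue = 0, ks = NA))
  grape$valid <- TRUE
  expect_equal(infer_subfamily_origin(ann, "SEP", list(mkblk("b1", 0.2)),
                                      list(grape)),
               "PRE_GAMMA")
  expect_equal(infer_subfamily_origin(ann, "AG", list()), "UNTRACEABLE")
  expect_error(infer_subfamily_origin(ann, "SQUA", list()), "no members")
})

test_that("mode classification matches the predicate oracle on random genomes", {
  for (seed in 1:5) {
    p <- sim_params(n_ancestral_genes = 12, n_tandem = 4, n_proximal = 3,
                    n_dispersed = 5, rng_seed = seed)
    g <- simulate_genome(p)
    blocks <- validate_blocks(g$blocks, g$annotation)
    calls <- classify_duplication_modes(g$annotation, g$pairs, blocks)
    want <- oracle_modes(g$annotation, g$pairs, blocks)
    expect_equal(setNames(calls$mode, calls$gene_id), want[calls$gene_id])
  }
})
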