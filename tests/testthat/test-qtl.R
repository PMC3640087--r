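test_that("marker/QTL rows group into loci by (chromosome, position)", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchromosome\tposition\tqtl_id\ttrait",
               "Satt1\tGM10\t5000000\tq1\tSeed protein",
               "Satt1\tGM10\t5000000\tq2\tPlant height",
               "Satt2\tGM10\t9000000\tq3\tSeed oil"), path)
  loci <- read_qtl_table(path)
  expect_equal(nrow(loci$loci), 2L)
  expect_equal(sum(loci$qtls$locus_id == loci$loci$locus_id[1]), 2L)

  ## duplicate (qtl, trait) rows collapse; bad positions are skipped
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchromosome\tposition\tqtl_id\ttrait",
               "Satt1\tGM10\t5000000\tq1\tSeed protein",
               "Satt1\tGM10\t5000000\tq1\tSeed protein",
               "Satt3\tGM10\tnot_a_number\tq4\tYield"), path2)
  expect_warning(loci2 <- read_qtl_table(path2), "non-numeric")
  expect_equal(nrow(loci2$loci), 1L)
  expect_equal(nrow(loci2$qtls), 1L)

  expect_error(read_qtl_table({
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines("marker_id\tchromosome\tposition", p)
    p
  }), "missing column")

  expect_equal(nrow(qtl_loci(data.frame(marker_id = character(),
                                        chromosome = character(),
                                        position = numeric(),
                                        qtl_id = character(),
                                        trait = character()))$loci), 0L)
})

test_that("trait categorization matches keywords case-insensitively", {
  expect_equal(categorize_trait(c("Seed protein", "Pod maturity date",
                                  "Plant height", "seed yield")),
               c("SEED", "SEED", "NON_SEED", "SEED"))
  expect_equal(categorize_trait("Height", seed_keywords = "height"), "SEED")
})

test_that("window association uses span distance on the same chromosome", {
  genes <- data.frame(
    gene_id = c("near", "far", "other"),
    chromosome = c("GM1", "GM1", "GM2"),
    strand = "+",
    start = c(6400000, 7100000, 6400000),
    end = c(6500000, 7200000, 6500000),
    exon_total_length = 1000)
  ann <- genome_annotation(genes)
  loci <- qtl_loci(data.frame(marker_id = "m1", chromosome = "GM1",
                              position = 5000000, qtl_id = "q1",
                              trait = "Seed oil"))
  assoc <- window_associate(ann, loci, window_bp = 2e6)
  expect_equal(assoc$gene_id, "near")
  expect_equal(assoc$distance, 1399999)
  expect_true(assoc$seed_flag)
  ## a marker inside the gene span is at distance 0
  loci0 <- qtl_loci(data.frame(marker_id = "m0", chromosome = "GM1",
                               position = 6450000, qtl_id = "q0",
                               trait = "Plant height"))
  a0 <- window_associate(ann, loci0, 2e6)
  expect_equal(a0$distance[a0$gene_id == "near"], 0)
  expect_false(a0$seed_flag[1])

  loci_bad <- qtl_loci(data.frame(marker_id = "m2", chromosome = "GM99",
                                  position = 100, qtl_id = "q2",
                                  trait = "Seed oil"))
  expect_warning(a2 <- window_associate(ann, loci_bad, 2e6), "absent")
  expect_equal(nrow(a2), 0L)
})

test_that("association equals the all-pairs oracle and grows with the window", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 40
    genes <- data.frame(
      gene_id = paste0("g", seq_len(n)),
      chromosome = sample(c("GM1", "GM2"), n, replace = TRUE),
      strand = "+",
      start = s <- sample(3e7, n), end = s + sample(5e4, n),
      exon_total_length = 1000)
    ann <- genome_annotation(genes)
    tab <- data.frame(marker_id = paste0("m", 1:15),
                      chromosome = sample(c("GM1", "GM2"), 15, replace = TRUE),
                      position = sample(3e7, 15),
                      qtl_id = paste0("q", 1:15), trait = "Seed oil")
    loci <- qtl_loci(tab)
    got <- window_associate(ann, loci, 2e6)
    want <- oracle_associations(ann, loci, 2e6)
    key <- function(d) sort(paste(d$gene_id, d$locus_id, d$distance))
    expect_equal(key(got), key(want))
    wider <- window_associate(ann, loci, 4e6)
    expect_true(all(paste(got$gene_id, got$locus_id) %in%
                      paste(wider$gene_id, wider$locus_id)))
  }
})

test_that("co-localization summary counts distinct entities, seed <= any", {
  genes <- data.frame(gene_id = c("gA", "gB"), chromosome = "GM1",
                      strand = "+", start = c(1e6, 2e6), end = c(1e6, 2e6) + 1e3,
                      exon_total_length = 1000)
  ann <- genome_annotation(genes)
  loci <- qtl_loci(data.frame(marker_id = "m1", chromosome = "GM1",
                              position = 1500000, qtl_id = c("q1", "q2"),
                              trait = "Seed weight"))
  assoc <- window_associate(ann, loci, 2e6)
  s <- summarize_colocalization(assoc, loci)
  expect_equal(unlist(s[c("n_genes_any", "n_loci_any", "n_qtls_any",
                          "n_traits_any")]),
               c(n_genes_any = 2L, n_loci_any = 1L, n_qtls_any = 2L,
                 n_traits_any = 1L))
  expect_equal(unlist(s[1:4]), unname(unlist(s[5:8])), ignore_attr = TRUE)

  none <- summarize_colocalization(window_associate(ann, loci, 2e6)[0, ], loci)
  expect_true(all(unlist(none) == 0))
})

test_that("seed candidates are the seed-expressed genes near seed loci", {
  assoc <- data.frame(gene_id = c("A", "B"), locus_id = c("L1", "L2"),
                      distance = 0, seed_flag = c(TRUE, FALSE))
  expect_equal(seed_candidate_genes(assoc, c("A", "B", "C")), "A")
  expect_equal(seed_candidate_genes(assoc, character()), character())
})
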