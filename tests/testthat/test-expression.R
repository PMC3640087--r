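make_cm <- function(counts, lib = NULL, len = NULL) {
  if (is.null(lib)) lib <- setNames(rep(1e6, ncol(counts)), colnames(counts))
  if (is.null(len)) len <- setNames(rep(1000, nrow(counts)), rownames(counts))
  count_matrix(counts, lib, len)
}

test_that("RPKM follows the closed form and rejects degenerate inputs", {
  counts <- matrix(c(100, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
  r <- compute_rpkm(make_cm(counts))
  expect_equal(unclass(r)["g1", ], c(s1 = 100, s2 = 0))
  expect_equal(expression_stage(r), "RPKM")
  ## linear in C, inverse-linear in L and N
  set.seed(1)
  C <- matrix(rpois(20, 50), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  lib <- setNames(runif(5, 1e6, 2e6), colnames(C))
  len <- setNames(runif(4, 500, 3000), rownames(C))
  r1 <- compute_rpkm(make_cm(C, lib, len))
  r2 <- compute_rpkm(make_cm(2 * C, lib, len))
  r3 <- compute_rpkm(make_cm(C, 2 * lib, 2 * len))
  expect_equal(unclass(r2), 2 * unclass(r1))
  expect_equal(unclass(r3), unclass(r1) / 4)

  expect_error(make_cm(C, lib, setNames(c(0, len[-1]), names(len))),
               "exon length.*g1")
  expect_error(make_cm(C, setNames(c(0, lib[-1]), names(lib)), len),
               "library size.*s1")
})

test_that("relative expression divides by the reference geometric mean", {
  m <- matrix(c(1, 4, 16, 4, 4, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("ref1", "target"), c("s1", "s2", "s3")))
  ## single reference gene: ref value per sample is the gene itself
  r <- relative_expression(famfates:::expression_matrix(m, "RPKM"), "ref1")
  expect_equal(unclass(r)["target", ], c(s1 = 4, s2 = 1, s3 = 0.25))

  ## three references (1, 4, 16) -> geometric mean 4
  m2 <- matrix(c(1, 4, 16, 4), 4, 1,
               dimnames = list(c("r1", "r2", "r3", "t"), "s1"))
  r2 <- relative_expression(famfates:::expression_matrix(m2, "RPKM"),
                            c("r1", "r2", "r3"))
  expect_equal(unname(unclass(r2)["t", 1]), 1)
  expect_equal(attr(r2, "reference_value"), c(s1 = 4))

  m2[1, 1] <- 0
  expect_error(relative_expression(famfates:::expression_matrix(m2, "RPKM"),
                                   c("r1", "r2", "r3")), "zero RPKM")
  expect_error(relative_expression(famfates:::expression_matrix(m2, "RPKM"),
                                   "absent"), "not in matrix")
})

test_that("the reference genes' relative geometric mean is 1 in every sample", {
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(runif(60, 0.5, 50), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    refs <- paste0("g", 1:3)
    r <- relative_expression(famfates:::expression_matrix(m, "RPKM"), refs)
    gm <- exp(colMeans(log(unclass(r)[refs, ])))
    expect_lt(max(abs(gm - 1)), 1e-9)
  }
})

test_that("detection, tissue bias and the seed-expressed set follow tau", {
  expect_false(detection_flags(matrix(0), 0)[1])
  expect_true(detection_flags(matrix(0.01), 0)[1])
  expect_false(detection_flags(matrix(0.4), 0.5)[1])

  samples <- tissue_labels()
  flags <- matrix(FALSE, 4, 17, dimnames = list(paste0("g", 1:4), samples))
  flags["g2", c("Gs", "Hs", "Cs")] <- TRUE          # seed only
  flags["g3", c("R", "S")] <- TRUE                  # non-seed only
  flags["g4", c("Gs", "R")] <- TRUE                 # both
  cat4 <- tissue_bias_category(flags)
  expect_equal(unname(cat4),
               c("UNDETECTED_ALL", "SEED_ONLY", "NONSEED_ONLY", "UNBIASED"))
  expect_setequal(seed_expressed_set(flags), c("g2", "g4"))

  ## categories partition the gene set
  set.seed(11)
  rf <- matrix(runif(170) > 0.6, 10, 17,
               dimnames = list(paste0("r", 1:10), samples))
  expect_equal(sum(table(tissue_bias_category(rf))), 10L)
  expect_error(tissue_bias_category(flags, samples), "strict subset")
})

test_that("gene-wise z-scores use the population sd and drop constants", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "const"), paste0("s", 1:3)))
  expect_message(z <- genewise_normalize(m), "constant")
  expect_equal(rownames(z), "a")
  expect_equal(attr(z, "excluded"), "const")
  expect_equal(round(unclass(z)["a", ], 4),
               c(s1 = -1.2247, s2 = 0, s3 = 1.2247))
  expect_error(genewise_normalize(matrix(1:3, 3, 1)), "single-sample")
})

test_that("pearson distance spans [0, 2] and matches the formula", {
  x <- c(1, 2, 3)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(round(pearson_distance(c(1, 2, 3), c(1, 2, 4)), 5), 0.01802)
  expect_error(pearson_distance(c(1, 1), c(1, 2)), "constant")
  expect_error(pearson_distance(1, 1), "length")
})

test_that("hierarchical clustering merges identical rows first", {
  set.seed(2)
  m <- rbind(a = c(1, 5, 2, 8, 3), b = c(2, 1, 9, 4, 6),
             c = c(1, 5, 2, 8, 3) * 2, d = c(9, 1, 2, 3, 4),
             e = c(0, 2, 4, 6, 9))
  ## rows a and c are perfectly correlated: distance 0, merged first
  cl <- hierarchical_cluster(m)
  expect_equal(cl$tree$height[1], 0)
  first <- rownames(m)[-cl$tree$merge[1, ]]
  expect_setequal(first, c("a", "c"))
  expect_equal(unname(hierarchical_cluster(m, k = 5)$labels), 1:5)
  expect_error(hierarchical_cluster(m, k = 9), "exceeds")
  expect_error(hierarchical_cluster(rbind(m, f = rep(1, 5))), "constant")
})

test_that("the UPGMA merge tree equals the brute-force agglomeration", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rnorm(30), 6, 5,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
    cl <- hierarchical_cluster(m)
    got <- as.matrix(stats::cophenetic(cl$tree))
    want <- oracle_upgma_cophenetic(stats::as.dist(1 - cor(t(m))))
    dimnames(want) <- dimnames(got)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("expression matrices round-trip with their stage header", {
  m <- famfates:::expression_matrix(
    matrix(c(1.5, 0, 2.25, 3), 2, 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2"))), "RELATIVE")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  back <- read_expression(path)
  expect_equal(expression_stage(back), "RELATIVE")
  expect_equal(unclass(back), unclass(m))
})
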