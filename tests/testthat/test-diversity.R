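test_that("rarefaction preserves totals and is bounded by the input", {
  m <- rbind(OTU_1 = c(100, 60, 5), OTU_2 = c(0, 40, 3))
  colnames(m) <- c("s1", "s2", "s3")
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), cultivar = "A",
                     soil = "PS", timepoint = c("T2", "T6", "T7"),
                     replicate = 1, storage_days = 150)
  x <- OtuExperiment(m, sampleData = meta)
  expect_message(xr <- rarefyCounts(x, depth = 100, seed = 1), "dropping")
  expect_identical(sampleIds(xr), c("s1", "s2"))
  expect_true(all(colSums(counts(xr)) == 100))
  expect_true(all(counts(xr) <= counts(x)[, sampleIds(xr)]))
  # a sample already at depth is unchanged
  expect_identical(unname(counts(xr)[, "s1"]), c(100, 0))
  # single-taxon forced outcome
  expect_identical(unname(counts(rarefyCounts(x[, 1], depth = 10,
                                              seed = 1))[, 1]), c(10, 0))
  # seed determinism
  a <- counts(rarefyCounts(x, depth = 50, seed = 9))
  b <- counts(rarefyCounts(x, depth = 50, seed = 9))
  expect_identical(a, b)
  expect_error(rarefyCounts(x, depth = 0), "positive")
})

test_that("rarefaction draws match the hypergeometric expectation", {
  # 10,000 independent samples of [50, 50] rarefied to depth 10: the
  # first-taxon count is hypergeometric with mean 5
  n_draws <- 10000
  m <- matrix(rep(c(50, 50), n_draws), nrow = 2,
              dimnames = list(c("OTU_1", "OTU_2"),
                              paste0("s", seq_len(n_draws))))
  meta <- data.frame(sample_id = colnames(m), cultivar = "A", soil = "PS",
                     timepoint = "T2", replicate = seq_len(n_draws),
                     storage_days = 150)
  x <- OtuExperiment(m, sampleData = meta)
  draws <- counts(rarefyCounts(x, depth = 10, seed = 11))["OTU_1", ]
  expect_equal(mean(draws), 5.0, tolerance = 0.1 / 5.0)
})

test_that("alpha indices match their defining formulas", {
  expect_identical(observedRichness(c(0, 0, 3)), 1L)
  expect_identical(observedRichness(c(0, 0, 0)), 0L)
  expect_identical(observedRichness(c(1, 1, 1, 1)), 4L)
  expect_equal(simpsonIndex(c(10, 0, 0)), 0)
  expect_equal(simpsonIndex(c(10, 10, 10, 10)), 0.75)
  expect_equal(simpsonIndex(c(5, 5)), 0.5)
  expect_equal(simpsonIndex(c(5, 5), variant = "inverse"), 2)
  # invariant to integer scaling of counts
  v <- c(3, 9, 1, 7)
  expect_equal(simpsonIndex(v), simpsonIndex(5L * v))
  expect_error(simpsonIndex(c(0, 0)), "zero-total")
})

test_that("permutation ANOVA F equals the textbook one-way F", {
  withr::with_seed(21, {
    for (k in c(2, 3, 4)) {
      g <- factor(rep(seq_len(k), each = 6))
      v <- rnorm(length(g)) + as.numeric(g) * 0.5
      res <- permutationAnova(v, g, n_perm = 49, seed = 1)
      expect_equal(res$F, oracle_anova_F(v, g), tolerance = 1e-10)
    }
  })
})

test_that("permutation ANOVA handles degenerate and separated groups", {
  g <- factor(rep(c("a", "b"), each = 3))
  res <- permutationAnova(rep(2, 6), g, n_perm = 99, seed = 1)
  expect_identical(res$F, 0)
  expect_identical(res$p, 1)

  # {0,0,0} vs {10,10,10}: exactly 2 of the 20 distinct relabellings give
  # perfect separation, so the exact p is 0.1
  res2 <- permutationAnova(c(0, 0, 0, 10, 10, 10), g, n_perm = 9999,
                           seed = 5)
  expect_equal(res2$p, 0.1, tolerance = 0.1)

  expect_error(permutationAnova(rnorm(4), factor(rep("a", 4))),
               "fewer than 2 levels")
})

test_that("marginal multi-factor tests report one row per factor", {
  withr::with_seed(3, {
    v <- rnorm(12)
    fl <- list(cultivar = factor(rep(c("A", "H"), 6)),
               timepoint = factor(rep(c("T2", "T6", "T7"), each = 4)))
    res <- permutationAnova(v, fl, n_perm = 99, seed = 2)
    expect_identical(res$factor, c("cultivar", "timepoint"))
    expect_identical(res$df, c(1L, 2L))
    expect_true(all(res$p >= 1 / 100))
  })
})
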