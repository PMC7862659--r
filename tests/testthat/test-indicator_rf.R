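test_that("stability classes follow batch-level tertiles", {
  meta <- batch_metadata(days_by_batch = 1:9)
  out <- assignStabilityClasses(meta)
  expect_identical(attr(out, "stability_cut_points"), c(3L, 6L))
  # shortest storage times are the earliest sprouters -> "short"
  cls <- tapply(as.character(out$stability_class), out$storage_days, unique)
  expect_true(all(cls[as.character(1:3)] == "short"))
  expect_true(all(cls[as.character(4:6)] == "medium"))
  expect_true(all(cls[as.character(7:9)] == "long"))
  expect_false(anyNA(out$stability_class))

  expect_error(assignStabilityClasses(batch_metadata(rep(150, 4))),
               "3 distinct")

  manual <- assignStabilityClasses(meta, method = "manual",
                                   cut_points = c(2, 5))
  expect_identical(sum(manual$stability_class == "short"), 6L)
})

test_that("backward elimination recovers planted class-determining OTUs", {
  withr::with_seed(71, {
    # six classes coded by five planted OTUs (one indicator bit each, the
    # sixth class is all-zero): every planted OTU is needed to separate
    # its class, so the minimal zero-error set must contain all five
    n <- 60
    g <- factor(rep(paste0("c", 1:6), each = 10))
    X <- matrix(rnorm(n * 205, sd = 0.4), nrow = n,
                dimnames = list(paste0("s", 1:n), paste0("OTU_", 1:205)))
    for (j in 1:5) {
      X[as.integer(g) == j, j] <- X[as.integer(g) == j, j] + 3
    }
    res <- rfSelect(X, g, n_trees = 500, seed = 7)
    expect_true(all(paste0("OTU_", 1:5) %in% selectedOtus(res)))
    expect_lte(length(selectedOtus(res)), 10L)
    path <- eliminationPath(res)
    sel_err <- path$oob_error[path$n_otus == length(selectedOtus(res))]
    expect_lte(sel_err, 0.05)
    # the se rule holds by construction
    e_min <- min(path$oob_error)
    expect_lte(sel_err, e_min + sqrt(e_min * (1 - e_min) / n))
    # the path shrinks by ceiling(drop_fraction * size) each step
    expect_true(all(diff(path$n_otus) < 0))
    expected_sizes <- Reduce(function(s, i) s - ceiling(0.2 * s),
                             seq_len(nrow(path) - 1L), accumulate = TRUE,
                             init = 205)
    expect_identical(path$n_otus, as.integer(expected_sizes))
  })
})

test_that("selection is deterministic given a seed", {
  withr::with_seed(72, {
    X <- matrix(rnorm(30 * 40), nrow = 30,
                dimnames = list(NULL, paste0("OTU_", 1:40)))
    g <- factor(rep(c("a", "b"), 15))
    r1 <- rfSelect(X, g, n_trees = 300, seed = 99)
    r2 <- rfSelect(X, g, n_trees = 300, seed = 99)
    expect_identical(selectedOtus(r1), selectedOtus(r2))
    expect_identical(eliminationPath(r1), eliminationPath(r2))
  })
})

test_that("a permuted response keeps OOB errors near the majority rate", {
  withr::with_seed(73, {
    n <- 40
    X <- matrix(rnorm(n * 60), nrow = n,
                dimnames = list(NULL, paste0("OTU_", 1:60)))
    g <- factor(rep(c("a", "b"), each = 20))
    res <- rfSelect(X, sample(g), n_trees = 500, seed = 3)
    base <- 0.5  # balanced two-class majority error
    tol <- 2 * sqrt(base * (1 - base) / n)
    path <- eliminationPath(res)
    # no spurious skill beyond sampling noise on the full model; late
    # steps are biased low because the ranking was learnt on the same
    # data, so only a generous lower bound is meaningful there
    expect_lte(abs(path$oob_error[1L] - base), tol + 0.05)
    expect_true(all(path$oob_error <= base + tol + 0.05))
    expect_gte(mean(path$oob_error), base - tol)
  })
})

test_that("a two-OTU table is a single-step path selecting both", {
  withr::with_seed(74, {
    X <- matrix(rnorm(20 * 2), nrow = 20,
                dimnames = list(NULL, c("OTU_1", "OTU_2")))
    g <- factor(rep(c("a", "b"), each = 10))
    res <- rfSelect(X, g, n_trees = 200, seed = 1)
    expect_identical(nrow(eliminationPath(res)), 1L)
    expect_setequal(selectedOtus(res), c("OTU_1", "OTU_2"))
  })
})

test_that("rfSelect validates its response", {
  X <- matrix(rnorm(12), nrow = 6, dimnames = list(NULL, c("a", "b")))
  expect_error(rfSelect(X, factor(rep("x", 6)), n_trees = 50),
               "at least 2 classes")
  expect_error(rfSelect(X, factor(c("x", "x", "x", "x", "x", "y")),
                        n_trees = 50), "at least 2 samples")
})
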