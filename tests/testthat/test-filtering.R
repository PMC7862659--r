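test_that("relative abundances are per-sample proportions", {
  m <- matrix(c(1, 1, 2), nrow = 1,
              dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(relativeAbundance(m)[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(relativeAbundance(matrix(7, 1, 1,
    dimnames = list("s1", "a")))[1, ]), 1)
  two <- matrix(c(10, 0, 0, 10), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(unname(relativeAbundance(two)), diag(2))
  zero <- matrix(c(1, 0), 2, 1, dimnames = list(c("s1", "s2"), "a"))
  expect_error(relativeAbundance(zero), "s2")
})

test_that("the rOTU filter retains exactly the hand-enumerated toy set", {
  x <- toy_experiment()
  rot <- filterRotus(x)
  expect_identical(retainedOtus(rot), c("OTU_A", "OTU_D"))
  log <- ruleLog(rot)
  rownames(log) <- log$otu_id
  # OTU_A: 2/3 replicates in one cell, mean relab 1.33e-4 -> retained
  expect_true(log["OTU_A", "retained"])
  # OTU_B: abundant but in only 1 replicate of every cell
  expect_false(log["OTU_B", "retained"])
  expect_false(log["OTU_B", "removed_by_abundance"])
  expect_true(log["OTU_B", "removed_by_replication"])
  # OTU_C: reproducible (3/3) but mean relab 3.3e-5
  expect_true(log["OTU_C", "removed_by_abundance"])
  expect_false(log["OTU_C", "removed_by_replication"])
  # OTU_E: all-zero, removed under defaults by both rules
  expect_true(log["OTU_E", "removed_by_abundance"])
  expect_true(log["OTU_E", "removed_by_replication"])
})

test_that("vacuous thresholds retain everything", {
  x <- toy_experiment()
  rot <- filterRotus(x, min_mean_relab = 0, min_present = 0)
  expect_identical(retainedOtus(rot), otuIds(x))
})

test_that("the rOTU filter is idempotent and monotone in its thresholds", {
  x <- random_experiment(n_otus = 30, seed = 7)
  # sparsify so the rules have something to do
  m <- counts(x)
  withr::with_seed(8, m[sample(length(m), length(m) * 0.6)] <- 0)
  m[1L, ] <- m[1L, ] + 50
  x <- OtuExperiment(m, sampleData = sampleData(x))
  rot <- filterRotus(x, min_mean_relab = 0.01)
  x2 <- applyRotuFilter(x, rot)
  rot2 <- filterRotus(x2, min_mean_relab = 0.01)
  expect_identical(retainedOtus(rot2), retainedOtus(rot))

  sizes_a <- vapply(c(0, 1e-4, 0.01, 0.05), function(thr) {
    length(retainedOtus(filterRotus(x, min_mean_relab = thr)))
  }, numeric(1))
  expect_true(all(diff(sizes_a) <= 0))
  sizes_b <- vapply(0:3, function(mp) {
    length(retainedOtus(filterRotus(x, min_present = mp)))
  }, numeric(1))
  expect_true(all(diff(sizes_b) <= 0))

  # removal reasons are exhaustive
  log <- ruleLog(rot)
  expect_identical(nrow(log), length(otuIds(x)))
  removed <- log[!log$retained, ]
  expect_true(all(removed$removed_by_abundance |
                    removed$removed_by_replication))
})

test_that("short replicate cells rescale the presence threshold", {
  x <- toy_experiment()
  x8 <- x[, 1:8]  # T7 cell loses one replicate
  expect_warning(rot <- filterRotus(x8), "fewer than 3")
  expect_true("OTU_A" %in% retainedOtus(rot))
})

test_that("ties filter removes OTUs dominated by one count value", {
  m <- rbind(OTU_1 = c(0, 0, 0, 0, 5, 7),   # mode 4/6 == 2/3 exactly
             OTU_2 = c(1, 2, 3, 4, 5, 6),   # all distinct
             OTU_3 = c(3, 3, 3, 3, 3, 3),   # constant
             OTU_4 = c(0, 0, 0, 0, 0, 7))   # mode 5/6
  colnames(m) <- paste0("s", 1:6)
  rot <- filterTies(m)
  # held exactly at 2/3 with a strict comparison: 4/6 is not removed
  expect_identical(retainedOtus(rot), c("OTU_1", "OTU_2"))
  expect_true(ruleLog(rot)["3", "removed_by_ties"])
  # the decimal-truncated threshold removes the boundary OTU
  rot2 <- filterTies(m, max_tie_fraction = 0.6666)
  expect_identical(retainedOtus(rot2), "OTU_2")
  expect_error(filterTies(m[, 1:2]), "at least 3")
})
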