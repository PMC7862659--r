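test_that("stage sums and repetition averages add up", {
  assay <- data.frame(
    treatment = rep(c("TSB10", "iso1"), each = 12),
    repetition = rep(rep(1:2, each = 6), 2),
    stage = c(rep(0, 6), c(0, 1, 1, 2, 0, 3),
              rep(0, 6), rep(0, 6)))
  ss <- stageSums(assay)
  per <- ss$per_repetition
  expect_identical(per$stage_sum[per$treatment == "TSB10" &
                                   per$repetition == 1], 0)
  expect_identical(per$stage_sum[per$treatment == "TSB10" &
                                   per$repetition == 2], 7)
  expect_equal(ss$treatment_means$mean_stage_sum[
    ss$treatment_means$treatment == "TSB10"], 3.5)
  # two repetitions with sums 7 and 9 average to 8
  ss2 <- stageSums(data.frame(treatment = "t",
                              repetition = rep(1:2, each = 3),
                              stage = c(2, 5, 0, 5, 3, 1)))
  expect_equal(ss2$per_repetition$stage_sum, c(7, 9))
  expect_equal(ss2$treatment_means$mean_stage_sum, 8)
  expect_error(stageSums(data.frame(treatment = "t", repetition = 1,
                                    stage = 4)), "invalid BBCH")
})

test_that("balanced contrasts equal group-mean differences exactly", {
  assay <- data.frame(treatment = rep(c("TSB10", "iso1"), each = 6),
                      repetition = 1,
                      stage = c(3, 2, 3, 5, 2, 3, 0, 1, 0, 0, 1, 0))
  res <- fitAndContrast(assay, control = "TSB10")
  expect_equal(res$contrasts$estimate,
               mean(assay$stage[assay$treatment == "iso1"]) -
                 mean(assay$stage[assay$treatment == "TSB10"]),
               tolerance = 1e-12)
  # EMMs equal arithmetic group means in the balanced one-factor case
  emm <- res$emmeans
  expect_equal(emm$emmean[emm$treatment == "iso1"],
               mean(assay$stage[assay$treatment == "iso1"]),
               tolerance = 1e-12)
  expect_error(fitAndContrast(assay, control = "water"), "absent")
})

test_that("identical stages give a null ANOVA and no hits", {
  assay <- data.frame(treatment = rep(c("TSB10", "a", "b"), each = 4),
                      repetition = 1, stage = 2)
  res <- fitAndContrast(assay)
  expect_identical(res$anova$`F value`[1], 0)
  expect_true(all(res$contrasts$p_adjusted == 1))
  expect_false(any(res$contrasts$inhibitor))
})

test_that("a strong inhibitor is detected and matches the pooled-t oracle", {
  withr::with_seed(101, {
    stages <- c(0, 1, 2, 3, 5)
    mk <- function(mu) {
      idx <- pmin(pmax(round(mu + rnorm(6, sd = 0.5)), 0), 4)
      stages[idx + 1]
    }
    assay <- data.frame(
      treatment = rep(c("TSB10", "iso_inh", "iso_neutral"), each = 6),
      repetition = rep(1:2, 9),
      stage = c(mk(2), mk(0.2), mk(2)))
    res <- fitAndContrast(assay, control = "TSB10")
    inh <- res$contrasts[res$contrasts$treatment == "iso_inh", ]
    expect_lt(inh$estimate, 0)
    expect_lt(inh$p_adjusted, 0.05)
    expect_true(inh$inhibitor)
    # unadjusted t matches the pooled-variance formula computed from sums
    res_un <- fitAndContrast(assay, control = "TSB10", adjust = "none")
    t_oracle <- oracle_contrast_t(assay$stage, factor(assay$treatment),
                                  "iso_inh", "TSB10")
    expect_equal(res_un$contrasts$t[res_un$contrasts$treatment == "iso_inh"],
                 t_oracle, tolerance = 1e-10)
  })
})

test_that("Dunnett-adjusted p-values dominate unadjusted ones", {
  withr::with_seed(102, {
    assay <- data.frame(
      treatment = rep(c("TSB10", "a", "b", "c"), each = 5),
      repetition = 1,
      stage = sample(c(0, 1, 2, 3, 5), 20, replace = TRUE))
    p_dun <- fitAndContrast(assay)$contrasts$p_adjusted
    p_un <- fitAndContrast(assay, adjust = "none")$contrasts$p_adjusted
    expect_true(all(p_dun >= p_un - 1e-12))
  })
})
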