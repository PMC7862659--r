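# Independent oracles used to freeze expected values: deliberately written
# from the defining formulas, not via the package's code paths.

# average ranks computed from first principles (sorting, then averaging
# positions of equal values)
oracle_ranks <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Spearman rho as Pearson correlation of the average ranks, computed from
# the raw sums
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  n <- length(x)
  sxy <- sum(rx * ry) - sum(rx) * sum(ry) / n
  sxx <- sum(rx^2) - sum(rx)^2 / n
  syy <- sum(ry^2) - sum(ry)^2 / n
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# Bray-Curtis from the defining min/total formula
oracle_bray <- function(a, b) {
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

# textbook one-way ANOVA F via lm/anova
oracle_anova_F <- function(values, g) {
  stats::anova(stats::lm(values ~ g))[["F value"]][1L]
}

# PERMANOVA sums of squares computed directly from pair loops
oracle_permanova_F <- function(D, g) {
  n <- nrow(D)
  k <- nlevels(g)
  sst <- 0
  ssw <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sst <- sst + D[i, j]^2 / n
      if (g[i] == g[j]) {
        ssw <- ssw + D[i, j]^2 / sum(g == g[i])
      }
    }
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# exact two-group PERMANOVA p by enumerating every label assignment
oracle_permanova_exact_p <- function(D, g) {
  n <- nrow(D)
  lv <- levels(g)
  n1 <- sum(g == lv[1L])
  f_obs <- oracle_permanova_F(D, g)
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2L, function(sel) {
    gp <- factor(ifelse(seq_len(n) %in% sel, lv[1L], lv[2L]), levels = lv)
    oracle_permanova_F(D, gp)
  })
  mean(f_all >= f_obs)
}

# pooled-variance (model MSE) treatment-vs-control t statistic from sums
oracle_contrast_t <- function(values, g, trt, ctrl) {
  lv <- levels(g)
  mse <- sum(unlist(lapply(lv, function(l) {
    v <- values[g == l]
    (v - mean(v))^2
  }))) / (length(values) - length(lv))
  n1 <- sum(g == trt)
  n0 <- sum(g == ctrl)
  (mean(values[g == trt]) - mean(values[g == ctrl])) /
    sqrt(mse * (1 / n1 + 1 / n0))
}
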