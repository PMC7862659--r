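# Rarefaction, alpha-diversity indices and the permutation ANOVA used to
# test design-factor effects on them.

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement so that every retained
#' sample sums exactly to \code{depth}; samples whose total is below the
#' depth are dropped (reported via a message and
#' \code{metadata(x)$rarefaction$dropped}). A single rarefaction draw is
#' used. Delegates the subsampling to \code{vegan::rrarefy}.
#'
#' @param x an [OtuExperiment-class].
#' @param depth target depth; \code{NULL} uses the minimum sample total.
#' @param seed integer seed for the subsampling draw (NULL: current RNG).
#' @return an [OtuExperiment-class] with rarefied counts.
#' @export
rarefyCounts <- function(x, depth = NULL, seed = NULL) {
  stopifnot(methods::is(x, "OtuExperiment"))
  totals <- colSums(counts(x))
  depth <- depth %||% min(totals)
  if (!is.finite(depth) || depth < 1) {
    stop("rarefaction depth must be a positive integer", call. = FALSE)
  }
  depth <- as.integer(depth)
  dropped <- names(totals)[totals < depth]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " sample(s) below rarefaction depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(colnames(x), dropped)
  x2 <- x[, keep]
  comm <- t(counts(x2))                    # samples x OTUs for vegan
  # rrarefy nags when a table has no singleton counts; irrelevant here
  rare <- .with_seed(seed, suppressWarnings(vegan::rrarefy(comm, depth)))
  out <- OtuExperiment(t(rare),
                       taxonomy = otuTaxonomy(x2), strict = FALSE)
  SummarizedExperiment::colData(out) <- SummarizedExperiment::colData(x2)
  S4Vectors::metadata(out)$rarefaction <-
    list(depth = depth, dropped = dropped, seed = seed)
  out
}

#' Observed richness per sample
#'
#' Number of OTUs with count > 0.
#'
#' @param x an [OtuExperiment-class], a counts vector for one sample, or a
#'   samples x OTUs matrix.
#' @return named integer vector per sample (or a single integer).
#' @export
observedRichness <- function(x) {
  if (methods::is(x, "OtuExperiment")) {
    return(colSums(counts(x) > 0))
  }
  if (is.matrix(x)) {
    return(rowSums(x > 0))
  }
  sum(x > 0)
}

#' Simpson's diversity index per sample
#'
#' Gini-Simpson form \eqn{1 - \sum p_i^2} on the sample's proportions
#' (default), or the inverse form \eqn{1 / \sum p_i^2}.
#'
#' @param x an [OtuExperiment-class], a counts vector, or a samples x OTUs
#'   matrix; every sample total must be positive.
#' @param variant \code{"gini-simpson"} (in [0,1]) or \code{"inverse"}.
#' @return named numeric vector per sample (or a single number).
#' @export
simpsonIndex <- function(x, variant = c("gini-simpson", "inverse")) {
  variant <- match.arg(variant)
  m <- if (methods::is(x, "OtuExperiment")) t(counts(x))
       else if (is.matrix(x)) x
       else matrix(x, nrow = 1L)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    bad <- rownames(m)[totals <= 0] %||% which(totals <= 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- m / totals
  d2 <- rowSums(p^2)
  out <- switch(variant, "gini-simpson" = 1 - d2, "inverse" = 1 / d2)
  if (!is.matrix(x) && !methods::is(x, "OtuExperiment")) out <- unname(out)
  out
}

# One-way ANOVA F statistic from raw values and a grouping factor.
# SSW == 0 with SSB > 0 yields Inf; SSB == 0 yields 0.
.oneway_F <- function(values, g) {
  n <- length(values)
  k <- nlevels(g)
  gs <- tapply(values, g, sum)
  ns <- tabulate(g, nbins = k)
  grand <- sum(values)
  ssb <- sum(gs^2 / ns) - grand^2 / n
  sst <- sum(values^2) - grand^2 / n
  ssw <- sst - ssb
  if (ssb <= 1e-12 * max(sst, 1)) {
    return(0)
  }
  if (ssw <= 1e-12 * max(sst, 1)) {
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Permutation ANOVA of an alpha-diversity value
#'
#' For each factor, computes the classic one-way ANOVA F statistic of
#' \code{values} on that factor and a permutation p-value
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})} under random
#' relabelling of the values across samples. Factors are tested marginally,
#' each with its own relabelling null.
#'
#' @param values numeric per-sample response (e.g. richness or Simpson's
#'   index).
#' @param factors a factor, or a named list / data.frame of factors aligned
#'   with \code{values}; every factor needs at least two levels.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @return data.frame with columns factor, df, F, p, n_perm.
#' @export
permutationAnova <- function(values, factors, n_perm = 9999, seed = NULL) {
  stopifnot(is.numeric(values))
  if (is.factor(factors) || is.character(factors)) {
    factors <- list(factor = factors)
  }
  factors <- as.list(factors)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    names(factors) <- paste0("factor", seq_along(factors))
  }
  n <- length(values)
  .with_seed(seed, {
    res <- lapply(names(factors), function(nm) {
      g <- droplevels(as.factor(factors[[nm]]))
      if (length(g) != n) {
        stop("factor '", nm, "' is not aligned with values", call. = FALSE)
      }
      if (nlevels(g) < 2L) {
        stop("factor '", nm, "' has fewer than 2 levels", call. = FALSE)
      }
      f_obs <- .oneway_F(values, g)
      f_perm <- vapply(seq_len(n_perm), function(i) {
        .oneway_F(values[sample.int(n)], g)
      }, numeric(1L))
      p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
      data.frame(factor = nm, df = nlevels(g) - 1L, F = f_obs, p = p,
                 n_perm = n_perm, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}
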