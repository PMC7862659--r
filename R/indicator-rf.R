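# Storage-stability classes and random-forest backward-elimination
# selection of indicator OTUs.

#' Assign short/medium/long storage-stability classes
#'
#' Storage stability is the number of days from harvest to sprouting of a
#' cultivar x soil batch. Batches are split at the tertiles of the distinct
#' batch-level storage_days values; a batch whose days fall at a cut point
#' goes to the lower class. The lowest tertile (earliest sprouting) is
#' \code{"short"}, the highest \code{"long"}.
#'
#' @param x an [OtuExperiment-class] with design metadata, or a metadata
#'   data.frame.
#' @param method \code{"tertiles"} (default) or \code{"manual"} with
#'   explicit \code{cut_points}.
#' @param cut_points two ordered storage_days thresholds for
#'   \code{method = "manual"}; samples with days <= cut_points[1] are short,
#'   <= cut_points[2] medium, else long.
#' @return for an OtuExperiment, the object with a \code{stability_class}
#'   colData column (levels short/medium/long) and the cut points in
#'   \code{metadata(x)$stability}; for a data.frame, the augmented frame
#'   with the cut points as an attribute.
#' @export
assignStabilityClasses <- function(x, method = c("tertiles", "manual"),
                                   cut_points = NULL) {
  method <- match.arg(method)
  meta <- if (methods::is(x, "OtuExperiment")) sampleData(x) else
    as.data.frame(x)
  if (!all(c("cultivar", "soil", "storage_days") %in% colnames(meta))) {
    stop("metadata needs cultivar, soil and storage_days", call. = FALSE)
  }
  if (anyNA(meta$storage_days)) {
    stop("storage_days missing for some samples", call. = FALSE)
  }
  batch <- interaction(meta$cultivar, meta$soil, drop = TRUE)
  batch_days <- tapply(meta$storage_days, batch, unique)
  if (method == "tertiles") {
    d <- sort(unique(unname(unlist(batch_days))))
    if (length(d) < 3L) {
      stop("tertile grouping needs at least 3 distinct storage_days values",
           call. = FALSE)
    }
    cut_points <- c(d[ceiling(length(d) / 3)], d[ceiling(2 * length(d) / 3)])
  } else {
    if (length(cut_points) != 2L || is.unsorted(cut_points)) {
      stop("manual method needs two ordered cut_points", call. = FALSE)
    }
  }
  cls <- cut(meta$storage_days,
             breaks = c(-Inf, cut_points[1L], cut_points[2L], Inf),
             labels = .STABILITY_LEVELS, right = TRUE)
  cls <- factor(as.character(cls), levels = .STABILITY_LEVELS)
  if (methods::is(x, "OtuExperiment")) {
    SummarizedExperiment::colData(x)$stability_class <- cls
    S4Vectors::metadata(x)$stability <- list(cut_points = cut_points,
                                             method = method)
    x
  } else {
    meta$stability_class <- cls
    attr(meta, "stability_cut_points") <- cut_points
    attr(meta, "stability_method") <- method
    meta
  }
}

#' Random-forest backward-elimination OTU selection
#'
#' varSelRF-style selection of differentially abundant OTUs for a
#' categorical response: (1) fit a random forest on relative abundances and
#' record the out-of-bag (OOB) error and the impurity (Gini) importances;
#' (2) repeatedly drop the \code{drop_fraction} least-important OTUs (ranks
#' from the initial fit, not recomputed, to avoid selection bias), refit and
#' record the OOB error, down to 2 OTUs; (3) select the smallest candidate
#' set whose OOB error does not exceed the path minimum by more than
#' \code{se_multiplier} standard errors, with
#' \eqn{SE = \sqrt{e(1-e)/n}} at the minimum error \eqn{e}.
#'
#' @param x an [OtuExperiment-class] or a samples x OTUs predictor matrix.
#' @param response class labels: a factor aligned with the samples, or the
#'   name of a colData column (e.g. \code{"stability_class"},
#'   \code{"timepoint"}). At least two classes with two samples each.
#' @param n_trees trees per forest (default 2000).
#' @param drop_fraction fraction of remaining OTUs removed per step.
#' @param se_multiplier multiplier for the standard-error rule (default 1).
#' @param seed integer seed; the whole elimination is deterministic given
#'   it.
#' @param recompute_importance recompute importances at every step instead
#'   of reusing the initial ranking.
#' @param use_relative_abundance convert counts to relative abundances
#'   (default) when \code{x} is an OtuExperiment.
#' @return an [RfSelectionResult-class].
#' @export
rfSelect <- function(x, response, n_trees = 2000, drop_fraction = 0.2,
                     se_multiplier = 1, seed = NULL,
                     recompute_importance = FALSE,
                     use_relative_abundance = TRUE) {
  if (methods::is(x, "OtuExperiment")) {
    X <- if (use_relative_abundance) relativeAbundance(x) else t(counts(x))
    if (is.character(response) && length(response) == 1L) {
      cd <- sampleData(x)
      if (!response %in% colnames(cd)) {
        stop("response column '", response, "' not found in colData",
             call. = FALSE)
      }
      response <- cd[[response]]
    }
  } else {
    X <- as.matrix(x)
  }
  y <- droplevels(as.factor(response))
  if (length(y) != nrow(X)) {
    stop("response is not aligned with the samples", call. = FALSE)
  }
  if (anyNA(y)) stop("response contains missing classes", call. = FALSE)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  if (ncol(X) < 2L) stop("need at least 2 OTUs", call. = FALSE)
  n <- nrow(X)

  .with_seed(seed, {
    oob <- function(fit) unname(fit$err.rate[nrow(fit$err.rate), "OOB"])
    fit0 <- randomForest::randomForest(X, y, ntree = n_trees)
    imp <- fit0$importance[, "MeanDecreaseGini"]
    full_rank <- stats::setNames(as.integer(rank(-imp, ties.method = "first")),
                                 colnames(X))
    current <- colnames(X)[order(imp, decreasing = TRUE)]
    sets <- list(current)
    errs <- oob(fit0)
    while (length(current) > 2L) {
      drop_n <- ceiling(drop_fraction * length(current))
      nxt <- length(current) - drop_n
      if (nxt < 2L) nxt <- 2L
      current <- current[seq_len(nxt)]
      fit <- randomForest::randomForest(X[, current, drop = FALSE], y,
                                        ntree = n_trees)
      if (recompute_importance && length(current) > 2L) {
        imp_c <- fit$importance[, "MeanDecreaseGini"]
        current <- current[order(imp_c, decreasing = TRUE)]
      }
      sets <- c(sets, list(current))
      errs <- c(errs, oob(fit))
    }
    path <- data.frame(n_otus = lengths(sets), oob_error = errs)
    e_min <- min(errs)
    se <- sqrt(e_min * (1 - e_min) / n)
    ok <- which(errs <= e_min + se_multiplier * se)
    pick <- ok[which.min(path$n_otus[ok])]
    selected <- sets[[pick]]
    methods::new("RfSelectionResult",
                 path = path, selected = selected,
                 importanceRank = full_rank[selected],
                 params = list(n_trees = n_trees,
                               drop_fraction = drop_fraction,
                               se_multiplier = se_multiplier, seed = seed,
                               classes = levels(y),
                               otu_ids = colnames(X)))
  })
}
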