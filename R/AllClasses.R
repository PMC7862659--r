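#' OtuExperiment: an OTU count table with sample design metadata
#'
#' An \code{OtuExperiment} is a
#' \linkS4class{SummarizedExperiment} holding one \code{"counts"} assay with
#' OTUs as rows and samples as columns. \code{colData} carries the storage
#' experiment design (cultivar, soil, timepoint, replicate, storage_days and,
#' once assigned, stability_class); \code{rowData} optionally carries a
#' \code{taxonomy} lineage string per OTU.
#'
#' Validity requires non-negative, non-missing whole-number counts, unique
#' OTU and sample identifiers, and (when design columns are present)
#' storage_days constant within each cultivar x soil batch.
#'
#' @aliases OtuExperiment-class
#' @seealso [OtuExperiment()] for construction, [readCountTable()] for
#'   reading from TSV.
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    msg <- c(msg, "counts must have OTU rownames and sample colnames")
  } else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate OTU identifiers")
    if (anyDuplicated(colnames(m))) {
      msg <- c(msg, "duplicate sample identifiers")
    }
  }
  if (anyNA(m)) msg <- c(msg, "counts contain missing values")
  else {
    if (any(m < 0)) msg <- c(msg, "counts contain negative values")
    if (!all(.is_whole(m))) msg <- c(msg, "counts must be whole numbers")
  }
  cd <- SummarizedExperiment::colData(object)
  if (all(c("cultivar", "soil", "storage_days") %in% colnames(cd)) &&
      nrow(cd) > 0L) {
    batch <- interaction(cd$cultivar, cd$soil, drop = TRUE)
    nb <- tapply(cd$storage_days, batch, function(d) length(unique(d)))
    if (any(nb > 1L)) {
      msg <- c(msg,
               "storage_days not constant within a cultivar x soil batch")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RotuSet: outcome of an OTU retention rule
#'
#' Records which OTUs survive a filtering rule (reproducible-OTU filtering or
#' the ties filter applied before correlation analysis), together with a
#' per-OTU log of the rule(s) that removed each discarded OTU.
#'
#' @slot retained character, the retained OTU identifiers in input order.
#' @slot ruleLog data.frame with one row per input OTU: \code{otu_id},
#'   \code{retained}, plus one logical column per rule that fired.
#' @slot params list of the filter parameters used.
#' @aliases RotuSet-class
#' @exportClass RotuSet
setClass("RotuSet",
  representation(retained = "character", ruleLog = "data.frame",
                 params = "list"))

setValidity("RotuSet", function(object) {
  msg <- character()
  log <- object@ruleLog
  if (!all(c("otu_id", "retained") %in% colnames(log))) {
    return("ruleLog needs columns otu_id and retained")
  }
  if (!setequal(object@retained, log$otu_id[log$retained])) {
    msg <- c(msg, "retained slot disagrees with ruleLog")
  }
  rule_cols <- setdiff(colnames(log), c("otu_id", "retained"))
  removed <- !log$retained
  if (length(rule_cols) && any(removed)) {
    fired <- rowSums(as.matrix(log[removed, rule_cols, drop = FALSE])) > 0
    if (!all(fired)) {
      msg <- c(msg, "every removed OTU must have at least one rule logged")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationNetwork: thresholded Spearman co-occurrence network
#'
#' Holds the Spearman correlation and p-value matrices over ties-filtered
#' rOTUs (plus the \code{"storage_days"} node when supplied), after entries
#' failing the correlation-strength or significance threshold have been set
#' to zero, and the surviving edges as a table.
#'
#' @slot nodes character node identifiers (rOTU ids, optionally
#'   \code{"storage_days"}).
#' @slot r numeric matrix, thresholded correlations (failed entries zero).
#' @slot p numeric matrix of two-sided p-values (unthresholded).
#' @slot rThreshold,pThreshold numeric thresholds applied.
#' @slot mode \code{"absolute"} (keep |r| >= threshold) or \code{"positive"}.
#' @slot edges data.frame with columns node_i, node_j, r, p for the surviving
#'   off-diagonal entries (each undirected edge once).
#' @aliases CorrelationNetwork-class
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  representation(nodes = "character", r = "matrix", p = "matrix",
                 rThreshold = "numeric", pThreshold = "numeric",
                 mode = "character", edges = "data.frame"))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  n <- length(object@nodes)
  if (!all(dim(object@r) == c(n, n)) || !all(dim(object@p) == c(n, n))) {
    msg <- c(msg, "r and p must be square matrices over the nodes")
  }
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "|r| must not exceed 1")
  }
  off <- object@r
  diag(off) <- 0
  n_nonzero <- sum(off != 0) / 2
  if (nrow(object@edges) != n_nonzero) {
    msg <- c(msg, "edge list does not match nonzero off-diagonal entries")
  }
  if (length(msg)) msg else TRUE
})

#' RfSelectionResult: random-forest backward-elimination outcome
#'
#' The trajectory of the varSelRF-style backward elimination (candidate-set
#' size and out-of-bag error at each step), the selected OTU set under the
#' s.e. rule, and importance ranks from the initial fit.
#'
#' @slot path data.frame with columns \code{n_otus} (strictly decreasing) and
#'   \code{oob_error}.
#' @slot selected character, OTU ids of the selected set.
#' @slot importanceRank named integer, rank (1 = most important) of each
#'   selected OTU in the initial full-model impurity importances.
#' @slot params list: n_trees, drop_fraction, se_multiplier, seed, response
#'   levels and the input OTU universe.
#' @aliases RfSelectionResult-class
#' @exportClass RfSelectionResult
setClass("RfSelectionResult",
  representation(path = "data.frame", selected = "character",
                 importanceRank = "integer", params = "list"))

setValidity("RfSelectionResult", function(object) {
  msg <- character()
  p <- object@path
  if (!all(c("n_otus", "oob_error") %in% colnames(p))) {
    return("path needs columns n_otus and oob_error")
  }
  if (nrow(p) > 1L && any(diff(p$n_otus) >= 0)) {
    msg <- c(msg, "path set sizes must be strictly decreasing")
  }
  if (any(p$oob_error < 0 | p$oob_error > 1)) {
    msg <- c(msg, "oob_error must lie in [0, 1]")
  }
  if (!length(object@selected)) {
    msg <- c(msg, "selected set must be non-empty")
  } else if (!any(p$n_otus == length(object@selected))) {
    msg <- c(msg, "selected set size must appear in the path")
  }
  if (length(msg)) msg else TRUE
})
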