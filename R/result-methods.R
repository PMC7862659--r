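# Accessors and show methods for the filtering, network and RF result
# classes.

#' @rdname tuberstab-generics
#' @export
setMethod("retainedOtus", "RotuSet", function(x) x@retained)

#' @rdname tuberstab-generics
#' @export
setMethod("ruleLog", "RotuSet", function(x) x@ruleLog)

setMethod("show", "RotuSet", function(object) {
  n_in <- nrow(object@ruleLog)
  cat("RotuSet:", length(object@retained), "of", n_in, "OTUs retained\n")
  rule_cols <- setdiff(colnames(object@ruleLog), c("otu_id", "retained"))
  for (rc in rule_cols) {
    cat("  removed by ", rc, ": ", sum(object@ruleLog[[rc]]), "\n", sep = "")
  }
})

#' Subset an OtuExperiment to the OTUs retained by a filter
#'
#' @param x an [OtuExperiment-class].
#' @param rotus a [RotuSet-class] computed on (a superset of) the OTUs of
#'   \code{x}.
#' @return \code{x} restricted to the retained OTUs, in their input order.
#' @export
applyRotuFilter <- function(x, rotus) {
  stopifnot(methods::is(x, "OtuExperiment"), methods::is(rotus, "RotuSet"))
  keep <- intersect(otuIds(x), retainedOtus(rotus))
  x[keep, ]
}

#' @rdname tuberstab-generics
#' @export
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)

#' @rdname tuberstab-generics
#' @export
setMethod("nodeDegree", "CorrelationNetwork", function(x) {
  deg <- stats::setNames(integer(length(x@nodes)), x@nodes)
  if (nrow(x@edges)) {
    tab <- table(c(x@edges$node_i, x@edges$node_j))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  cat("  thresholds: |r| >=", object@rThreshold, "(mode", object@mode,
      "), p <=", object@pThreshold, "\n")
  if ("storage_days" %in% object@nodes) {
    k <- nodeDegree(object)[["storage_days"]]
    cat("  storage_days node degree:", k, "\n")
  }
})

#' @rdname tuberstab-generics
#' @export
setMethod("selectedOtus", "RfSelectionResult", function(x) x@selected)

#' @rdname tuberstab-generics
#' @export
setMethod("eliminationPath", "RfSelectionResult", function(x) x@path)

#' @rdname tuberstab-generics
#' @export
setMethod("importanceRanks", "RfSelectionResult", function(x) {
  x@importanceRank
})

setMethod("show", "RfSelectionResult", function(object) {
  cat("RfSelectionResult:", length(object@selected), "OTUs selected from",
      object@path$n_otus[1L], "candidates\n")
  best <- min(object@path$oob_error)
  sel <- object@path$oob_error[object@path$n_otus ==
                                 length(object@selected)]
  cat(sprintf("  OOB error: selected set %.3f, path minimum %.3f over %d steps\n",
              sel, best, nrow(object@path)))
})
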