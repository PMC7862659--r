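# Intersection of the random-forest and correlation-network selection
# routes into direction-labelled key OTUs.

#' Intersect RF-selected OTUs with the correlation network
#'
#' An OTU is a key OTU iff it was selected by the random-forest backward
#' elimination (the union over strata when several results are supplied)
#' AND it has at least one surviving edge in the thresholded network
#' (restricted to edges with the \code{"storage_days"} node when
#' \code{storage_edge_only = TRUE}). OTUs with a surviving storage-node
#' edge carry its correlation and p-value; a direction label is assigned
#' from the correlation sign, falling back to the stability class with the
#' maximal mean relative abundance (see [assignDirection()]).
#'
#' @param rf an [RfSelectionResult-class] or a (possibly named) list of them
#'   from per-stratum runs; selections are pooled by union with per-OTU
#'   origin recorded.
#' @param net a [CorrelationNetwork-class] built on the same rOTU universe.
#' @param relab optional samples x OTUs relative-abundance matrix used for
#'   the class-mean fallback of the direction label.
#' @param stability_class optional per-sample factor with levels
#'   short/medium/long, aligned with \code{relab}.
#' @param storage_edge_only require a direct edge to the storage-time node.
#' @return data.frame with columns otu_id, direction, r_storage, p_storage,
#'   rf_importance_rank, evidence, origin, ordered by |r_storage| then RF
#'   rank. Zero rows when either route selected nothing.
#' @export
intersectKeyOtus <- function(rf, net, relab = NULL, stability_class = NULL,
                             storage_edge_only = FALSE) {
  if (methods::is(rf, "RfSelectionResult")) rf <- list(rf)
  if (is.null(names(rf))) names(rf) <- paste0("stratum", seq_along(rf))
  stopifnot(methods::is(net, "CorrelationNetwork"))
  universe <- unique(unlist(lapply(rf, function(r) r@params$otu_ids)))
  net_otus <- setdiff(net@nodes, "storage_days")
  if (length(universe) && !length(intersect(universe, net_otus))) {
    stop("RF and network OTU universes are disjoint; RF ids: ",
         paste(utils::head(universe, 3L), collapse = ", "),
         " ... vs network ids: ",
         paste(utils::head(net_otus, 3L), collapse = ", "), call. = FALSE)
  }
  sel_by_stratum <- lapply(rf, selectedOtus)
  pooled <- unique(unlist(sel_by_stratum))
  deg <- nodeDegree(net)
  edges <- networkEdges(net)
  if (storage_edge_only) {
    se <- edges[edges$node_i == "storage_days" |
                  edges$node_j == "storage_days", , drop = FALSE]
    connected <- setdiff(unique(c(se$node_i, se$node_j)), "storage_days")
  } else {
    connected <- names(deg)[deg > 0]
    connected <- setdiff(connected, "storage_days")
  }
  keys <- intersect(pooled, connected)
  empty <- data.frame(otu_id = character(), direction = character(),
                      r_storage = numeric(), p_storage = numeric(),
                      rf_importance_rank = integer(),
                      evidence = character(), origin = character(),
                      stringsAsFactors = FALSE)
  if (!length(keys)) {
    return(empty)
  }
  has_storage <- "storage_days" %in% net@nodes
  r_st <- if (has_storage) net@r[keys, "storage_days"] else
    stats::setNames(numeric(length(keys)), keys)
  p_st <- if (has_storage) net@p[keys, "storage_days"] else
    stats::setNames(rep(NA_real_, length(keys)), keys)
  p_st[r_st == 0] <- NA_real_

  class_means <- NULL
  if (!is.null(relab) && !is.null(stability_class)) {
    cls <- factor(as.character(stability_class),
                  levels = .STABILITY_LEVELS)
    class_means <- vapply(.STABILITY_LEVELS, function(lv) {
      colMeans(relab[cls == lv, keys, drop = FALSE])
    }, numeric(length(keys)))
    if (is.null(dim(class_means))) {
      class_means <- matrix(class_means, nrow = 1L,
                            dimnames = list(keys, .STABILITY_LEVELS))
    }
  }
  direction <- vapply(seq_along(keys), function(i) {
    cm <- if (is.null(class_means)) NULL else class_means[i, ]
    assignDirection(r_st[i], cm)
  }, character(1L))

  rank_min <- vapply(keys, function(id) {
    rks <- unlist(lapply(rf, function(r) r@importanceRank[id]))
    as.integer(min(rks, na.rm = TRUE))
  }, integer(1L))
  origin <- vapply(keys, function(id) {
    paste(names(rf)[vapply(sel_by_stratum, function(s) id %in% s,
                           logical(1L))], collapse = ",")
  }, character(1L))

  out <- data.frame(otu_id = keys, direction = direction,
                    r_storage = unname(r_st), p_storage = unname(p_st),
                    rf_importance_rank = rank_min, evidence = "rf,network",
                    origin = origin, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r_storage), out$rf_importance_rank), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction label of a key OTU
#'
#' A positive correlation with the storage-time node means higher relative
#' abundance in tubers that sprouted late (\code{"long"} storage
#' stability); a negative one means \code{"short"}. An OTU linked only to
#' other OTUs (\code{r_storage == 0}) is labelled by the stability class in
#' which its mean relative abundance is maximal; with no class means — or
#' all of them equal — the direction is \code{NA} with a warning.
#'
#' @param r_storage signed correlation with the storage-time node (0 if
#'   none).
#' @param class_means optional named numeric with names short/medium/long.
#' @return one of "short", "medium", "long" or NA.
#' @export
assignDirection <- function(r_storage, class_means = NULL) {
  if (!is.na(r_storage) && r_storage > 0) {
    return("long")
  }
  if (!is.na(r_storage) && r_storage < 0) {
    return("short")
  }
  if (is.null(class_means) || all(is.na(class_means)) ||
      length(unique(round(class_means, 15))) == 1L) {
    warning("no storage edge and no informative class means; ",
            "direction unset", call. = FALSE)
    return(NA_character_)
  }
  names(which.max(class_means))
}
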