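# Spearman correlation matrix over ties-filtered rOTUs plus a storage-time
# node, and its thresholding into a co-occurrence network.

#' Spearman correlation matrix with a storage-time node
#'
#' Computes pairwise Spearman rank correlations (average ranks for ties)
#' between all OTUs — on relative abundances by default — and, when
#' \code{storage_days} is supplied, an additional \code{"storage_days"}
#' node holding each sample's batch-level days from harvest to sprouting.
#' Two-sided p-values come from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} (or from a permutation null with
#' \code{p_method = "permutation"}).
#'
#' Constant nodes have undefined correlations; they are recorded as
#' r = 0, p = 1 with a warning (the ties filter normally prevents this).
#'
#' @param x an [OtuExperiment-class] (typically already restricted to
#'   ties-filtered rOTUs) or a samples x OTUs matrix; at least 4 samples.
#' @param storage_days per-sample days, aligned with the samples, or
#'   \code{NULL} to omit the storage node.
#' @param use_relative_abundance convert counts to proportions first.
#' @param p_method \code{"t"} (default) or \code{"permutation"}.
#' @param n_perm,seed permutation-null settings.
#' @return list with elements \code{r}, \code{p} (symmetric matrices over
#'   the nodes), \code{n} (number of samples), \code{nodes}.
#' @export
spearmanMatrix <- function(x, storage_days = NULL,
                           use_relative_abundance = TRUE,
                           p_method = c("t", "permutation"),
                           n_perm = 999, seed = NULL) {
  p_method <- match.arg(p_method)
  X <- if (methods::is(x, "OtuExperiment")) {
    if (use_relative_abundance) relativeAbundance(x) else t(counts(x))
  } else {
    as.matrix(x)
  }
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (!is.null(storage_days)) {
    if (length(storage_days) != n) {
      stop("storage_days is not aligned with the samples", call. = FALSE)
    }
    X <- cbind(X, storage_days = as.numeric(storage_days))
  }
  constant <- apply(X, 2L, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning("constant node(s) with undefined correlation recorded as ",
            "r = 0, p = 1: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X, method = "spearman"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  if (p_method == "t") {
    r_clamp <- pmin(pmax(r, -1), 1)
    tt <- r_clamp * sqrt((n - 2) / pmax(1 - r_clamp^2, .Machine$double.eps))
    tt[abs(r_clamp) >= 1 - 1e-15] <- Inf
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- .with_seed(seed, .spearman_perm_p(X, r, n_perm))
  }
  diag(p) <- 0
  p[constant, ] <- 1
  p[, constant] <- 1
  r[constant, ] <- 0
  r[, constant] <- 0
  diag(r) <- 1
  diag(p) <- 0
  list(r = r, p = p, n = n, nodes = colnames(X))
}

# Permutation p-values: permute the rows of one variable's ranks against the
# others; shared permutations across pairs keep the cost linear in n_perm.
.spearman_perm_p <- function(X, r_obs, n_perm) {
  n <- nrow(X)
  R <- apply(X, 2L, rank)
  count <- matrix(0, ncol(X), ncol(X))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_perm <- suppressWarnings(stats::cor(R, R[perm, , drop = FALSE]))
    r_perm[is.na(r_perm)] <- 0
    count <- count + (abs(r_perm) >= abs(r_obs) - 1e-12)
  }
  (1 + count) / (1 + n_perm)
}

#' Threshold a correlation matrix into a network
#'
#' Keeps only strong, highly significant correlations: in
#' \code{mode = "absolute"} an entry survives iff \eqn{|r| \ge}
#' \code{r_threshold} and \eqn{p \le} \code{p_threshold}; in
#' \code{mode = "positive"} only positive correlations survive. All other
#' entries are set to zero and the surviving off-diagonal entries become the
#' edge list.
#'
#' @param r,p symmetric correlation and p-value matrices (as from
#'   [spearmanMatrix()], which may also be passed directly as \code{r}).
#' @param r_threshold,p_threshold thresholds, both in [0, 1].
#' @param mode \code{"absolute"} (default) or \code{"positive"}.
#' @return a [CorrelationNetwork-class].
#' @export
thresholdNetwork <- function(r, p = NULL, r_threshold = 0.5,
                             p_threshold = 0.001,
                             mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  if (is.list(r) && is.null(p)) {
    p <- r$p
    r <- r$r
  }
  if (!isTRUE(all.equal(dim(r), dim(p)))) {
    stop("r and p must have the same shape", call. = FALSE)
  }
  if (r_threshold < 0 || r_threshold > 1 || p_threshold < 0 ||
      p_threshold > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  nodes <- colnames(r) %||% paste0("node_", seq_len(ncol(r)))
  dimnames(r) <- dimnames(p) <- list(nodes, nodes)
  keep <- if (mode == "absolute") abs(r) >= r_threshold else r >= r_threshold
  keep <- keep & (p <= p_threshold)
  r_thr <- ifelse(keep, r, 0)
  diag(r_thr) <- 1
  ut <- upper.tri(r_thr)
  sel <- which(ut & r_thr != 0, arr.ind = TRUE)
  edges <- data.frame(node_i = nodes[sel[, 1L]], node_j = nodes[sel[, 2L]],
                      r = r_thr[sel], p = p[sel],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("CorrelationNetwork", nodes = nodes, r = r_thr, p = p,
               rThreshold = r_threshold, pThreshold = p_threshold,
               mode = mode, edges = edges)
}
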