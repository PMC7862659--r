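# Bray-Curtis dissimilarity, PERMANOVA and (constrained) principal
# coordinates ordination.

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(i,j) = 1 - 2 \sum_k \min(x_{ik}, x_{jk}) /
#' (\sum_k x_{ik} + \sum_k x_{jk})}, computed with
#' \code{vegan::vegdist}. Accepts raw counts or proportions; with
#' \code{normalize = TRUE} (default) samples are first converted to relative
#' abundances so that library size carries no signal.
#'
#' @param x an [OtuExperiment-class] or a samples x OTUs matrix; every
#'   sample total must be positive.
#' @param normalize convert to per-sample proportions first.
#' @return a \code{dist} with sample labels; entries lie in [0, 1].
#' @export
brayCurtis <- function(x, normalize = TRUE) {
  m <- if (methods::is(x, "OtuExperiment")) t(counts(x)) else as.matrix(x)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    bad <- rownames(m)[totals <= 0] %||% which(totals <= 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (normalize) m <- m / totals
  vegan::vegdist(m, method = "bray")
}

# Within-group sum of squared interpoint distances from a squared-distance
# matrix and a list of per-group index vectors.
.permanova_ssw <- function(D2, idx_list) {
  s <- 0
  for (idx in idx_list) {
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's pseudo-F from the partitioned squared distances:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}, \eqn{SS_{within}} from
#' within-group pairs, \eqn{F = (SS_B/(k-1)) / (SS_W/(n-k))}, with the
#' p-value from unrestricted permutation of the group labels (or, with
#' \code{exact = TRUE} and two groups, from complete enumeration of the
#' distinct label assignments).
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param grouping factor-like group labels aligned with the samples;
#'   at least two groups, none empty, and fewer groups than samples.
#' @param n_perm number of permutations (ignored when \code{exact}).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct assignments (two groups only);
#'   p is then the exact fraction of assignments with \eqn{F \ge F_{obs}}.
#' @param strata optional factor restricting permutations to occur within
#'   its levels.
#' @return data.frame with columns pseudo_F, R2, p, n_perm, df.
#' @export
permanova <- function(d, grouping, n_perm = 9999, seed = NULL,
                      exact = FALSE, strata = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  g <- droplevels(as.factor(grouping))
  if (length(g) != n) {
    stop("grouping is not aligned with the distance matrix", call. = FALSE)
  }
  k <- nlevels(g)
  if (k < 2L) stop("grouping needs at least 2 groups", call. = FALSE)
  if (k >= n) {
    stop("grouping must have fewer groups than samples", call. = FALSE)
  }
  D2 <- D^2
  sst <- sum(D2) / (2 * n)
  idx <- split(seq_len(n), g)
  ssw <- .permanova_ssw(D2, idx)
  ssb <- sst - ssw
  f_obs <- if (ssw <= 1e-12 * max(sst, 1)) {
    if (ssb <= 1e-12 * max(sst, 1)) 0 else Inf
  } else {
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  if (ssb <= 1e-12 * max(sst, 1)) f_obs <- 0
  r2 <- if (sst > 0) ssb / sst else 0

  f_of_labels <- function(gp) {
    sw <- .permanova_ssw(D2, split(seq_len(n), gp))
    sb <- sst - sw
    if (sw <= 1e-12 * max(sst, 1)) {
      if (sb <= 1e-12 * max(sst, 1)) 0 else Inf
    } else {
      (sb / (k - 1)) / (sw / (n - k))
    }
  }

  if (exact) {
    if (k != 2L) {
      stop("exact enumeration is implemented for two groups only",
           call. = FALSE)
    }
    n1 <- sum(g == levels(g)[1L])
    combos <- utils::combn(n, n1)
    f_all <- apply(combos, 2L, function(sel) {
      gp <- factor(ifelse(seq_len(n) %in% sel, levels(g)[1L], levels(g)[2L]),
                   levels = levels(g))
      f_of_labels(gp)
    })
    p <- mean(f_all >= f_obs)
    n_perm <- ncol(combos)
  } else {
    p <- .with_seed(seed, {
      f_perm <- vapply(seq_len(n_perm), function(i) {
        gp <- if (is.null(strata)) {
          g[sample.int(n)]
        } else {
          ord <- seq_len(n)
          for (lv in split(seq_len(n), strata)) ord[lv] <- lv[sample.int(length(lv))]
          g[ord]
        }
        f_of_labels(gp)
      }, numeric(1L))
      (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    })
  }
  data.frame(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_perm,
             df = k - 1L, stringsAsFactors = FALSE)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Classical scaling of the double-centred \eqn{-d^2/2} matrix via
#' \code{stats::cmdscale}. Coordinates are returned only for axes with
#' positive eigenvalues; all eigenvalues (including negative ones) are
#' reported, with a warning when the negative mass exceeds 5\% of the
#' positive mass.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param n_axes number of axes to return (default: all positive).
#' @return an object of class \code{tuber_ordination}: list with
#'   \code{coordinates} (samples x axes, centred), \code{eigenvalues},
#'   \code{constrained = FALSE}.
#' @export
pcoaOrdination <- function(d, n_axes = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  k_req <- min(n_axes %||% (n - 1L), n - 1L)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = k_req,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  neg <- -sum(eig[eig < 0])
  if (pos > 0 && neg > 0.05 * pos) {
    warning(sprintf(
      "negative eigenvalue mass is %.1f%% of the positive mass; ",
      100 * neg / pos), "coordinates omit those axes", call. = FALSE)
  }
  coords <- fit$points
  if (!is.null(coords) && ncol(coords)) {
    keep <- seq_len(min(ncol(coords), sum(eig > 1e-8 * max(abs(eig)))))
    coords <- coords[, keep, drop = FALSE]
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 constrained = FALSE),
            class = "tuber_ordination")
}

#' Constrained analysis of principal coordinates (CAP)
#'
#' Discriminant rotation of retained PCoA axes with respect to a grouping:
#' PCoA axes covering at least \code{var_cutoff} of the positive eigenvalue
#' mass (or the first \code{n_pcoa_axes}) are passed to a linear
#' discriminant analysis, whose scores are the constrained coordinates
#' (at most \code{groups - 1} axes).
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param grouping factor-like group labels (at least two levels).
#' @param n_pcoa_axes number of PCoA axes fed to the discriminant step;
#'   default chooses the smallest count explaining \code{var_cutoff} of the
#'   positive eigenvalue mass.
#' @param var_cutoff proportion of positive eigenvalue mass to retain.
#' @return a \code{tuber_ordination} with \code{constrained = TRUE};
#'   eigenvalues are the squared singular values of the discriminant.
#' @export
capOrdination <- function(d, grouping, n_pcoa_axes = NULL,
                          var_cutoff = 0.85) {
  g <- droplevels(as.factor(grouping))
  if (nlevels(g) < 2L) {
    stop("grouping needs at least 2 levels", call. = FALSE)
  }
  pc <- pcoaOrdination(d)
  scores <- pc$coordinates
  n <- nrow(scores)
  eig_pos <- pc$eigenvalues[pc$eigenvalues > 0]
  if (is.null(n_pcoa_axes)) {
    cum <- cumsum(eig_pos) / sum(eig_pos)
    n_pcoa_axes <- which(cum >= var_cutoff)[1L]
  }
  if (n_pcoa_axes > n - 1L) {
    stop("more PCoA axes requested than samples - 1", call. = FALSE)
  }
  n_pcoa_axes <- min(n_pcoa_axes, ncol(scores))
  sub <- scores[, seq_len(n_pcoa_axes), drop = FALSE]
  fit <- MASS::lda(sub, grouping = g)
  coords <- stats::predict(fit, sub)$x
  coords <- scale(coords, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  colnames(coords) <- paste0("CAP", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = fit$svd^2,
                 constrained = TRUE, n_pcoa_axes = n_pcoa_axes,
                 grouping = g),
            class = "tuber_ordination")
}

#' @export
print.tuber_ordination <- function(x, ...) {
  kind <- if (isTRUE(x$constrained)) "CAP" else "PCoA"
  cat(kind, "ordination:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  ev <- x$eigenvalues
  cat("  eigenvalues:", paste(signif(utils::head(ev, 5L), 4L),
                              collapse = ", "),
      if (length(ev) > 5L) "...", "\n")
  invisible(x)
}
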