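# Reproducible-OTU (rOTU) filtering and the ties filter applied before
# correlation analysis.

#' Reproducible-OTU (rOTU) filter
#'
#' Retains an OTU iff (a) its relative abundance summary across the analysis
#' samples reaches \code{min_mean_relab} (default 0.01\%) and (b) there is at
#' least one cultivar x soil x timepoint replicate cell in which it is
#' present (count > 0) in at least \code{min_present} of \code{of_replicates}
#' replicates. Both rules are evaluated and logged independently for every
#' OTU.
#'
#' Cells with fewer than \code{of_replicates} samples trigger a warning and
#' rule (b) is evaluated with the threshold rescaled to
#' \code{ceiling(min_present / of_replicates * available)}.
#'
#' @param x an [OtuExperiment-class] with design metadata.
#' @param min_mean_relab relative-abundance floor (proportion, default 1e-4
#'   = 0.01\%).
#' @param min_present,of_replicates replicate-presence rule: present in at
#'   least \code{min_present} of \code{of_replicates} replicates of some
#'   cell.
#' @param abundance_stat how the per-OTU abundance summary is formed:
#'   \code{"mean"} of per-sample relative abundances (default), their
#'   \code{"max"}, or the \code{"pooled"} read fraction.
#' @param presence_scope \code{"any"}: the presence criterion must hold in at
#'   least one cell (default); \code{"all"}: in every cell.
#' @return a [RotuSet-class]; the rule log records, per OTU, whether the
#'   abundance and/or replication rule removed it.
#' @seealso [applyRotuFilter()], [filterTies()]
#' @export
filterRotus <- function(x, min_mean_relab = 1e-4, min_present = 2,
                        of_replicates = 3,
                        abundance_stat = c("mean", "max", "pooled"),
                        presence_scope = c("any", "all")) {
  stopifnot(methods::is(x, "OtuExperiment"))
  abundance_stat <- match.arg(abundance_stat)
  presence_scope <- match.arg(presence_scope)
  meta <- sampleData(x)
  needed <- c("cultivar", "soil", "timepoint")
  if (!all(needed %in% colnames(meta))) {
    stop("filterRotus needs design metadata (cultivar, soil, timepoint)",
         call. = FALSE)
  }
  m <- counts(x)                               # OTUs x samples
  relab <- t(relativeAbundance(x))             # OTUs x samples
  abundance <- switch(abundance_stat,
    mean = rowMeans(relab),
    max = apply(relab, 1L, max),
    pooled = rowSums(m) / sum(m))
  pass_a <- abundance >= min_mean_relab

  cell <- interaction(meta$cultivar, meta$soil, meta$timepoint, drop = TRUE)
  cell_sizes <- table(cell)
  if (any(cell_sizes < of_replicates)) {
    warning("replicate cell(s) with fewer than ", of_replicates,
            " samples: ",
            paste(names(cell_sizes)[cell_sizes < of_replicates],
                  collapse = ", "),
            "; presence threshold rescaled to the available replicates",
            call. = FALSE)
  }
  present <- m > 0
  # per-cell presence counts: OTUs x cells
  idx_by_cell <- split(seq_len(ncol(m)), cell)
  pass_cell <- vapply(idx_by_cell, function(idx) {
    avail <- length(idx)
    thr <- if (avail >= of_replicates) min_present
           else ceiling(min_present / of_replicates * avail)
    rowSums(present[, idx, drop = FALSE]) >= thr
  }, logical(nrow(m)))
  if (is.null(dim(pass_cell))) pass_cell <- matrix(pass_cell, nrow = nrow(m))
  pass_b <- if (presence_scope == "any") rowSums(pass_cell) > 0
            else rowSums(pass_cell) == ncol(pass_cell)

  retained <- pass_a & pass_b
  log <- data.frame(otu_id = rownames(m), retained = retained,
                    removed_by_abundance = !pass_a,
                    removed_by_replication = !pass_b,
                    stringsAsFactors = FALSE, row.names = NULL)
  methods::new("RotuSet", retained = rownames(m)[retained], ruleLog = log,
               params = list(min_mean_relab = min_mean_relab,
                             min_present = min_present,
                             of_replicates = of_replicates,
                             abundance_stat = abundance_stat,
                             presence_scope = presence_scope))
}

#' Ties filter for correlation analysis
#'
#' Removes OTUs whose modal count value occurs in strictly more than
#' \code{max_tie_fraction} of the samples (usually the zero count) — such
#' OTUs would carry mostly tied ranks into the Spearman correlation. The
#' fraction is held exactly (default 2/3) and compared strictly, so an OTU
#' tied in exactly two-thirds of the samples is retained.
#'
#' @param x an [OtuExperiment-class] or an OTUs x samples count matrix with
#'   at least 3 samples.
#' @param max_tie_fraction maximal tolerated modal-count fraction.
#' @return a [RotuSet-class] with a \code{removed_by_ties} rule log.
#' @export
filterTies <- function(x, max_tie_fraction = 2 / 3) {
  m <- if (methods::is(x, "OtuExperiment")) counts(x) else as.matrix(x)
  if (ncol(m) < 3L) {
    stop("ties filter needs at least 3 samples", call. = FALSE)
  }
  if (!is.finite(max_tie_fraction) || max_tie_fraction <= 0 ||
      max_tie_fraction > 1) {
    stop("max_tie_fraction must lie in (0, 1]", call. = FALSE)
  }
  modal_fraction <- apply(m, 1L, function(v) max(table(v)) / length(v))
  retained <- modal_fraction <= max_tie_fraction
  log <- data.frame(otu_id = rownames(m), retained = retained,
                    removed_by_ties = !retained,
                    stringsAsFactors = FALSE, row.names = NULL)
  methods::new("RotuSet", retained = rownames(m)[retained], ruleLog = log,
               params = list(max_tie_fraction = max_tie_fraction))
}
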