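# Internal helpers and study-level constants.

# Factor levels of the storage experiment design. Sample identifiers follow
# the cultivar_timepoint_soil_replicate scheme but are treated as opaque
# strings; design factors always come from the metadata columns.
.CULTIVARS <- c("A", "F", "H", "LC")
.SOILS <- c("PS", "KA", "KB", "K", "T")
.TIMEPOINTS <- c("T0", "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T7_Sprouts")
.STABILITY_LEVELS <- c("short", "medium", "long")

.METADATA_COLUMNS <- c("sample_id", "cultivar", "soil", "timepoint",
                       "replicate", "storage_days")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed; NULL seed leaves the RNG alone.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a stage-specific seed from one global seed so that individual
# pipeline stages can be re-run in isolation with identical randomness.
.derive_seed <- function(seed, stage) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

.is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

.check_metadata_frame <- function(meta, strict = TRUE) {
  missing_cols <- setdiff(.METADATA_COLUMNS, colnames(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (strict) {
    .check_enum(meta$cultivar, .CULTIVARS, "cultivar")
    .check_enum(meta$soil, .SOILS, "soil")
    .check_enum(meta$timepoint, .TIMEPOINTS, "timepoint")
  }
  if (any(!is.finite(meta$storage_days)) || any(meta$storage_days <= 0)) {
    stop("storage_days must be positive and finite for every sample",
         call. = FALSE)
  }
  batch <- interaction(meta$cultivar, meta$soil, drop = TRUE)
  per_batch <- tapply(meta$storage_days, batch, function(d) length(unique(d)))
  if (any(per_batch > 1L)) {
    bad <- names(per_batch)[per_batch > 1L]
    stop("storage_days must be constant within a cultivar x soil batch; ",
         "violated by: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cell <- interaction(meta$cultivar, meta$soil, meta$timepoint, drop = TRUE)
  rep_dup <- tapply(meta$replicate, cell, anyDuplicated)
  if (any(rep_dup > 0L)) {
    bad <- names(rep_dup)[rep_dup > 0L]
    stop("replicate indices must be distinct within a ",
         "cultivar x soil x timepoint cell; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

.check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad)) {
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(levels, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
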