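#' Construct an OtuExperiment
#'
#' @param counts numeric matrix of read counts. Orientation is given by
#'   \code{otusAsRows}; internally OTUs are stored as rows (the
#'   SummarizedExperiment feature convention).
#' @param sampleData optional data.frame / DataFrame of per-sample design
#'   metadata with columns sample_id, cultivar, soil, timepoint, replicate,
#'   storage_days (see [readSampleData()]). Rows are matched to samples by
#'   sample_id.
#' @param taxonomy optional named character vector of lineage strings,
#'   names matching OTU ids.
#' @param otusAsRows logical; set \code{FALSE} when \code{counts} has samples
#'   as rows.
#' @param strict logical; validate design factor levels against the study's
#'   enumerations.
#' @return an [OtuExperiment-class] object.
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2", "s3")))
#' OtuExperiment(m)
#' @export
OtuExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                          otusAsRows = TRUE, strict = TRUE) {
  counts <- as.matrix(counts)
  if (!otusAsRows) counts <- t(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("OTU_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  storage.mode(counts) <- "double"
  row_df <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) {
      stop("taxonomy must be named by OTU id", call. = FALSE)
    }
    row_df$taxonomy <- unname(taxonomy[rownames(counts)])
  }
  col_df <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    .check_metadata_frame(sampleData, strict = strict)
    missing <- setdiff(colnames(counts), sampleData$sample_id)
    if (length(missing)) {
      stop("sample(s) present in counts but absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                             drop = FALSE]
    col_df <- S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = row_df, colData = col_df)
  methods::new("OtuExperiment", se)
}

#' @describeIn OtuExperiment read counts (OTUs x samples)
#' @param object an OtuExperiment.
#' @export
setMethod("counts", "OtuExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname tuberstab-generics
#' @export
setMethod("otuIds", "OtuExperiment", function(x) rownames(x))

#' @rdname tuberstab-generics
#' @export
setMethod("sampleIds", "OtuExperiment", function(x) colnames(x))

#' @rdname tuberstab-generics
#' @export
setMethod("sampleData", "OtuExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname tuberstab-generics
#' @export
setMethod("otuTaxonomy", "OtuExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"taxonomy" %in% colnames(rd)) {
    return(NULL)
  }
  stats::setNames(rd$taxonomy, rownames(x))
})

#' Per-sample relative abundances
#'
#' Converts counts to within-sample proportions. Returned as a samples x
#' OTUs matrix (the community-matrix convention used by downstream
#' correlation and classification steps) whose rows each sum to 1; zero
#' counts stay zero.
#'
#' @param x an [OtuExperiment-class] or a samples x OTUs count matrix.
#' @param ... unused.
#' @return numeric matrix, samples x OTUs, rows summing to 1.
#' @export
#' @rdname relativeAbundance
setMethod("relativeAbundance", "OtuExperiment", function(x, ...) {
  relativeAbundance(t(counts(x)))
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  totals <- rowSums(x)
  if (any(totals <= 0)) {
    bad <- rownames(x)[totals <= 0] %||% which(totals <= 0)
    stop("zero-total sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sweep(x, 1L, totals, "/")
})

setMethod("show", "OtuExperiment", function(object) {
  cat("OtuExperiment:", nrow(object), "OTUs x", ncol(object), "samples\n")
  tot <- colSums(counts(object))
  if (ncol(object)) {
    cat("  library sizes:", min(tot), "-", max(tot), "\n")
  }
  cd <- SummarizedExperiment::colData(object)
  design <- intersect(c("cultivar", "soil", "timepoint", "storage_days",
                        "stability_class"), colnames(cd))
  if (length(design)) {
    cat("  design columns:", paste(design, collapse = ", "), "\n")
  }
  if ("taxonomy" %in% colnames(SummarizedExperiment::rowData(object))) {
    cat("  taxonomy: present\n")
  }
})
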