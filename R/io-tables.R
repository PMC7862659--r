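# Reading and writing of count tables, sample metadata and key-OTU reports.
# All files are UTF-8, tab-delimited, "." decimal. The classic BIOM TSV
# dialect (one leading "#" comment line, header starting "#OTU ID") is
# accepted on read.

#' Read an OTU count table from TSV
#'
#' The first column holds identifiers for the row dimension; remaining
#' columns are counts. A non-numeric column named \code{taxonomy} is split
#' off as OTU lineages (otus-as-rows orientation). With
#' \code{orientation = "auto"}, rows are taken as OTUs when row identifiers
#' look like OTU ids (or a taxonomy column is present), as samples when
#' column identifiers do; otherwise the longer dimension is assumed to be
#' the OTUs.
#'
#' @param path TSV file path, optionally in the classic BIOM TSV dialect.
#' @param orientation one of \code{"auto"}, \code{"samples-as-rows"},
#'   \code{"otus-as-rows"}.
#' @param strict passed to [OtuExperiment()].
#' @return an [OtuExperiment-class] (no sample metadata attached; see
#'   [attachSampleData()]).
#' @export
readCountTable <- function(path,
                           orientation = c("auto", "samples-as-rows",
                                           "otus-as-rows"),
                           strict = TRUE) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  # BIOM TSV dialect: drop pure comment lines, un-comment the "#OTU ID"
  # header if present.
  is_comment <- startsWith(lines, "#")
  if (any(is_comment)) {
    header_idx <- which(startsWith(lines, "#OTU ID"))
    if (length(header_idx)) {
      lines[header_idx[1L]] <- sub("^#", "", lines[header_idx[1L]])
      is_comment[header_idx[1L]] <- FALSE
    }
    lines <- lines[!is_comment]
  }
  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate identifier(s) in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  tax_col <- which(tolower(colnames(df)) %in% c("taxonomy", "lineage"))
  if (length(tax_col)) {
    taxonomy <- stats::setNames(as.character(df[[tax_col[1L]]]), ids)
    df <- df[, -tax_col, drop = FALSE]
  }
  m <- as.matrix(df)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate identifier(s) in header: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | m < 0 | !.is_whole(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count at row '", ids[bad[1L, 1L]],
         "', column '", colnames(m)[bad[1L, 2L]], "'", call. = FALSE)
  }
  rownames(m) <- ids

  otus_as_rows <- switch(orientation,
    "otus-as-rows" = TRUE,
    "samples-as-rows" = FALSE,
    "auto" = {
      row_otu <- mean(grepl("^OTU", ids, ignore.case = TRUE))
      col_otu <- mean(grepl("^OTU", colnames(m), ignore.case = TRUE))
      if (!is.null(taxonomy) || row_otu > col_otu) TRUE
      else if (col_otu > row_otu) FALSE
      else nrow(m) >= ncol(m)
    })
  OtuExperiment(m, taxonomy = taxonomy, otusAsRows = otus_as_rows,
                strict = strict)
}

#' Write an OTU count table to TSV
#'
#' @param x an [OtuExperiment-class].
#' @param path output path.
#' @param otusAsRows orientation of the written table.
#' @param taxonomy include the taxonomy column when present (otus-as-rows
#'   only).
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(x, path, otusAsRows = TRUE, taxonomy = TRUE) {
  m <- counts(x)
  if (otusAsRows) {
    df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    tax <- otuTaxonomy(x)
    if (taxonomy && !is.null(tax)) df$taxonomy <- unname(tax[rownames(m)])
  } else {
    df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-sample design metadata from TSV
#'
#' Expected columns: sample_id, cultivar, soil, timepoint, replicate,
#' storage_days. Factor levels are validated against the study design
#' (cultivars A/F/H/LC, soils PS/KA/KB/K/T, timepoints T0..T7 and
#' T7_Sprouts) unless \code{strict = FALSE}; duplicated sample ids, unknown
#' levels, non-positive storage_days, storage_days varying within a
#' cultivar x soil batch, and replicate clashes within a design cell are
#' rejected.
#'
#' @param path TSV file path.
#' @param strict validate enumerations.
#' @return data.frame of validated metadata.
#' @export
readSampleData <- function(path, strict = TRUE) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  .check_metadata_frame(meta, strict = strict)
  meta
}

#' Write per-sample design metadata to TSV
#'
#' @param meta data.frame of metadata (or an [OtuExperiment-class], whose
#'   colData is written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleData <- function(meta, path) {
  if (methods::is(meta, "OtuExperiment")) meta <- sampleData(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach sample metadata to an OtuExperiment
#'
#' @param x an [OtuExperiment-class].
#' @param meta metadata data.frame as returned by [readSampleData()].
#' @param strict validate enumerations.
#' @return \code{x} with colData populated; errors list samples present in
#'   the counts but missing from the metadata.
#' @export
attachSampleData <- function(x, meta, strict = TRUE) {
  OtuExperiment(counts(x), sampleData = meta, taxonomy = otuTaxonomy(x),
                strict = strict)
}

.KEY_OTU_COLUMNS <- c("otu_id", "taxonomy", "direction", "r_storage",
                      "p_storage", "rf_importance_rank")

#' Write / read a key-OTU report
#'
#' The report is a TSV with columns otu_id, taxonomy, direction, r_storage,
#' p_storage, rf_importance_rank and round-trips losslessly through
#' \code{readKeyOtuReport}.
#'
#' @param keyOtus data.frame as returned by [intersectKeyOtus()] (may have
#'   zero rows).
#' @param path output path.
#' @return \code{path} invisibly (write); the report data.frame (read).
#' @export
writeKeyOtuReport <- function(keyOtus, path) {
  df <- as.data.frame(keyOtus)
  for (col in .KEY_OTU_COLUMNS) {
    if (!col %in% colnames(df)) df[[col]] <- rep(NA, nrow(df))
  }
  df <- df[, .KEY_OTU_COLUMNS, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeKeyOtuReport
#' @export
readKeyOtuReport <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(otu_id = "character",
                                         taxonomy = "character",
                                         direction = "character",
                                         r_storage = "numeric",
                                         p_storage = "numeric",
                                         rf_importance_rank = "integer"))
  df
}
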