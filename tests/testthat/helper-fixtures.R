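# Small in-code fixtures shared across test files.

toy_counts_path <- function() {
  system.file("extdata", "toy_counts.tsv", package = "tuberstab",
              mustWork = TRUE)
}

toy_metadata_path <- function() {
  system.file("extdata", "toy_metadata.tsv", package = "tuberstab",
              mustWork = TRUE)
}

toy_experiment <- function() {
  x <- readCountTable(toy_counts_path(), orientation = "otus-as-rows")
  attachSampleData(x, readSampleData(toy_metadata_path()))
}

# a minimal valid design: one cultivar x soil batch over `n_tp` timepoints
# with 3 replicates, random counts
random_experiment <- function(n_otus = 12, n_tp = 3, seed = 1,
                              days = 150) {
  withr::with_seed(seed, {
    tps <- c("T2", "T6", "T7")[seq_len(n_tp)]
    meta <- expand.grid(replicate = 1:3, timepoint = tps,
                        stringsAsFactors = FALSE)
    meta$cultivar <- "A"
    meta$soil <- "PS"
    meta$storage_days <- days
    meta$sample_id <- paste("A", meta$timepoint, "PS", meta$replicate,
                            sep = "_")
    m <- matrix(rpois(n_otus * nrow(meta), lambda = 40),
                nrow = n_otus,
                dimnames = list(paste0("OTU_", seq_len(n_otus)),
                                meta$sample_id))
    m[1L, ] <- m[1L, ] + 1L  # guarantee positive totals
    OtuExperiment(m, sampleData = meta)
  })
}

# metadata covering several batches with chosen per-batch storage days
batch_metadata <- function(days_by_batch) {
  n <- length(days_by_batch)
  cultivars <- rep(c("A", "F", "H", "LC"), length.out = n)
  soils <- rep(c("PS", "KA", "KB", "K", "T"), each = 4)[seq_len(n)]
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = paste(cultivars[i], "T2", soils[i], 1:3,
                                 sep = "_"),
               cultivar = cultivars[i], soil = soils[i], timepoint = "T2",
               replicate = 1:3, storage_days = days_by_batch[i],
               stringsAsFactors = FALSE)
  }))
}
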