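# End-to-end pipeline driver: simulate (or load) -> rOTU filter -> alpha /
# beta diversity -> stability classes -> per-stratum random forest -> ties
# filter -> Spearman network -> key OTUs, with a JSON manifest.

#' Pipeline configuration
#'
#' Collects all stage parameters with their defaults. Either
#' \code{simulate = TRUE} (with a [simulationConfig()]) or both
#' \code{counts_path} and \code{metadata_path} must be provided.
#'
#' @param simulate draw the study from the simulator.
#' @param sim a \code{simulation_config} used when \code{simulate}.
#' @param counts_path,metadata_path input TSVs when \code{simulate =
#'   FALSE}.
#' @param out_dir optional output directory; when set, all stage tables and
#'   a JSON manifest are written.
#' @param seed global seed; per-stage seeds are derived from it by
#'   stage-name hashing so single stages can be re-run in isolation.
#' @param min_mean_relab,min_present,of_replicates rOTU filter settings
#'   (see [filterRotus()]).
#' @param rarefaction_depth depth for alpha diversity; \code{NULL} = the
#'   minimum sample total.
#' @param n_perm permutations for the permutation ANOVA and PERMANOVA.
#' @param rf_strata colData column defining RF strata (default
#'   \code{"timepoint"}: one backward elimination per timepoint, selections
#'   pooled by union); \code{NULL} for a single pooled run.
#' @param n_trees,drop_fraction,se_multiplier RF settings (see
#'   [rfSelect()]).
#' @param r_threshold,p_threshold,network_mode network thresholds (see
#'   [thresholdNetwork()]).
#' @param storage_edge_only restrict key OTUs to those with a direct
#'   storage-node edge.
#' @return a \code{pipeline_config} list.
#' @export
pipelineConfig <- function(simulate = TRUE, sim = simulationConfig(),
                           counts_path = NULL, metadata_path = NULL,
                           out_dir = NULL, seed = NULL,
                           min_mean_relab = 1e-4, min_present = 2,
                           of_replicates = 3,
                           rarefaction_depth = NULL, n_perm = 999,
                           rf_strata = "timepoint", n_trees = 2000,
                           drop_fraction = 0.2, se_multiplier = 1,
                           r_threshold = 0.5, p_threshold = 0.001,
                           network_mode = "absolute",
                           storage_edge_only = FALSE) {
  if (!simulate && (is.null(counts_path) || is.null(metadata_path))) {
    stop("simulate = FALSE requires counts_path and metadata_path",
         call. = FALSE)
  }
  structure(list(simulate = simulate, sim = sim,
                 counts_path = counts_path, metadata_path = metadata_path,
                 out_dir = out_dir, seed = seed,
                 min_mean_relab = min_mean_relab,
                 min_present = min_present,
                 of_replicates = of_replicates,
                 rarefaction_depth = rarefaction_depth, n_perm = n_perm,
                 rf_strata = rf_strata, n_trees = n_trees,
                 drop_fraction = drop_fraction,
                 se_multiplier = se_multiplier,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 network_mode = network_mode,
                 storage_edge_only = storage_edge_only),
            class = "pipeline_config")
}

#' Run the full storage-stability analysis pipeline
#'
#' Executes every stage on simulated or loaded data and, when the input was
#' simulated, scores the recovery of the planted taxa against the ground
#' truth. With \code{out_dir} set, writes the rOTU rule log, alpha results,
#' PERMANOVA table, network edge list, key-OTU report and a JSON manifest
#' (parameters, derived seeds, file checksums, package version); two runs
#' with the same seed produce byte-identical reports.
#'
#' @param config a [pipelineConfig()] (or arguments for one via
#'   \code{...}).
#' @param ... passed to [pipelineConfig()] when \code{config} is missing.
#' @return list with the experiment, rotus, alpha / beta results, stability
#'   grouping, RF results, network, key_otus, truth and recovery metrics
#'   (when simulated), and written file paths.
#' @export
runPipeline <- function(config = NULL, ...) {
  config <- config %||% pipelineConfig(...)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # --- data ----------------------------------------------------------
  truth <- NULL
  if (config$simulate) {
    sim_cfg <- config$sim
    if (is.null(sim_cfg$seed)) {
      sim_cfg$seed <- .derive_seed(seed, "simulate")
    }
    sim <- simulateStudy(sim_cfg)
    x <- sim$experiment
    truth <- sim$truth
  } else {
    x <- readCountTable(config$counts_path)
    meta <- readSampleData(config$metadata_path)
    x <- attachSampleData(x, meta)
  }

  # --- rOTU filter ---------------------------------------------------
  rotus <- filterRotus(x, min_mean_relab = config$min_mean_relab,
                       min_present = config$min_present,
                       of_replicates = config$of_replicates)
  xr <- applyRotuFilter(x, rotus)

  # --- alpha diversity ----------------------------------------------
  xrare <- rarefyCounts(xr, depth = config$rarefaction_depth,
                        seed = .derive_seed(seed, "rarefy"))
  alpha <- data.frame(sample_id = sampleIds(xrare),
                      observed_richness = unname(observedRichness(xrare)),
                      simpson = unname(simpsonIndex(xrare)),
                      stringsAsFactors = FALSE)
  meta_r <- sampleData(xrare)
  test_factors <- Filter(
    function(nm) length(unique(meta_r[[nm]])) >= 2L,
    intersect(c("cultivar", "timepoint", "soil"), colnames(meta_r)))
  alpha_tests <- NULL
  if (length(test_factors)) {
    fl <- lapply(test_factors, function(nm) factor(meta_r[[nm]]))
    names(fl) <- test_factors
    rich <- permutationAnova(alpha$observed_richness, fl,
                             n_perm = config$n_perm,
                             seed = .derive_seed(seed, "anova_richness"))
    simp <- permutationAnova(alpha$simpson, fl, n_perm = config$n_perm,
                             seed = .derive_seed(seed, "anova_simpson"))
    rich$response <- "observed_richness"
    simp$response <- "simpson"
    alpha_tests <- rbind(rich, simp)
  }

  # --- beta diversity ------------------------------------------------
  meta_x <- sampleData(xr)
  bc <- brayCurtis(xr)
  beta_tests <- do.call(rbind, lapply(test_factors, function(nm) {
    res <- permanova(bc, factor(meta_x[[nm]]), n_perm = config$n_perm,
                     seed = .derive_seed(seed, paste0("permanova_", nm)))
    cbind(data.frame(factor = nm, stringsAsFactors = FALSE), res)
  }))
  ordination <- pcoaOrdination(bc)
  cap <- if ("timepoint" %in% test_factors) {
    capOrdination(bc, factor(meta_x$timepoint))
  } else {
    NULL
  }

  # --- stability classes and per-stratum RF -------------------------
  xr <- assignStabilityClasses(xr)
  meta_x <- sampleData(xr)
  strata <- config$rf_strata
  rf_results <- if (is.null(strata) ||
                    !strata %in% colnames(meta_x) ||
                    length(unique(meta_x[[strata]])) < 2L) {
    list(pooled = rfSelect(xr, "stability_class",
                           n_trees = config$n_trees,
                           drop_fraction = config$drop_fraction,
                           se_multiplier = config$se_multiplier,
                           seed = .derive_seed(seed, "rf_pooled")))
  } else {
    # one backward elimination per stratum plus one pooled over all
    # samples; selections are later pooled by union with origins recorded
    lv <- sort(unique(as.character(meta_x[[strata]])))
    res <- lapply(lv, function(l) {
      sub <- xr[, meta_x[[strata]] == l]
      rfSelect(sub, "stability_class", n_trees = config$n_trees,
               drop_fraction = config$drop_fraction,
               se_multiplier = config$se_multiplier,
               seed = .derive_seed(seed, paste0("rf_", l)))
    })
    names(res) <- lv
    res$pooled <- rfSelect(xr, "stability_class",
                           n_trees = config$n_trees,
                           drop_fraction = config$drop_fraction,
                           se_multiplier = config$se_multiplier,
                           seed = .derive_seed(seed, "rf_pooled"))
    res
  }

  # --- correlation network ------------------------------------------
  ties <- filterTies(xr)
  xt <- applyRotuFilter(xr, ties)
  sm <- spearmanMatrix(xt, storage_days = sampleData(xt)$storage_days)
  net <- thresholdNetwork(sm, r_threshold = config$r_threshold,
                          p_threshold = config$p_threshold,
                          mode = config$network_mode)

  # --- key OTUs ------------------------------------------------------
  relab <- relativeAbundance(xr)
  keys <- intersectKeyOtus(rf_results, net, relab = relab,
                           stability_class = meta_x$stability_class,
                           storage_edge_only = config$storage_edge_only)
  tax <- otuTaxonomy(xr)
  keys$taxonomy <- if (is.null(tax)) NA_character_ else
    unname(tax[keys$otu_id])

  # --- recovery vs truth --------------------------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- scoreRecovery(keys, truth)
  }

  result <- list(experiment = x, rotus = rotus, rarefied = xrare,
                 alpha = alpha, alpha_tests = alpha_tests,
                 bray_curtis = bc, beta_tests = beta_tests,
                 ordination = ordination, cap = cap,
                 stability = list(
                   classes = meta_x$stability_class,
                   cut_points = S4Vectors::metadata(xr)$stability$cut_points),
                 rf = rf_results, ties = ties, network = net,
                 key_otus = keys, truth = truth, recovery = recovery,
                 config = config, files = character())

  if (!is.null(config$out_dir)) {
    result$files <- .write_pipeline_outputs(result, config)
  }
  result
}

#' Score key-OTU recovery against the simulation truth
#'
#' @param keys key-OTU table from [intersectKeyOtus()].
#' @param truth a \code{simulation_truth}.
#' @return list: planted recovery percentage (planted OTUs reported with
#'   the correct direction), percentage of reported key OTUs that were not
#'   planted, and the underlying id sets.
#' @export
scoreRecovery <- function(keys, truth) {
  planted <- c(truth$planted_long, truth$planted_short)
  expected_dir <- stats::setNames(
    rep(c("long", "short"),
        c(length(truth$planted_long), length(truth$planted_short))),
    planted)
  reported <- keys$otu_id
  correct <- intersect(reported, planted)
  correct <- correct[keys$direction[match(correct, keys$otu_id)] ==
                       expected_dir[correct]]
  unplanted <- setdiff(reported, planted)
  list(
    n_planted = length(planted), n_reported = length(reported),
    recovered = correct, unplanted = unplanted,
    recovery_pct = if (length(planted)) 100 * length(correct) /
      length(planted) else NA_real_,
    unplanted_pct = if (length(reported)) 100 * length(unplanted) /
      length(reported) else 0)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()
  writeCountTable(result$experiment, out("counts.tsv"))
  files <- c(files, out("counts.tsv"))
  writeSampleData(result$experiment, out("metadata.tsv"))
  files <- c(files, out("metadata.tsv"))
  utils::write.table(ruleLog(result$rotus), out("rotu_rule_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, out("rotu_rule_log.tsv"))
  utils::write.table(result$alpha, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("alpha_diversity.tsv"))
  if (!is.null(result$alpha_tests)) {
    utils::write.table(result$alpha_tests, out("alpha_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, out("alpha_tests.tsv"))
  }
  if (!is.null(result$beta_tests)) {
    utils::write.table(result$beta_tests, out("permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("permanova.tsv"))
  }
  utils::write.table(networkEdges(result$network), out("network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, out("network_edges.tsv"))
  writeKeyOtuReport(result$key_otus, out("key_otus.tsv"))
  files <- c(files, out("key_otus.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("tuberstab")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("sim", "out_dir"))],
    simulation = if (config$simulate) {
      config$sim[setdiff(names(config$sim), "seed")]
    } else {
      NULL
    },
    recovery = if (!is.null(result$recovery)) {
      result$recovery[c("n_planted", "n_reported", "recovery_pct",
                        "unplanted_pct")]
    } else {
      NULL
    },
    n_rotus = length(retainedOtus(result$rotus)),
    n_key_otus = nrow(result$key_otus),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files <- c(files, out("manifest.json"))
  files
}
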