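# Dirichlet-multinomial simulation of a storage study with planted
# storage-associated taxa, and an in vitro sprouting-assay simulator.

#' Configuration for the study simulator
#'
#' Defaults emulate the structure of the storage experiment at desk scale:
#' a 3 cultivar x 3 soil x 3 timepoint design with 3 replicate tubers per
#' cell (81 samples), 500 OTUs with a log-normal baseline composition,
#' batch-level storage times spread over 135-169 days, planted taxa whose
#' expected relative abundance changes log-linearly with storage days
#' (+effect_size per day for the "long" set, -effect_size for the "short"
#' set), and a timepoint-indexed community shift on a subset of OTUs.
#' Counts are Dirichlet-multinomial: per-sample proportions are drawn from
#' a Dirichlet around the sample's expected composition (precision
#' \code{concentration}) and reads from a multinomial at the sample's
#' library size.
#'
#' @param cultivars,soils,timepoints design factor levels (subsets of the
#'   study enumerations).
#' @param n_replicates replicate tubers per cultivar x soil x timepoint
#'   cell.
#' @param n_otus total number of OTUs.
#' @param n_long_otus,n_short_otus planted taxa counts (their sum must not
#'   exceed \code{n_otus}).
#' @param effect_size per-day log relative-abundance slope of planted taxa
#'   (default 0.02/day, about 2-fold over a 34-day spread).
#' @param storage_days_range batch-level days from harvest to sprouting are
#'   drawn (distinct, uniform) from this range.
#' @param library_size_range per-sample read totals, uniform integers
#'   (minimum 100).
#' @param base_log_sigma log-normal spread of the baseline composition.
#' @param planted_base_relab baseline relative abundance given to each
#'   planted taxon.
#' @param concentration Dirichlet precision of the replicate-to-replicate
#'   compositional noise.
#' @param shift_strength total log-fold change of shifted OTUs between the
#'   first and last timepoint (random sign per OTU).
#' @param shift_fraction fraction of (unplanted) OTUs participating in the
#'   timepoint shift.
#' @param seed integer seed; the emitted study is fully reproducible given
#'   it.
#' @return a validated \code{simulation_config} list.
#' @export
simulationConfig <- function(cultivars = c("A", "H", "LC"),
                             soils = c("PS", "KA", "K"),
                             timepoints = c("T2", "T6", "T7"),
                             n_replicates = 3,
                             n_otus = 500,
                             n_long_otus = 10, n_short_otus = 10,
                             effect_size = 0.02,
                             storage_days_range = c(135, 169),
                             library_size_range = c(7000, 40000),
                             base_log_sigma = 1.5,
                             planted_base_relab = 0.01,
                             concentration = 5000,
                             shift_strength = 1.2,
                             shift_fraction = 0.01,
                             seed = NULL) {
  cfg <- list(cultivars = cultivars, soils = soils, timepoints = timepoints,
              n_replicates = n_replicates, n_otus = n_otus,
              n_long_otus = n_long_otus, n_short_otus = n_short_otus,
              effect_size = effect_size,
              storage_days_range = storage_days_range,
              library_size_range = library_size_range,
              base_log_sigma = base_log_sigma,
              planted_base_relab = planted_base_relab,
              concentration = concentration,
              shift_strength = shift_strength,
              shift_fraction = shift_fraction, seed = seed)
  .check_enum(cultivars, .CULTIVARS, "cultivar")
  .check_enum(soils, .SOILS, "soil")
  .check_enum(timepoints, .TIMEPOINTS, "timepoint")
  if (n_long_otus + n_short_otus > n_otus) {
    stop("n_long_otus + n_short_otus must not exceed n_otus", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (min(library_size_range) < 100) {
    stop("library sizes must be at least 100", call. = FALSE)
  }
  if (length(storage_days_range) != 2L ||
      storage_days_range[1L] > storage_days_range[2L] ||
      storage_days_range[1L] <= 0) {
    stop("storage_days_range must be an ordered positive pair",
         call. = FALSE)
  }
  n_planted <- n_long_otus + n_short_otus
  if (n_planted * planted_base_relab >= 0.9) {
    stop("planted taxa would occupy >= 90% of the community", call. = FALSE)
  }
  if (concentration <= 0 || shift_strength < 0 || shift_fraction < 0 ||
      shift_fraction > 1) {
    stop("invalid noise/shift settings", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a storage study
#'
#' Draws a full study — OTU counts, design metadata and the generating
#' ground truth — from a [simulationConfig()]. Per sample, the expected
#' composition is the baseline perturbed by the planted storage-day effects
#' and the timepoint shift; observed proportions are
#' Dirichlet(concentration x expected) and counts multinomial at the
#' sample's library size. Each sample's counts sum exactly to its drawn
#' library size, and each expected composition sums to 1.
#'
#' @param config a \code{simulation_config} (or arguments for one via
#'   \code{...}).
#' @param ... passed to [simulationConfig()] when \code{config} is missing.
#' @return list with \code{experiment} (an [OtuExperiment-class] with
#'   metadata and placeholder taxonomy) and \code{truth} (class
#'   \code{simulation_truth}): planted id sets, shifted ids and signs,
#'   batch storage days, the samples x OTUs expected-composition matrix and
#'   the config.
#' @export
simulateStudy <- function(config = NULL, ...) {
  config <- config %||% simulationConfig(...)
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cfg) {
  otu_ids <- sprintf("OTU_%d", seq_len(cfg$n_otus))
  n_planted <- cfg$n_long_otus + cfg$n_short_otus
  planted <- sample(otu_ids, n_planted)
  planted_long <- planted[seq_len(cfg$n_long_otus)]
  planted_short <- setdiff(planted, planted_long)

  # baseline composition: log-normal weights; planted taxa pinned to the
  # target baseline relative abundance
  w <- stats::rlnorm(cfg$n_otus, meanlog = 0, sdlog = cfg$base_log_sigma)
  names(w) <- otu_ids
  others <- setdiff(otu_ids, planted)
  if (n_planted > 0L) {
    v <- cfg$planted_base_relab * sum(w[others]) /
      (1 - n_planted * cfg$planted_base_relab)
    w[planted] <- v
  }

  # timepoint-shifted subset with random sign
  n_shift <- round(cfg$shift_fraction * cfg$n_otus)
  shifted <- if (n_shift > 0L) sample(others, min(n_shift, length(others)))
             else character()
  shift_sign <- stats::setNames(sample(c(-1, 1), length(shifted),
                                       replace = TRUE), shifted)

  # design and batch-level storage days (distinct where possible)
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      timepoint = cfg$timepoints, soil = cfg$soils,
                      cultivar = cfg$cultivars, stringsAsFactors = FALSE)
  grid <- grid[, c("cultivar", "soil", "timepoint", "replicate")]
  batches <- unique(grid[, c("cultivar", "soil")])
  # batch-level sprouting times span the configured range evenly (the
  # storage experiment tracks every batch to its own sprouting date) and
  # are assigned to batches at random
  n_batches <- nrow(batches)
  batches$storage_days <- if (n_batches == 1L) {
    mean(cfg$storage_days_range)
  } else {
    day_grid <- seq(cfg$storage_days_range[1L], cfg$storage_days_range[2L],
                    length.out = n_batches)
    round(sample(day_grid), 1L)
  }
  meta <- merge(grid, batches, by = c("cultivar", "soil"), sort = FALSE)
  meta$sample_id <- paste(meta$cultivar, meta$timepoint, meta$soil,
                          meta$replicate, sep = "_")
  meta <- meta[order(meta$cultivar, meta$soil, meta$timepoint,
                     meta$replicate), ]
  meta <- meta[, c("sample_id", "cultivar", "soil", "timepoint",
                   "replicate", "storage_days")]
  rownames(meta) <- NULL
  n_samples <- nrow(meta)

  # expected composition per sample
  mid_day <- mean(cfg$storage_days_range)
  tp_index <- match(meta$timepoint, cfg$timepoints)
  tp_scaled <- if (length(cfg$timepoints) > 1L) {
    (tp_index - 1) / (length(cfg$timepoints) - 1) - 0.5
  } else {
    rep(0, n_samples)
  }
  logw <- matrix(log(w), nrow = n_samples, ncol = cfg$n_otus,
                 byrow = TRUE, dimnames = list(meta$sample_id, otu_ids))
  day_c <- meta$storage_days - mid_day
  if (length(planted_long)) {
    logw[, planted_long] <- logw[, planted_long] +
      cfg$effect_size * day_c
  }
  if (length(planted_short)) {
    logw[, planted_short] <- logw[, planted_short] -
      cfg$effect_size * day_c
  }
  if (length(shifted)) {
    logw[, shifted] <- logw[, shifted] +
      outer(tp_scaled, cfg$shift_strength * shift_sign[shifted])
  }
  expected <- exp(logw)
  expected <- expected / rowSums(expected)

  # Dirichlet-multinomial draw
  lib_sizes <- sample(seq(cfg$library_size_range[1L],
                          cfg$library_size_range[2L]),
                      n_samples, replace = TRUE)
  counts <- matrix(0, nrow = cfg$n_otus, ncol = n_samples,
                   dimnames = list(otu_ids, meta$sample_id))
  for (s in seq_len(n_samples)) {
    alpha <- cfg$concentration * expected[s, ]
    gam <- stats::rgamma(cfg$n_otus, shape = alpha, rate = 1)
    if (sum(gam) <= 0) gam <- alpha
    p <- gam / sum(gam)
    counts[, s] <- stats::rmultinom(1L, size = lib_sizes[s], prob = p)
  }

  taxonomy <- stats::setNames(
    sprintf("Bacteria;SimPhylum_%d;SimGenus_%d",
            (seq_len(cfg$n_otus) - 1L) %% 10L + 1L, seq_len(cfg$n_otus)),
    otu_ids)
  exp_obj <- OtuExperiment(counts, sampleData = meta, taxonomy = taxonomy)
  truth <- structure(list(planted_long = planted_long,
                          planted_short = planted_short,
                          shifted = shifted, shift_sign = shift_sign,
                          batch_days = batches,
                          expected_composition = expected,
                          library_sizes = stats::setNames(lib_sizes,
                                                          meta$sample_id),
                          config = cfg),
                     class = "simulation_truth")
  list(experiment = exp_obj, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", length(x$planted_long), "long +",
      length(x$planted_short), "short planted OTUs,",
      length(x$shifted), "timepoint-shifted OTUs\n")
  invisible(x)
}

#' Simulate an in vitro sprouting assay
#'
#' Each bud disc follows a monotone stochastic progression through the
#' first principal BBCH growth stages (codes 00, 01, 02, 03, 05): over
#' \code{n_days} scoring days the disc advances one ordinal stage with its
#' treatment's daily probability, capped at stage 05. Treatments with rate
#' 0 stay at stage 00 (dormancy); inhibitor treatments therefore have
#' lower final stage sums in expectation.
#'
#' @param rates named numeric vector of per-day stage-advance
#'   probabilities, one per treatment (all >= 0; values above 1 are capped).
#' @param n_discs bud discs per treatment and repetition (default 6).
#' @param n_repetitions assay repetitions (default 2).
#' @param n_days scoring days until the assay ends (default 10; in the wet
#'   assay this endpoint is reached when maleic-hydrazide discs show stage
#'   01).
#' @param varieties character vector of tuber varieties screened; discs are
#'   balanced over them.
#' @param seed integer seed.
#' @return an assay table: data.frame with disc_id, treatment, variety,
#'   repetition, stage (numeric BBCH code in 0/1/2/3/5).
#' @export
simulateAssay <- function(rates, n_discs = 6, n_repetitions = 2,
                          n_days = 10, varieties = "LC", seed = NULL) {
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be named by treatment", call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  stage_codes <- c(0, 1, 2, 3, 5)
  .with_seed(seed, {
    rows <- list()
    for (trt in names(rates)) {
      pr <- min(rates[[trt]], 1)
      for (rep_i in seq_len(n_repetitions)) {
        for (v in varieties) {
          adv <- stats::rbinom(n_discs, size = n_days, prob = pr)
          stage_idx <- pmin(adv, length(stage_codes) - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            treatment = trt, variety = v, repetition = rep_i,
            stage = stage_codes[stage_idx + 1L],
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out$disc_id <- sprintf("disc_%03d", seq_len(nrow(out)))
    out[, c("disc_id", "treatment", "variety", "repetition", "stage")]
  })
}
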