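# Statistics for the in vitro sprouting assay: BBCH stage sums, a one-way
# linear model with ANOVA, and estimated-marginal-mean contrasts of each
# treatment against the medium control.

.ASSAY_STAGES <- c(0, 1, 2, 3, 5)

.check_assay <- function(assay) {
  needed <- c("treatment", "repetition", "stage")
  if (!all(needed %in% colnames(assay))) {
    stop("assay table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(assay$stage), .ASSAY_STAGES)
  if (length(bad)) {
    stop("invalid BBCH stage code(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.ASSAY_STAGES, collapse = ", "),
         call. = FALSE)
  }
  if (any(table(assay$treatment) < 1L)) {
    stop("every treatment needs at least one disc", call. = FALSE)
  }
  invisible(assay)
}

#' BBCH stage sums per treatment and repetition
#'
#' Sums the final BBCH stage codes of all discs within a treatment x
#' repetition, and averages those sums over repetitions per treatment (the
#' assay's reporting summary).
#'
#' @param assay assay table as from [simulateAssay()] (columns treatment,
#'   repetition, stage).
#' @return list with \code{per_repetition} (treatment, repetition,
#'   stage_sum) and \code{treatment_means} (treatment, mean_stage_sum).
#' @export
stageSums <- function(assay) {
  .check_assay(assay)
  agg <- stats::aggregate(stage ~ treatment + repetition, data = assay,
                          FUN = sum)
  names(agg)[names(agg) == "stage"] <- "stage_sum"
  agg <- agg[order(agg$treatment, agg$repetition), ]
  rownames(agg) <- NULL
  means <- stats::aggregate(stage_sum ~ treatment, data = agg, FUN = mean)
  names(means)[names(means) == "stage_sum"] <- "mean_stage_sum"
  list(per_repetition = agg, treatment_means = means)
}

#' Linear model, ANOVA and treatment-vs-control contrasts
#'
#' Fits a one-way linear model of the per-disc final stage on treatment
#' (optionally with variety as an additive factor), reports the overall
#' ANOVA, and contrasts every non-control treatment against the medium
#' control via estimated marginal means with a many-to-one (Dunnett-style)
#' multiplicity adjustment. Treatments with a negative estimate and
#' adjusted p below \code{alpha} are flagged as sprouting inhibitors.
#'
#' @param assay assay table (columns treatment, stage, optionally variety).
#' @param control control treatment contrasted against (default
#'   \code{"TSB10"}, the sterile 10\% tryptic-soy-broth medium).
#' @param adjust \code{"dunnett"} (deterministic multivariate-t
#'   approximation), \code{"bonferroni"}, or \code{"none"}.
#' @param include_variety add variety as an additive factor.
#' @param alpha significance level for the inhibitor flag.
#' @return list with \code{anova} (data.frame), \code{emmeans} (per
#'   treatment), and \code{contrasts} (treatment, estimate, SE, df, t,
#'   p_adjusted, inhibitor).
#' @export
fitAndContrast <- function(assay, control = "TSB10",
                           adjust = c("dunnett", "bonferroni", "none"),
                           include_variety = FALSE, alpha = 0.05) {
  adjust <- match.arg(adjust)
  .check_assay(assay)
  assay$treatment <- factor(assay$treatment)
  if (nlevels(assay$treatment) < 2L) {
    stop("need at least 2 treatments", call. = FALSE)
  }
  if (any(table(assay$treatment) < 2L)) {
    stop("every treatment needs at least 2 discs", call. = FALSE)
  }
  if (!control %in% levels(assay$treatment)) {
    stop("control treatment '", control, "' absent from the assay",
         call. = FALSE)
  }
  assay$treatment <- stats::relevel(assay$treatment, ref = control)
  if (stats::var(assay$stage) == 0) {
    # degenerate assay: no variation anywhere, nothing to test
    trts <- setdiff(levels(assay$treatment), control)
    an <- data.frame(term = c("treatment", "Residuals"),
                     Df = c(nlevels(assay$treatment) - 1L,
                            nrow(assay) - nlevels(assay$treatment)),
                     `Sum Sq` = c(0, 0), `Mean Sq` = c(0, 0),
                     `F value` = c(0, NA), `Pr(>F)` = c(1, NA),
                     check.names = FALSE)
    ct <- data.frame(treatment = trts, estimate = 0, SE = NA_real_,
                     df = nrow(assay) - nlevels(assay$treatment),
                     t = NA_real_, p_adjusted = 1, inhibitor = FALSE,
                     stringsAsFactors = FALSE)
    emm_df <- data.frame(treatment = levels(assay$treatment),
                         emmean = assay$stage[1L], stringsAsFactors = FALSE)
    return(list(anova = an, emmeans = emm_df, contrasts = ct, model = NULL,
                alpha = alpha, control = control, adjust = adjust))
  }
  form <- if (include_variety && "variety" %in% colnames(assay) &&
              length(unique(assay$variety)) > 1L) {
    stage ~ treatment + variety
  } else {
    stage ~ treatment
  }
  fit <- stats::lm(form, data = assay)
  an <- as.data.frame(stats::anova(fit))
  an <- data.frame(term = rownames(an), an, check.names = FALSE,
                   row.names = NULL)
  emm <- emmeans::emmeans(fit, "treatment")
  emm_adjust <- switch(adjust, dunnett = "dunnettx",
                       bonferroni = "bonferroni", none = "none")
  ct <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = control,
                          adjust = emm_adjust)
  ct_df <- as.data.frame(summary(ct))
  out <- data.frame(
    treatment = sub(" - .*$", "", ct_df$contrast),
    estimate = ct_df$estimate, SE = ct_df$SE, df = ct_df$df,
    t = ct_df$t.ratio, p_adjusted = ct_df$p.value,
    stringsAsFactors = FALSE)
  out$inhibitor <- out$estimate < 0 & out$p_adjusted < alpha
  list(anova = an, emmeans = as.data.frame(summary(emm)), contrasts = out,
       model = fit, alpha = alpha, control = control, adjust = adjust)
}
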