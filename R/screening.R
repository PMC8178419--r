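#' Thermostability activity: percent of activity retained after heat
#'
#' The modeled response of a loop-walking screen: the ratio of residual
#' enzymatic activity after heat treatment (here 60 degC, 30 min) to the
#' activity without heat treatment, as a percentage. The reporting
#' convention rounds to the nearest integer percent; the unrounded value is
#' returned alongside.
#'
#' @param activity_no_heat Activity without heat treatment (U/mL); must be
#'   positive.
#' @param residual_activity Activity after heat treatment (U/mL);
#'   non-negative.
#' @return Numeric vector of unrounded percentages with attribute
#'   `"reported"` holding the integer-rounded values.
#' @export
#' @examples
#' thermostability_activity(1000, 52)   # 5.2, reported 5
#' thermostability_activity(1220, 800)  # 65.6, reported 66
thermostability_activity <- function(activity_no_heat, residual_activity) {
  if (any(!is.finite(activity_no_heat)) || any(activity_no_heat <= 0)) {
    stop("activity_no_heat must be positive and finite", call. = FALSE)
  }
  if (any(residual_activity < 0)) {
    stop("residual_activity must be non-negative", call. = FALSE)
  }
  pct <- 100 * residual_activity / activity_no_heat
  attr(pct, "reported") <- round(pct)
  pct
}

#' Activities of a mutant relative to the wild-type enzyme
#'
#' Expresses a mutant's no-heat activity and residual activity as
#' percentages of the wild-type values measured in the same run, the axes of
#' the quadrant plot. Headline reporting rounds the relative residual
#' activity to two significant figures (so 1076.9 percent is reported as
#' 1100 percent).
#'
#' @param mutant,wildtype Lists or one-row data frames with elements
#'   `activity_no_heat` and `residual_activity` (same units).
#' @return List with `rel_activity_vs_wt`, `rel_residual_vs_wt`,
#'   `percent_retained` (all unrounded percentages) and
#'   `rel_residual_reported` (two significant figures).
#' @export
#' @examples
#' wt <- list(activity_no_heat = 1000, residual_activity = 52)
#' mu <- list(activity_no_heat = 1580, residual_activity = 560)
#' relative_to_wildtype(mu, wt)$rel_residual_reported  # 1100
relative_to_wildtype <- function(mutant, wildtype) {
  if (wildtype$activity_no_heat <= 0) {
    stop("wild-type activity_no_heat must be positive", call. = FALSE)
  }
  if (wildtype$residual_activity <= 0) {
    stop("wild-type residual activity is zero: relative residual undefined",
         call. = FALSE)
  }
  rel_act <- 100 * mutant$activity_no_heat / wildtype$activity_no_heat
  rel_res <- 100 * mutant$residual_activity / wildtype$residual_activity
  list(
    rel_activity_vs_wt = rel_act,
    rel_residual_vs_wt = rel_res,
    percent_retained = as.numeric(
      thermostability_activity(mutant$activity_no_heat,
                               mutant$residual_activity)),
    rel_residual_reported = signif(rel_res, 2)
  )
}

#' Quadrant classification of a mutant against wild-type
#'
#' Partitions the (relative activity, relative residual activity) plane at
#' the wild-type point (100 percent, 100 percent): quadrant I means both
#' improved (the ideal variant), II thermostability improved only, III both
#' reduced, IV activity improved only. Values exactly equal to 100 percent
#' are classed as non-improved.
#'
#' @param rel_activity_vs_wt,rel_residual_vs_wt Percentages relative to
#'   wild-type; vectors recycle.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' quadrant_classify(158, 1100)  # I
quadrant_classify <- function(rel_activity_vs_wt, rel_residual_vs_wt) {
  if (any(!is.finite(rel_activity_vs_wt)) || any(!is.finite(rel_residual_vs_wt))) {
    stop("relative measures must be finite", call. = FALSE)
  }
  act_up <- rel_activity_vs_wt > 100
  res_up <- rel_residual_vs_wt > 100
  q <- ifelse(act_up & res_up, "I",
       ifelse(!act_up & res_up, "II",
       ifelse(!act_up & !res_up, "III", "IV")))
  factor(q, levels = c("I", "II", "III", "IV"))
}

#' Hit rate of a selection
#'
#' Fraction of selected variants meeting a success criterion (for example
#' landing in quadrant I, or exceeding wild-type residual activity), with
#' the counts retained for reporting "k out of n" style rates.
#'
#' @param success Logical vector, one entry per assayed variant.
#' @return List with `successes`, `total`, `fraction` and `percent`.
#' @export
#' @examples
#' hit_rate(c(rep(TRUE, 16), rep(FALSE, 4)))$percent  # 80
hit_rate <- function(success) {
  if (!length(success)) stop("empty selection: hit rate undefined", call. = FALSE)
  if (anyNA(success)) stop("success indicators must not be NA", call. = FALSE)
  k <- sum(success)
  n <- length(success)
  list(successes = k, total = n, fraction = k / n, percent = 100 * k / n)
}

#' Synergy of a triple mutation beyond its three single mutations
#'
#' The null model for combining ratio-valued effects is multiplicative: if
#' the three single substitutions acted independently, the triple's residual
#' activity relative to wild-type would be the product of the three single
#' relative residual activities. The score works in log10 space, where that
#' null is additive: `synergy = log10(triple) - sum(log10(singles))`, all as
#' fractions of wild-type. Positive synergy means the triple outperforms the
#' independence expectation.
#'
#' @param triple_rel_residual Relative residual activity of the triple
#'   mutant, percent of wild-type.
#' @param single_rel_residuals Numeric vector of 3 single-mutant relative
#'   residual activities, percent of wild-type.
#' @return List with `observed_log_rel_residual`,
#'   `expected_log_rel_residual` and `synergy` (log10 units).
#' @export
#' @examples
#' synergy_score(1100, c(327, 45, 62))$synergy  # about +1.08
synergy_score <- function(triple_rel_residual, single_rel_residuals) {
  stopifnot(length(single_rel_residuals) == 3L)
  if (triple_rel_residual <= 0 || any(single_rel_residuals <= 0)) {
    stop("relative residual activities must be positive (log undefined at 0)",
         call. = FALSE)
  }
  obs <- log10(triple_rel_residual / 100)
  exp_ <- sum(log10(single_rel_residuals / 100))
  list(observed_log_rel_residual = obs,
       expected_log_rel_residual = exp_,
       synergy = obs - exp_)
}

#' Quadrant summary of a whole screen
#'
#' Convenience wrapper computing relative measures and quadrant labels for
#' every mutant record against the wild-type record.
#'
#' @param records Data frame of mutant records with columns `variant_id`,
#'   `activity_no_heat`, `residual_activity`.
#' @param wildtype One-row data frame or list for the wild-type enzyme.
#' @return Data frame with relative measures, reported values and quadrant
#'   per record.
#' @export
screen_summary <- function(records, wildtype) {
  rel <- lapply(seq_len(nrow(records)), function(i) {
    relative_to_wildtype(records[i, ], wildtype)
  })
  out <- data.frame(
    variant_id = records$variant_id,
    rel_activity_vs_wt = vapply(rel, `[[`, numeric(1), "rel_activity_vs_wt"),
    rel_residual_vs_wt = vapply(rel, `[[`, numeric(1), "rel_residual_vs_wt"),
    percent_retained = vapply(rel, `[[`, numeric(1), "percent_retained"),
    rel_residual_reported = vapply(rel, `[[`, numeric(1), "rel_residual_reported"),
    stringsAsFactors = FALSE
  )
  out$percent_retained_reported <- round(out$percent_retained)
  out$quadrant <- quadrant_classify(out$rel_activity_vs_wt,
                                    out$rel_residual_vs_wt)
  out
}
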