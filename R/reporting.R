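#' Assemble the factor effect table
#'
#' One row per factor in factor-id order, with exposed counts rendered as
#' `"n (pct)"` (percentages of the split size at 1 decimal place), odds
#' ratios and confidence bounds rounded half-away-from-zero at 2 decimal
#' places, and p-values below 1e-4 displayed as `"<0.0001"`. Raw numeric
#' columns are kept alongside the rendered ones so the display round-trips
#' to the stored values.
#'
#' @param effects an `effect_estimates` data frame from [evaluate_factors()].
#' @param factors optional list of factor definitions; adds a member-code
#'   column (semicolon-separated).
#' @return Data frame with rendered columns `case_freq`, `ref_freq`,
#'   `or_ci`, `p_display` plus the raw numeric columns.
#' @export
build_factor_table <- function(effects, factors = NULL) {
  stopifnot(nrow(effects) >= 1L)
  o <- order(effects$factor_id)
  e <- effects[o, , drop = FALSE]
  out <- data.frame(
    factor_id = e$factor_id,
    case_freq = sprintf("%d (%s)", e$n_case, fmt_fixed(e$pct_case, 1)),
    ref_freq = sprintf("%d (%s)", e$n_ref, fmt_fixed(e$pct_ref, 1)),
    or_ci = ifelse(is.finite(e$or),
                   sprintf("%s [%s, %s]", fmt_fixed(e$or, 2),
                           fmt_fixed(e$ci_low, 2), fmt_fixed(e$ci_high, 2)),
                   e$flag),
    p_display = ifelse(is.na(e$p_value), "",
                       ifelse(e$p_value < 1e-4, "<0.0001",
                              fmt_fixed(e$p_value, 4))),
    stringsAsFactors = FALSE)
  if (!is.null(factors)) {
    members <- vapply(factors, function(f)
      paste(f$member_codes, collapse = ";"), "")
    out$member_codes <- members[match(out$factor_id,
                                      vapply(factors, `[[`, 0L,
                                             "factor_id"))]
  }
  cbind(out, e[, c("n_case", "pct_case", "n_ref", "pct_ref", "or",
                   "ci_low", "ci_high", "p_value", "flag")],
        row.names = NULL)
}

#' Word-cloud weight specification
#'
#' The canonical word-cloud artifact is a deterministic factor-to-weight
#' mapping (rendered layouts are engine-dependent): the raw weight is the
#' case exposure count (mode `"frequency"`) or the odds-ratio point estimate
#' (mode `"odds_ratio"`), rescaled linearly to the font range, so weight
#' ordering is preserved. A single factor maps to the midpoint of the range.
#'
#' @param effects an `effect_estimates` data frame.
#' @param mode `"frequency"` or `"odds_ratio"`.
#' @param font_range numeric length-2 font-size range.
#' @return Data frame `factor_id`, `weight`, `font_size` (factors with
#'   nonpositive or non-finite weights are dropped).
#' @export
wordcloud_weights <- function(effects, mode = c("frequency", "odds_ratio"),
                              font_range = c(10, 60)) {
  mode <- match.arg(mode)
  w <- switch(mode, frequency = effects$n_case, odds_ratio = effects$or)
  keep <- is.finite(w) & w > 0
  w <- w[keep]
  id <- effects$factor_id[keep]
  if (length(w) == 0L)
    stop("no factor has a positive finite weight", call. = FALSE)
  rng <- range(w)
  font <- if (diff(rng) == 0) {
    rep(mean(font_range), length(w))
  } else {
    font_range[1] + (w - rng[1]) / diff(rng) * diff(font_range)
  }
  data.frame(factor_id = id, weight = w, font_size = font)
}

#' Cohort summary table
#'
#' Counts and percentages for the matching covariates plus per-arm visit
#' statistics. Visit means are reported both overall and restricted to the
#' pre-index lookback window (the study frame).
#'
#' @param cohort a [matched_cohort()].
#' @param visits long-format visit table.
#' @param lookback_days,exclusion_days window for the in-window visit count.
#' @return List with elements `n_pairs`, `covariates` (data frame), and
#'   `visits` (per-arm mean/SD of total and in-window visit counts).
#' @export
summarize_cohort <- function(cohort, visits, lookback_days = 1825L,
                             exclusion_days = 30L) {
  stopifnot(inherits(cohort, "matched_cohort"))
  p <- cohort$pairs
  if (nrow(p) == 0L) stop("empty-summary: cohort has no pairs", call. = FALSE)
  cov <- data.frame(
    statistic = c("male_pct", "female_pct", "age_mean", "age_sd",
                  sprintf("income_q%d_pct", 1:5), "rural_pct"),
    value = c(100 * mean(p$sex == "M"), 100 * mean(p$sex == "F"),
              mean(p$age), stats::sd(p$age),
              vapply(1:5, function(q)
                100 * mean(p$income_quintile == q), 0),
              100 * mean(p$rural == 1)))
  enc <- unique(visits[, c("patient_id", "visit_id", "visit_date")])
  idx <- cohort$index_dates
  arm_stats <- function(ids) {
    e <- enc[enc$patient_id %in% ids, , drop = FALSE]
    total <- tabulate(match(e$patient_id, ids), nbins = length(ids))
    off <- as.integer(idx[e$patient_id]) - as.integer(e$visit_date)
    inw <- off > exclusion_days & off <= lookback_days
    inwin <- tabulate(match(e$patient_id[inw], ids), nbins = length(ids))
    c(mean_visits = mean(total), sd_visits = stats::sd(total),
      mean_inwindow = mean(inwin), sd_inwindow = stats::sd(inwin))
  }
  vt <- rbind(case = arm_stats(p$case_id),
              reference = arm_stats(p$reference_id))
  list(n_pairs = nrow(p),
       covariates = cov,
       visits = as.data.frame(vt))
}
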