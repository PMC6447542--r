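#' Screening configuration
#'
#' @param q FDR level for the Benjamini-Yekutieli procedure (default 0.05).
#' @param test_variant `"asymptotic"`, `"exact"`, or `"auto"` (exact binomial
#'   when the discordant total is below `small_count_threshold`, else the
#'   asymptotic chi-squared statistic without continuity correction).
#' @param small_count_threshold discordant-total threshold for `"auto"`
#'   (default 25).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(q = 0.05,
                             test_variant = c("auto", "asymptotic", "exact"),
                             small_count_threshold = 25L) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop_config("q", "must lie strictly between 0 and 1")
  test_variant <- match.arg(test_variant)
  if (!is_count(small_count_threshold, min = 0L))
    stop_config("small_count_threshold", "must be a nonnegative integer")
  structure(list(q = q, test_variant = test_variant,
                 small_count_threshold = as.integer(small_count_threshold)),
            class = "screening_config")
}

#' Discordant-pair cross-tabulation
#'
#' Counts matched pairs by joint exposure: `n11` both members exposed, `n10`
#' case only, `n01` reference only, `n00` neither. Accepts either a single
#' pair of binary vectors (one code) or aligned binary matrices (codes in
#' columns), rows aligned so that row i of `case` is matched to row i of
#' `reference`.
#'
#' @param case,reference binary vectors or matrices of identical shape.
#' @return A data frame with columns `block` (column names, or `"code"` for
#'   vectors), `n11`, `n10`, `n01`, `n00`.
#' @export
discordant_counts <- function(case, reference) {
  if (is.null(dim(case))) {
    case <- matrix(case, ncol = 1L, dimnames = list(NULL, "code"))
    reference <- matrix(reference, ncol = 1L)
  }
  stopifnot(identical(dim(case), dim(reference)))
  if (!all(case %in% c(0L, 1L)) || !all(reference %in% c(0L, 1L)))
    stop("exposure columns must be binary", call. = FALSE)
  cs <- case == 1L
  rs <- reference == 1L
  data.frame(
    block = colnames(case) %||% sprintf("V%d", seq_len(ncol(case))),
    n11 = colSums(cs & rs),
    n10 = colSums(cs & !rs),
    n01 = colSums(!cs & rs),
    n00 = colSums(!cs & !rs),
    row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Matched McNemar test from discordant counts
#'
#' Asymptotic variant: statistic `(n10 - n01)^2 / (n10 + n01)` referred to a
#' chi-squared distribution with one degree of freedom (no continuity
#' correction). Exact variant: two-sided binomial test of `n10` successes in
#' `n10 + n01` trials at probability one half. The odds ratio is the
#' discordant ratio `n10 / n01` (the conditional maximum-likelihood estimate
#' under 1:1 matching), `Inf` when `n01 = 0 < n10`, and `NaN` (undefined)
#' for the degenerate case `n10 + n01 = 0`, which yields `p = 1` rather than
#' an error.
#'
#' @param n10,n01 discordant counts (vectors allowed, recycled together).
#' @param config a [screening_config()].
#' @return Data frame with columns `statistic`, `p_value`, `or_estimate`,
#'   `variant`.
#' @export
mcnemar_test <- function(n10, n01, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  nd <- n10 + n01
  stat <- ifelse(nd > 0, (n10 - n01)^2 / nd, 0)
  use_exact <- switch(config$test_variant,
                      asymptotic = rep(FALSE, length(nd)),
                      exact = rep(TRUE, length(nd)),
                      auto = nd < config$small_count_threshold)
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  if (any(use_exact)) {
    p[use_exact] <- mapply(function(b, n) {
      if (n == 0L) return(1)
      binom.test(b, n, p = 0.5)$p.value
    }, n10[use_exact], nd[use_exact])
  }
  p[nd == 0] <- 1
  or <- ifelse(nd == 0, NaN, ifelse(n01 == 0, Inf, n10 / n01))
  data.frame(statistic = ifelse(nd == 0, NA_real_, stat),
             p_value = pmin(p, 1),
             or_estimate = or,
             variant = ifelse(use_exact, "exact", "asymptotic"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Yekutieli step-up rejections
#'
#' Step-up rule under arbitrary dependence: with `m` hypotheses and harmonic
#' correction `c(m) = sum(1/k)`, reject the `k*` smallest p-values where
#' `k* = max(i : p(i) <= i q / (m c(m)))`. Implemented through
#' `stats::p.adjust(method = "BY")`, whose adjusted p-values satisfy
#' `adjusted <= q` exactly for the step-up rejection set; tied p-values
#' necessarily share a decision.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return Logical rejection flags in input order.
#' @export
benjamini_yekutieli <- function(p_values, q = 0.05) {
  if (length(p_values) < 1L)
    stop("p_values must be nonempty", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p_values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BY") <= q
}

#' Screen all codes on one split by matched McNemar + BY
#'
#' Runs the matched McNemar test per code on the given split, applies the
#' Benjamini-Yekutieli procedure across all tested codes, and flags as
#' screened (`by_rejected`) only codes that are both BY-rejected and
#' over-represented in cases (`or_estimate > 1`; an infinite estimate
#' qualifies). The pure multiplicity decision is kept in `by_significant`.
#'
#' @param code_matrix binary patient x block matrix (see
#'   [build_code_matrix()]).
#' @param cohort a [matched_cohort()] with split labels.
#' @param split split to screen (default `"training"`; `NULL` = all pairs).
#' @param config a [screening_config()].
#' @return Data frame of class `screening_result`: `block`, discordant
#'   counts, `statistic`, `p_value`, `or_estimate`, `by_significant`,
#'   `by_rejected`, `validated` (initialized `NA`).
#' @export
screen_codes <- function(code_matrix, cohort, split = "training",
                         config = screening_config()) {
  if (ncol(code_matrix) == 0L) {
    out <- data.frame(block = character(0), n11 = integer(0),
                      n10 = integer(0), n01 = integer(0), n00 = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      or_estimate = numeric(0), by_significant = logical(0),
                      by_rejected = logical(0), validated = logical(0))
    class(out) <- c("screening_result", class(out))
    return(out)
  }
  cs <- code_matrix[split_ids(cohort, split, "case"), , drop = FALSE]
  rf <- code_matrix[split_ids(cohort, split, "reference"), , drop = FALSE]
  tab <- discordant_counts(cs, rf)
  test <- mcnemar_test(tab$n10, tab$n01, config)
  by_sig <- benjamini_yekutieli(test$p_value, config$q)
  out <- cbind(tab, test[, c("statistic", "p_value", "or_estimate")])
  out$by_significant <- by_sig
  out$by_rejected <- by_sig & out$or_estimate > 1
  out$validated <- NA
  class(out) <- c("screening_result", class(out))
  out
}

#' Re-test screened candidates on the validation split
#'
#' Re-runs the matched McNemar test and the BY procedure at the same FDR
#' level, restricted to the candidate set (the multiplicity denominator is
#' the number of candidates carried forward), with the same OR > 1 filter.
#'
#' @param screened a `screening_result` from [screen_codes()] on training.
#' @param code_matrix binary patient x block matrix.
#' @param cohort a [matched_cohort()].
#' @param split validation split label (default `"validation"`).
#' @param config a [screening_config()].
#' @return The training `screening_result` with its `validated` column
#'   filled in (`TRUE` only where `by_rejected` was `TRUE`).
#' @export
validate_codes <- function(screened, code_matrix, cohort,
                           split = "validation",
                           config = screening_config()) {
  candidates <- screened$block[screened$by_rejected]
  screened$validated <- FALSE
  if (length(candidates) == 0L) return(screened)
  cs <- code_matrix[split_ids(cohort, split, "case"), candidates,
                    drop = FALSE]
  rf <- code_matrix[split_ids(cohort, split, "reference"), candidates,
                    drop = FALSE]
  tab <- discordant_counts(cs, rf)
  test <- mcnemar_test(tab$n10, tab$n01, config)
  ok <- benjamini_yekutieli(test$p_value, config$q) & test$or_estimate > 1
  screened$validated[match(candidates, screened$block)] <- ok
  screened
}
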