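#' Binary factor-based scores
#'
#' A patient scores 1 on a factor iff any of the factor's member codes is
#' present in their binary code row, 0 otherwise.
#'
#' @param code_matrix binary patient x block matrix (or a single row).
#' @param factors list of factor definitions from
#'   [assign_codes_to_factors()].
#' @return Integer matrix (patients x factors) in \{0,1\}, columns named
#'   `factor_<id>`.
#' @export
factor_score <- function(code_matrix, factors) {
  if (is.null(dim(code_matrix)))
    code_matrix <- matrix(code_matrix, nrow = 1L,
                          dimnames = list(NULL, names(code_matrix)))
  stopifnot(length(factors) >= 1L)
  S <- vapply(factors, function(f) {
    stopifnot(length(f$member_codes) >= 1L)
    present <- intersect(f$member_codes, colnames(code_matrix))
    if (length(present) == 0L) return(rep(0L, nrow(code_matrix)))
    as.integer(rowSums(code_matrix[, present, drop = FALSE]) > 0)
  }, integer(nrow(code_matrix)))
  S <- matrix(S, nrow = nrow(code_matrix),
              dimnames = list(rownames(code_matrix),
                              sprintf("factor_%d",
                                      vapply(factors, `[[`, 0L,
                                             "factor_id"))))
  S
}

#' Matched odds ratio with Wald interval from discordant counts
#'
#' For a single binary covariate under 1:1 matching the conditional
#' maximum-likelihood odds ratio is the discordant ratio `n10 / n01`, with
#' 95% Wald interval `exp(log(OR) +/- 1.96 * sqrt(1/n10 + 1/n01))` and a
#' two-sided Wald test of `log(OR) = 0`. When one discordant cell is zero
#' the point estimate is left uncorrected (`Inf` or `0`), flagged, and a
#' one-sided exact bound from the binomial tail of the discordant split is
#' reported instead of the missing Wald limit.
#'
#' @param n10 pairs exposed in the case only.
#' @param n01 pairs exposed in the reference only.
#' @param conf_level confidence level (default 0.95).
#' @return List: `or`, `ci_low`, `ci_high`, `p_value`, `flag`
#'   (`"ok"`, `"n01_zero"`, `"n10_zero"`).
#' @export
matched_or <- function(n10, n01, conf_level = 0.95) {
  if (n10 + n01 == 0)
    stop("no-information: no discordant pairs", call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (n10 > 0 && n01 > 0) {
    or <- n10 / n01
    se <- sqrt(1 / n10 + 1 / n01)
    lo <- exp(log(or) - z * se)
    hi <- exp(log(or) + z * se)
    return(list(or = or, ci_low = lo, ci_high = hi,
                p_value = 2 * stats::pnorm(-abs(log(or) / se)),
                flag = "ok"))
  }
  n <- n10 + n01
  alpha <- 1 - conf_level
  if (n01 == 0) {
    # exact one-sided lower bound on the discordant proportion -> OR
    p_lo <- qbeta(alpha / 2, n10, 1)
    list(or = Inf, ci_low = p_lo / (1 - p_lo), ci_high = Inf,
         p_value = min(1, 2 * 0.5^n), flag = "n01_zero")
  } else {
    p_hi <- qbeta(1 - alpha / 2, 1, n01)
    list(or = 0, ci_low = 0, ci_high = p_hi / (1 - p_hi),
         p_value = min(1, 2 * 0.5^n), flag = "n10_zero")
  }
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the pair-conditional likelihood
#' `prod exp(beta' dx) / (1 + exp(beta' dx))` over pair differences
#' `dx = x_case - x_reference` by damped Newton ascent (step-halving until
#' the log-likelihood does not decrease), converging when the gradient's
#' maximum absolute entry falls below `tol` or after `max_iter` iterations.
#' Pairs with `dx = 0` are uninformative and drop out of the likelihood. A
#' covariate whose nonzero differences all share one sign is separated: its
#' coefficient diverges, and it is flagged rather than reported as converged.
#'
#' @param delta numeric matrix of pair differences (pairs x covariates), or a
#'   vector for a single covariate.
#' @param tol gradient convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return List: `coef` (named), `converged`, `separated` (logical per
#'   covariate), `loglik`, `iter`, `vcov`.
#' @export
fit_conditional_logistic <- function(delta, tol = 1e-8, max_iter = 100L) {
  if (is.null(dim(delta))) delta <- matrix(delta, ncol = 1L)
  storage.mode(delta) <- "double"
  p <- ncol(delta)
  cn <- colnames(delta) %||% sprintf("x%d", seq_len(p))
  nz <- delta != 0
  separated <- vapply(seq_len(p), function(j) {
    d <- delta[nz[, j], j]
    length(d) > 0L && (all(d > 0) || all(d < 0))
  }, TRUE)
  informative <- rowSums(nz) > 0
  X <- delta[informative, , drop = FALSE]
  if (nrow(X) == 0L) {
    warning("flat likelihood: all pair differences are zero", call. = FALSE)
    return(list(coef = stats::setNames(rep(0, p), cn), converged = TRUE,
                separated = stats::setNames(separated, cn),
                loglik = 0, iter = 0L, vcov = matrix(NA_real_, p, p)))
  }
  beta <- rep(0, p)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(eta - log1p(exp(eta)))
  }
  llcur <- ll(beta)
  iter <- 0L
  converged <- FALSE
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, 1 - mu))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    Wt <- mu * (1 - mu)
    H <- crossprod(X, X * Wt)
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    damp <- 1
    repeat {
      cand <- beta + damp * step
      llnew <- ll(cand)
      if (llnew >= llcur - 1e-12 || damp < 1e-8) break
      damp <- damp / 2
    }
    beta <- cand
    llcur <- llnew
  }
  if (any(separated)) converged <- FALSE
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(coef = stats::setNames(beta, cn),
       converged = converged,
       separated = stats::setNames(separated, cn),
       loglik = llcur, iter = iter,
       vcov = vc)
}

#' Per-factor matched odds ratios on a held-out split
#'
#' Scores every patient of the chosen split on each factor, cross-tabulates
#' the scores within matched pairs, and reports the matched odds ratio with
#' 95% Wald interval and two-sided p-value per factor, together with the
#' exposed counts and cohort percentages per arm. Factors with no exposed
#' patient in the split are reported with an explicit `no_information` flag
#' rather than an estimate.
#'
#' @param factors list of factor definitions.
#' @param code_matrix binary patient x block matrix.
#' @param cohort a [matched_cohort()].
#' @param split split label (default `"testing"`).
#' @return Data frame of class `effect_estimates`: one row per factor with
#'   `factor_id`, exposure counts/percentages, discordant table, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `flag`.
#' @export
evaluate_factors <- function(factors, code_matrix, cohort,
                             split = "testing") {
  case_ids <- split_ids(cohort, split, "case")
  ref_ids <- split_ids(cohort, split, "reference")
  S <- factor_score(code_matrix, factors)
  Sc <- S[case_ids, , drop = FALSE]
  Sr <- S[ref_ids, , drop = FALSE]
  tab <- discordant_counts(Sc, Sr)
  n_split <- length(case_ids)
  rows <- lapply(seq_along(factors), function(i) {
    n10 <- tab$n10[i]
    n01 <- tab$n01[i]
    est <- if (n10 + n01 == 0) {
      list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p_value = NA_real_, flag = "no_information")
    } else {
      matched_or(n10, n01)
    }
    data.frame(
      factor_id = factors[[i]]$factor_id,
      n_case = tab$n11[i] + n10,
      pct_case = 100 * (tab$n11[i] + n10) / n_split,
      n_ref = tab$n11[i] + n01,
      pct_ref = 100 * (tab$n11[i] + n01) / n_split,
      n11 = tab$n11[i], n10 = n10, n01 = n01, n00 = tab$n00[i],
      or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
      p_value = est$p_value, flag = est$flag,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_estimates", class(out))
  out
}
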