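#' Phi (Pearson) correlation matrix of binary code columns
#'
#' Constant columns carry no correlation information and are dropped with a
#' warning before computing the Pearson correlation of the remaining binary
#' columns (the phi coefficient).
#'
#' @param code_matrix binary patient x block matrix.
#' @param blocks columns to use (default: all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(code_matrix, blocks = colnames(code_matrix)) {
  x <- code_matrix[, blocks, drop = FALSE]
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d constant code column(s): %s",
                    sum(v == 0),
                    paste(utils::head(colnames(x)[v == 0], 5L),
                          collapse = ", ")),
            call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L)
    stop("at least two non-constant codes are required", call. = FALSE)
  stats::cor(x)
}

#' Principal-component factor extraction
#'
#' Eigendecomposition of the correlation matrix with eigenvalues sorted
#' descending; loading column j is eigenvector j scaled by `sqrt(lambda_j)`,
#' and each column's sign is flipped so its largest-magnitude entry is
#' positive. Eigenvalues that are negative by rounding error are clamped at
#' zero.
#'
#' @param correlation symmetric correlation matrix.
#' @param tol symmetry tolerance.
#' @return Object of class `pc_factor_model`: list with `eigenvalues`,
#'   `loadings` (codes x components), `codes`.
#' @export
principal_component_factors <- function(correlation, tol = 1e-8) {
  if (!is.matrix(correlation) ||
      nrow(correlation) != ncol(correlation) ||
      max(abs(correlation - t(correlation))) > tol)
    stop("correlation must be a symmetric square matrix", call. = FALSE)
  eg <- eigen(correlation, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  load <- eg$vectors %*% diag(sqrt(lambda), nrow = length(lambda))
  flip <- apply(load, 2L, function(col) {
    j <- which.max(abs(col))
    if (col[j] < 0) -1 else 1
  })
  load <- sweep(load, 2L, flip, `*`)
  dimnames(load) <- list(rownames(correlation),
                         sprintf("PC%d", seq_along(lambda)))
  structure(list(eigenvalues = lambda, loadings = load,
                 codes = rownames(correlation)),
            class = "pc_factor_model")
}

#' @export
print.pc_factor_model <- function(x, ...) {
  cat(sprintf("pc_factor_model: %d codes, %d eigenvalues > 1\n",
              length(x$codes), sum(x$eigenvalues > 1)))
  invisible(x)
}

#' Factor-retention diagnostics
#'
#' Reports the three descriptive retention criteria: (i) the count of
#' eigenvalues above one (Kaiser rule); (ii) the scree elbow, operationalized
#' as the interior index maximizing the centred second difference of the
#' eigenvalue sequence (first interior index on ties; a flat scree is
#' degenerate and returns 1 with a warning); (iii) the cumulative proportion
#' of variance, with the smallest count reaching `cum_var_threshold`.
#'
#' @param eigenvalues nonincreasing, nonnegative eigenvalue sequence.
#' @param cum_var_threshold target cumulative variance proportion for
#'   criterion (iii) (default 0.8).
#' @return List with `kaiser`, `scree_elbow`, `cumulative_variance`
#'   (full profile), `k_cumulative`.
#' @export
retention_diagnostics <- function(eigenvalues, cum_var_threshold = 0.8) {
  d <- length(eigenvalues)
  if (d < 1L || any(diff(eigenvalues) > 1e-12) || any(eigenvalues < -1e-12))
    stop("eigenvalues must be nonincreasing and nonnegative", call. = FALSE)
  kaiser <- sum(eigenvalues > 1)
  if (d >= 3L) {
    i <- 2:(d - 1L)
    curv <- eigenvalues[i - 1L] - 2 * eigenvalues[i] + eigenvalues[i + 1L]
    if (max(curv) <= 1e-12) {
      warning("degenerate scree: no curvature; elbow defaults to 1",
              call. = FALSE)
      elbow <- 1L
    } else {
      elbow <- i[which.max(curv)]
    }
  } else {
    warning("degenerate scree: fewer than 3 eigenvalues; elbow defaults to 1",
            call. = FALSE)
    elbow <- 1L
  }
  cumvar <- cumsum(eigenvalues) / sum(eigenvalues)
  list(kaiser = kaiser,
       scree_elbow = elbow,
       cumulative_variance = cumvar,
       k_cumulative = which(cumvar >= cum_var_threshold)[1L])
}

#' Assign codes to factors by the loading cutoff
#'
#' A code belongs to factor j iff its (signed, after the positive-dominant
#' sign convention) loading on component j is at least `cutoff`; codes may
#' belong to zero, one, or several factors. Factors with empty membership are
#' dropped with a warning.
#'
#' @param model a `pc_factor_model` (or a loadings matrix).
#' @param k_retained number of leading components to turn into factors.
#' @param cutoff loading cutoff in (0, 1) (default 0.2, boundary inclusive).
#' @return List of factor definitions, each a list with `factor_id`,
#'   `member_codes`, `loadings`.
#' @export
assign_codes_to_factors <- function(model, k_retained, cutoff = 0.2) {
  loadings <- if (inherits(model, "pc_factor_model")) model$loadings else
    model
  if (!(cutoff > 0 && cutoff < 1))
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  stopifnot(k_retained >= 1L, k_retained <= ncol(loadings))
  codes <- rownames(loadings)
  defs <- lapply(seq_len(k_retained), function(j) {
    sel <- loadings[, j] >= cutoff
    list(factor_id = j,
         member_codes = codes[sel],
         loadings = stats::setNames(loadings[sel, j], codes[sel]))
  })
  empty <- vapply(defs, function(f) length(f$member_codes) == 0L, TRUE)
  if (any(empty))
    warning(sprintf("dropping %d factor(s) with no loading >= %.2g",
                    sum(empty), cutoff), call. = FALSE)
  defs[!empty]
}

#' Select the retained factor count by validation-split AUC
#'
#' For each candidate k: build factor definitions at the loading cutoff,
#' compute binary factor scores, fit one joint conditional logistic model on
#' the training pairs with the k scores as covariates, evaluate the fitted
#' linear predictor on validation-split patients, and measure the AUC of that
#' predictor for discriminating case from reference members. Returns the k
#' with maximal AUC (smallest k on ties). Candidates whose model fails to
#' converge are skipped with a warning.
#'
#' @param model a `pc_factor_model` fitted on the training split.
#' @param candidate_ks candidate retained-factor counts.
#' @param code_matrix binary patient x block matrix (all splits).
#' @param cohort a [matched_cohort()] with split labels.
#' @param cutoff loading cutoff (default 0.2).
#' @param training,validation split labels.
#' @return List with `k` (selected), `auc` (named vector over candidates).
#' @export
select_k_by_auc <- function(model, candidate_ks, code_matrix, cohort,
                            cutoff = 0.2, training = "training",
                            validation = "validation") {
  stopifnot(length(candidate_ks) >= 1L,
            all(candidate_ks >= 1L),
            all(candidate_ks <= ncol(model$loadings)))
  tr_case <- split_ids(cohort, training, "case")
  tr_ref <- split_ids(cohort, training, "reference")
  va_case <- split_ids(cohort, validation, "case")
  va_ref <- split_ids(cohort, validation, "reference")
  aucs <- stats::setNames(rep(NA_real_, length(candidate_ks)),
                          candidate_ks)
  for (i in seq_along(candidate_ks)) {
    k <- candidate_ks[i]
    defs <- withCallingHandlers(
      assign_codes_to_factors(model, k, cutoff),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(defs) == 0L) next
    S <- factor_score(code_matrix, defs)
    fit <- fit_conditional_logistic(S[tr_case, , drop = FALSE] -
                                      S[tr_ref, , drop = FALSE])
    if (!fit$converged) {
      warning(sprintf("candidate k = %d skipped: model did not converge", k),
              call. = FALSE)
      next
    }
    lp <- as.vector(S[c(va_case, va_ref), , drop = FALSE] %*% fit$coef)
    lab <- rep(c(TRUE, FALSE), c(length(va_case), length(va_ref)))
    aucs[i] <- auc_rank(lp, lab)
  }
  if (all(is.na(aucs)))
    stop("selection error: no candidate k produced a converged model",
         call. = FALSE)
  best <- which(aucs == max(aucs, na.rm = TRUE))[1L]
  list(k = candidate_ks[best], auc = aucs)
}
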