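test_that("phi correlation handles identical, complementary, independent columns", {
  x <- rbinom(400, 1, 0.4)
  m <- cbind(a = x, b = x, c = 1L - x)
  rownames(m) <- sprintf("p%03d", 1:400)
  cc <- correlation_matrix(m)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))

  set.seed(40)
  ind <- cbind(u = rbinom(10000, 1, 0.3), v = rbinom(10000, 1, 0.3))
  expect_lt(abs(correlation_matrix(ind)["u", "v"]), 4 / sqrt(10000))

  const <- cbind(k = rep(1L, 50), u = rbinom(50, 1, 0.5),
                 v = rbinom(50, 1, 0.5))
  expect_warning(cc2 <- correlation_matrix(const), "constant")
  expect_identical(colnames(cc2), c("u", "v"))
  expect_warning(expect_error(correlation_matrix(const[, 1:2]), "two"),
                 "constant")
})

test_that("principal components obey the 2x2 hand solution and spectral identities", {
  r <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  mod <- principal_component_factors(r)
  expect_equal(mod$eigenvalues, c(1.6, 0.4))
  expect_equal(unname(round(mod$loadings[, 1], 3)), c(0.894, 0.894))

  expect_equal(principal_component_factors(diag(2))$eigenvalues, c(1, 1))
  expect_error(principal_component_factors(matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")

  set.seed(41)
  x <- matrix(rbinom(3000, 1, 0.3), 300, 10,
              dimnames = list(NULL, sprintf("c%02d", 1:10)))
  x[, 2] <- ifelse(runif(300) < 0.5, x[, 1], x[, 2])
  cc <- correlation_matrix(x)
  m2 <- principal_component_factors(cc)
  d <- ncol(cc)
  expect_equal(sum(m2$eigenvalues), d, tolerance = 1e-8)       # trace
  expect_equal(m2$loadings %*% t(m2$loadings), cc,
               tolerance = 1e-8)                               # reconstruction
  expect_equal(colSums(m2$loadings^2), m2$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)           # column norms
  gram <- crossprod(m2$loadings[, 1:5] %*%
                      diag(1 / sqrt(m2$eigenvalues[1:5])))
  expect_equal(gram, diag(5), tolerance = 1e-8)                # orthogonality
  for (j in seq_len(d)) {                                      # sign rule
    expect_gte(m2$loadings[which.max(abs(m2$loadings[, j])), j], 0)
  }
})

test_that("retention diagnostics implement the three descriptive criteria", {
  d1 <- retention_diagnostics(c(3, 1.5, 0.9, 0.6))
  expect_identical(d1$kaiser, 2L)
  expect_equal(d1$cumulative_variance, cumsum(c(3, 1.5, 0.9, 0.6)) / 6)

  d2 <- retention_diagnostics(c(5, 2, 1.8, 1.7, 1.6))
  expect_identical(d2$scree_elbow, 2L)

  expect_warning(flat <- retention_diagnostics(rep(2, 5)), "degenerate")
  expect_identical(flat$scree_elbow, 1L)
  expect_error(retention_diagnostics(c(1, 2, 3)), "nonincreasing")
  expect_identical(retention_diagnostics(c(2.4, 1.2, 0.4),
                                         cum_var_threshold = 0.8)$k_cumulative,
                   2L)
})

test_that("code-to-factor assignment is boundary-inclusive and overlapping", {
  L <- matrix(c(0.25, 0.19, 0.20,
                0.30, 0.10, 0.30), ncol = 2,
              dimnames = list(c("A01", "A02", "A03"), NULL))
  defs <- assign_codes_to_factors(L, 2, cutoff = 0.2)
  expect_setequal(defs[[1]]$member_codes, c("A01", "A03"))
  expect_setequal(defs[[2]]$member_codes, c("A01", "A03"))
  # A01 and A03 sit in both factors; no restriction on multiple loading
  low <- matrix(c(0.5, 0.4, 0.1, 0.15), ncol = 2,
                dimnames = list(c("A01", "A02"), NULL))
  expect_warning(kept <- assign_codes_to_factors(low, 2, 0.2), "dropping")
  expect_length(kept, 1L)
  expect_error(assign_codes_to_factors(L, 2, cutoff = 0), "cutoff")
})

test_that("block-structured planted factors are recovered at cutoff 0.2", {
  vocab <- default_code_vocabulary(30)
  members <- list(vocab[1:8], vocab[9:14], vocab[15:19], vocab[20:23])
  cfg <- sim_config(n_pairs = 8000, code_vocabulary = vocab,
                    background_code_prob = 0.01, visit_rate = 1, seed = 77,
                    factors_truth = lapply(members, function(m)
                      planted_factor(m, 0.3, 0.5, 1.5)))
  g <- generate_cohort(cfg)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates,
                           split = rep("training", 8000))
  mat <- build_code_matrix(g$visits, cohort, canonical_blocks = vocab)
  mod <- principal_component_factors(correlation_matrix(mat))
  defs <- assign_codes_to_factors(mod, 4, 0.2)
  est <- lapply(defs, `[[`, "member_codes")
  expect_gte(matched_jaccard(est, members), 0.8)
})

test_that("AUC-based k selection agrees with an independent re-evaluation", {
  skip_if_not_installed("survival")
  skip_if_not_installed("pROC")
  suppressPackageStartupMessages(library(survival))
  vocab <- default_code_vocabulary(24)
  members <- list(vocab[1:6], vocab[7:11], vocab[12:15])
  cfg <- sim_config(n_pairs = 4000, code_vocabulary = vocab,
                    background_code_prob = 0.02, visit_rate = 1, seed = 55,
                    factors_truth = list(
                      planted_factor(members[[1]], 0.30, 0.55, 3.0),
                      planted_factor(members[[2]], 0.20, 0.60, 2.2),
                      planted_factor(members[[3]], 0.12, 0.60, 4.0)))
  g <- generate_cohort(cfg)
  split <- assign_splits(4000, seed = 3)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates, split)
  mat <- build_code_matrix(g$visits, cohort, canonical_blocks = vocab)
  train <- c(cohort$pairs$case_id[split == "training"],
             cohort$pairs$reference_id[split == "training"])
  mod <- principal_component_factors(
    correlation_matrix(mat[train, , drop = FALSE]))

  candidates <- 1:5
  sel <- select_k_by_auc(mod, candidates, mat, cohort)
  expect_identical(sel$k, as.integer(names(which.max(sel$auc))))

  # oracle: survival::clogit fit + pROC AUC, recomputed from scratch
  oracle_auc <- vapply(candidates, function(k) {
    defs <- suppressWarnings(assign_codes_to_factors(mod, k))
    S <- factor_score(mat, defs)
    tr_case <- cohort$pairs$case_id[split == "training"]
    tr_ref <- cohort$pairs$reference_id[split == "training"]
    df <- data.frame(y = rep(c(1, 0), each = length(tr_case)),
                     strat = rep(seq_along(tr_case), 2))
    X <- rbind(S[tr_case, , drop = FALSE], S[tr_ref, , drop = FALSE])
    colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
    fit <- survival::clogit(
      y ~ . - strat + survival::strata(strat),
      data = cbind(df, as.data.frame(X)))
    va <- c(cohort$pairs$case_id[split == "validation"],
            cohort$pairs$reference_id[split == "validation"])
    lab <- rep(c(1, 0), c(sum(split == "validation"),
                          sum(split == "validation")))
    lp <- as.vector(S[va, , drop = FALSE] %*% coef(fit))
    as.numeric(pROC::auc(pROC::roc(lab, lp, quiet = TRUE,
                                   direction = "<")))
  }, 0)
  expect_identical(sel$k, candidates[which.max(oracle_auc)])
  expect_equal(unname(sel$auc), oracle_auc, tolerance = 1e-6)

  # forced single candidate
  expect_identical(select_k_by_auc(mod, 2L, mat, cohort)$k, 2L)
})
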