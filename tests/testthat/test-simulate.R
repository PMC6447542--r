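test_that("generation is deterministic given seed and differs across seeds", {
  vocab <- default_code_vocabulary(20)
  cfg <- sim_config(n_pairs = 10, code_vocabulary = vocab, seed = 42,
                    factors_truth = list(
                      planted_factor(vocab[1:3], 0.3, 0.6, 2)))
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_visit_table(g1$visits, f1)
  write_visit_table(g2$visits, f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg$seed <- 43L
  expect_false(identical(generate_cohort(cfg)$visits, g1$visits))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(sim_config(n_pairs = 0), "n_pairs")
  expect_error(sim_config(n_pairs = 10, code_vocabulary = c("a1", "B22x")),
               "code_vocabulary")
  expect_error(sim_config(n_pairs = 10, code_vocabulary = c("A01", "A01")),
               "code_vocabulary")
  expect_error(sim_config(n_pairs = 10, background_code_prob = 1.3),
               "background_code_prob")
  expect_error(sim_config(n_pairs = 10, visit_rate = -1), "visit_rate")
  expect_error(sim_config(n_pairs = 10, spike_multiplier = 0.5),
               "spike_multiplier")
  expect_error(sim_config(n_pairs = 10, event_block = "A00",
                          code_vocabulary = c("A00", "A01")), "event_block")
  expect_error(planted_factor(character(0), 0.5, 0.5, 2), "member_codes")
  expect_error(planted_factor("A00", 0.5, 0.5, -2), "case_odds_ratio")
  expect_error(planted_factor("A00", 1.5, 0.5, 2), "carrier_prevalence")
  expect_error(
    sim_config(n_pairs = 10, code_vocabulary = c("A00", "A01"),
               factors_truth = list(planted_factor("Z99", 0.5, 0.5, 2))),
    "factors_truth")
})

test_that("a null configuration leaves case and reference arms exchangeable", {
  vocab <- default_code_vocabulary(40)
  cfg <- sim_config(n_pairs = 5000, code_vocabulary = vocab,
                    background_code_prob = 0.03, visit_rate = 1,
                    spike_multiplier = 1, seed = 9,
                    factors_truth = list(
                      planted_factor(vocab[1:5], 0.3, 0.5, 1)))
  g <- generate_cohort(cfg)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates,
                           split = rep("training", 5000))
  m <- build_code_matrix(g$visits, cohort, canonical_blocks = vocab)
  pc <- colMeans(m[g$pairing$case_id, ])
  pr <- colMeans(m[g$pairing$reference_id, ])
  pbar <- (pc + pr) / 2
  se <- sqrt(2 * pbar * (1 - pbar) / 5000)
  expect_lt(max(abs(pc - pr) / se), 4)
})

test_that("per-code prevalence matches its closed-form expectation", {
  vocab <- default_code_vocabulary(30)
  cfg <- sim_config(n_pairs = 5000, code_vocabulary = vocab,
                    background_code_prob = 0.02, visit_rate = 0.6, seed = 5,
                    factors_truth = list(
                      planted_factor(vocab[1:4], 0.3, 0.5, 3),
                      planted_factor(vocab[3:8], 0.15, 0.7, 2)))
  g <- generate_cohort(cfg)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates,
                           split = rep("training", 5000))
  m <- build_code_matrix(g$visits, cohort, canonical_blocks = vocab)
  expected <- expected_code_prevalence(cfg)
  emp <- cbind(case = colMeans(m[g$pairing$case_id, vocab]),
               reference = colMeans(m[g$pairing$reference_id, vocab]))
  z <- (emp - expected) / sqrt(expected * (1 - expected) / 5000)
  expect_lt(max(abs(z)), 4)
})

test_that("mean in-window visit count equals visit_rate times window years", {
  cfg <- sim_config(n_pairs = 5000, visit_rate = 0.4, seed = 21,
                    code_vocabulary = default_code_vocabulary(10))
  g <- generate_cohort(cfg)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates,
                           split = rep("training", 5000))
  s <- summarize_cohort(cohort, g$visits)
  # 0.4 visits/yr x 5 yr = 2 expected in-window visits in both arms
  for (arm in c("case", "reference")) {
    se <- s$visits[arm, "sd_inwindow"] / sqrt(5000)
    expect_lt(abs(s$visits[arm, "mean_inwindow"] - 2), 4 * se)
  }
})

test_that("null-cohort McNemar p-values are super-uniform", {
  vocab <- default_code_vocabulary(100)
  pooled <- unlist(lapply(1:5, function(s) {
    cfg <- sim_config(n_pairs = 1000, code_vocabulary = vocab,
                      background_code_prob = 0.03, visit_rate = 1, seed = s,
                      factors_truth = list(
                        planted_factor(vocab[1:6], 0.3, 0.5, 4)))
    nc <- generate_null_cohort(cfg)
    cohort <- matched_cohort(nc$pairing, visits = nc$visits,
                             split = rep("training", 1000))
    m <- build_code_matrix(nc$visits, cohort, canonical_blocks = vocab)
    screen_codes(m, cohort, "training")$p_value
  }))
  ks <- suppressWarnings(
    stats::ks.test(pooled, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted score-level odds ratios have a closed form the data follow", {
  fix <- tiny_planted_cohort(n_pairs = 5000, seed = 3, or = 4,
                             prevalence = 0.2, code_prob = 0.7)
  truth <- true_factor_or(fix$config)
  defs <- list(list(factor_id = 1L, member_codes = fix$members))
  S <- factor_score(fix$matrix, defs)
  p_case <- mean(S[fix$generated$pairing$case_id, ])
  p_ref <- mean(S[fix$generated$pairing$reference_id, ])
  expect_lt(abs(p_case - truth$case_score_prob), 0.02)
  expect_lt(abs(p_ref - truth$reference_score_prob), 0.02)
  emp_or <- p_case * (1 - p_ref) / ((1 - p_case) * p_ref)
  expect_lt(abs(log(emp_or) - log(truth$odds_ratio)), 0.15)
})
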