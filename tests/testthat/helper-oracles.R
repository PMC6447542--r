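# Independent oracles and small fixture builders shared across test files.
# Each oracle deliberately re-derives its quantity from first principles so it
# never shares code with the implementation it checks.

# Benjamini-Yekutieli step-up by direct threshold enumeration.
by_stepup_oracle <- function(p, q) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_len(m) * q / (m * cm)
  kstar <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (kstar > 0L) rej[o[seq_len(kstar)]] <- TRUE
  rej
}

# Naive per-pair discordant counting loop.
discordant_oracle <- function(case, reference) {
  n11 <- n10 <- n01 <- n00 <- 0L
  for (i in seq_along(case)) {
    if (case[i] == 1L && reference[i] == 1L) n11 <- n11 + 1L
    else if (case[i] == 1L) n10 <- n10 + 1L
    else if (reference[i] == 1L) n01 <- n01 + 1L
    else n00 <- n00 + 1L
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

# All permutations of a small integer vector (for factor-to-truth matching).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Mean per-factor Jaccard after the best factor-to-truth matching
# (exhaustive over permutations; fine for <= 6 factors).
matched_jaccard <- function(estimated, truth) {
  k <- length(truth)
  stopifnot(length(estimated) >= 1L)
  J <- matrix(0, nrow = k, ncol = k)
  for (i in seq_len(min(k, length(estimated))))
    for (j in seq_len(k))
      J[i, j] <- jaccard(estimated[[i]], truth[[j]])
  max(vapply(all_perms(seq_len(k)), function(p)
    mean(J[cbind(p, seq_len(k))]), 0))
}

# One-patient visit table from day offsets and codes.
make_visits <- function(patient_id, days, codes = NA_character_,
                        origin = as.Date("2015-06-01")) {
  n <- max(length(days), length(codes))
  data.frame(visit_id = seq_len(n),
             patient_id = patient_id,
             visit_date = origin + rep_len(days, n),
             setting = "emergency",
             dx = rep_len(codes, n),
             stringsAsFactors = FALSE)
}

# Small cohort with one planted factor; returns everything downstream tests
# need (matrix, cohort, config, truth).
tiny_planted_cohort <- function(n_pairs = 800, seed = 1,
                                or = 3, prevalence = 0.25,
                                code_prob = 0.6, n_codes = 12,
                                members = 1:4, split = "training") {
  vocab <- default_code_vocabulary(n_codes)
  cfg <- sim_config(
    n_pairs = n_pairs, code_vocabulary = vocab,
    background_code_prob = 0.03, visit_rate = 1, seed = seed,
    factors_truth = list(planted_factor(vocab[members], prevalence,
                                        code_prob, or)))
  g <- generate_cohort(cfg)
  cohort <- matched_cohort(g$pairing, g$truth$index_dates,
                           split = rep(split, n_pairs))
  mat <- build_code_matrix(g$visits, cohort, canonical_blocks = vocab)
  list(config = cfg, generated = g, cohort = cohort, matrix = mat,
       members = vocab[members])
}
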