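#' Describe a planted latent comorbidity factor
#'
#' A planted factor is a latent binary trait ("carrier" status) that raises the
#' probability of a set of member diagnosis blocks appearing in a patient's
#' pre-index history. Carrier prevalence is specified for the reference arm;
#' the case arm's prevalence is derived from `case_odds_ratio` on the odds
#' scale, so the planted odds ratio is the carrier-level case-vs-reference OR.
#'
#' @param member_codes character vector of three-character blocks (e.g. "F10").
#' @param carrier_prevalence probability a reference patient carries the trait.
#' @param code_prob_given_carrier probability that a carrier expresses each
#'   member code (independently per code).
#' @param case_odds_ratio target odds ratio (> 0) of carrier status for cases
#'   relative to references.
#' @return An object of class `planted_factor`.
#' @seealso [sim_config()], [true_factor_or()]
#' @export
planted_factor <- function(member_codes, carrier_prevalence,
                           code_prob_given_carrier, case_odds_ratio) {
  if (length(member_codes) < 1L || anyNA(member_codes))
    stop_config("member_codes", "must be a nonempty character vector")
  if (anyDuplicated(member_codes))
    stop_config("member_codes", "must be unique")
  if (!is_prob(carrier_prevalence) || carrier_prevalence <= 0)
    stop_config("carrier_prevalence", "must be a probability in (0, 1]")
  if (!is_prob(code_prob_given_carrier))
    stop_config("code_prob_given_carrier", "must be a probability in [0, 1]")
  if (!is.numeric(case_odds_ratio) || length(case_odds_ratio) != 1L ||
      is.na(case_odds_ratio) || case_odds_ratio <= 0)
    stop_config("case_odds_ratio", "must be a positive real")
  structure(
    list(member_codes = as.character(member_codes),
         carrier_prevalence = carrier_prevalence,
         code_prob_given_carrier = code_prob_given_carrier,
         case_odds_ratio = case_odds_ratio),
    class = "planted_factor")
}

#' Default synthetic code vocabulary
#'
#' Generates `n` syntactically valid, distinct three-character blocks spread
#' over the letters A-N (skipping S/T/U blocks so injury, event and
#' provisional code ranges stay free for anchors).
#'
#' @param n number of blocks.
#' @return Character vector of blocks like "A00", "B17".
#' @export
default_code_vocabulary <- function(n = 60) {
  letters_pool <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                    "L", "M", "N")
  grid <- as.vector(outer(sprintf("%02d", 0:99), letters_pool,
                          function(d, l) paste0(l, d)))
  if (n > length(grid)) stop_config("code_vocabulary", "request too large")
  sort(grid)[seq_len(n)]
}

#' Simulation configuration for a matched claims cohort
#'
#' Bundles and validates all generator parameters. Every probability must lie
#' in \[0, 1\], code identifiers must match `^[A-Z][0-9]{2}$` and be unique,
#' and factor member codes must be drawn from the vocabulary. The event block
#' (placed on each case's index visit) and the peri-event filler block (placed
#' on spike visits) may not belong to the vocabulary, so the anchor visits can
#' never shift a case's first-event index date or leak into the code matrix.
#'
#' @param n_pairs number of matched pairs (>= 1).
#' @param code_vocabulary character vector of three-character blocks.
#' @param factors_truth list of [planted_factor()] objects.
#' @param background_code_prob per-code, per-patient activation probability
#'   independent of any latent factor.
#' @param visit_rate mean pre-index history visits per patient per year; the
#'   realized in-window visit count is `1 + Poisson(visit_rate * years - 1)`,
#'   so every patient has at least one in-window visit and the mean equals
#'   `visit_rate * years` whenever that product is >= 1.
#' @param lookback_days length of the pre-index history window (default 1825).
#' @param spike_half_width_days half-width of the peri-index visit spike
#'   (default 30); history visits are generated strictly outside it.
#' @param spike_multiplier multiplier (>= 1) applied to case visit intensity
#'   within the spike window.
#' @param event_block three-character block marking the case-defining event.
#' @param peri_event_block filler block carried by spike visits.
#' @param index_date_range Date vector of length 2; index dates are uniform
#'   over this range.
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs,
                       code_vocabulary = default_code_vocabulary(60),
                       factors_truth = list(),
                       background_code_prob = 0.02,
                       visit_rate = 1,
                       lookback_days = 1825L,
                       spike_half_width_days = 30L,
                       spike_multiplier = 8,
                       event_block = "S06",
                       peri_event_block = "R51",
                       index_date_range = as.Date(c("2012-01-01",
                                                    "2015-12-31")),
                       seed = 1L) {
  if (!is_count(n_pairs, min = 1L)) stop_config("n_pairs", "must be >= 1")
  if (length(code_vocabulary) < 1L ||
      !all(grepl("^[A-Z][0-9]{2}$", code_vocabulary)))
    stop_config("code_vocabulary",
                "entries must match one uppercase letter + two digits")
  if (anyDuplicated(code_vocabulary))
    stop_config("code_vocabulary", "entries must be unique")
  if (!is_prob(background_code_prob))
    stop_config("background_code_prob", "must be a probability in [0, 1]")
  if (!is.numeric(visit_rate) || visit_rate < 0)
    stop_config("visit_rate", "must be nonnegative")
  if (!is_count(lookback_days, min = 1L))
    stop_config("lookback_days", "must be a positive integer")
  if (!is_count(spike_half_width_days, min = 0L) ||
      spike_half_width_days >= lookback_days)
    stop_config("spike_half_width_days",
                "must be a nonnegative integer below lookback_days")
  if (!is.numeric(spike_multiplier) || spike_multiplier < 1)
    stop_config("spike_multiplier", "must be >= 1")
  if (!grepl("^[A-Z][0-9]{2}$", event_block) ||
      event_block %in% code_vocabulary)
    stop_config("event_block", "must be a valid block outside the vocabulary")
  if (!grepl("^[A-Z][0-9]{2}$", peri_event_block) ||
      peri_event_block %in% code_vocabulary ||
      peri_event_block == event_block)
    stop_config("peri_event_block",
                "must be a valid block outside the vocabulary")
  if (!inherits(index_date_range, "Date") || length(index_date_range) != 2L ||
      index_date_range[2] < index_date_range[1])
    stop_config("index_date_range", "must be an increasing Date pair")
  if (!is_count(seed)) stop_config("seed", "must be an integer")
  for (i in seq_along(factors_truth)) {
    f <- factors_truth[[i]]
    if (!inherits(f, "planted_factor"))
      stop_config("factors_truth", "entries must be planted_factor objects")
    if (!all(f$member_codes %in% code_vocabulary))
      stop_config("factors_truth",
                  sprintf("factor %d has member codes outside the vocabulary",
                          i))
  }
  structure(
    list(n_pairs = as.integer(n_pairs),
         code_vocabulary = code_vocabulary,
         factors_truth = factors_truth,
         background_code_prob = background_code_prob,
         visit_rate = visit_rate,
         lookback_days = as.integer(lookback_days),
         spike_half_width_days = as.integer(spike_half_width_days),
         spike_multiplier = spike_multiplier,
         event_block = event_block,
         peri_event_block = peri_event_block,
         index_date_range = index_date_range,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Case-arm carrier prevalence implied by the reference prevalence and the
# planted odds ratio.
case_prevalence <- function(p0, odds_ratio) {
  odds1 <- odds_ratio * p0 / (1 - p0)
  odds1 / (1 + odds1)
}

#' Closed-form factor-score odds ratio implied by a configuration
#'
#' The binary factor-based score ("any member code present") attenuates the
#' planted carrier-level odds ratio whenever member codes are noisy
#' (`code_prob_given_carrier < 1`) or arise from the background process. This
#' returns the exact population odds ratio of the score for case vs reference
#' membership, the estimand that matched odds-ratio estimation targets.
#'
#' @param config a [sim_config()].
#' @param factor_id index into `config$factors_truth`.
#' @return Named list with the score prevalences per arm and the true score OR.
#' @export
true_factor_or <- function(config, factor_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$factors_truth[[factor_id]]
  bg <- config$background_code_prob
  m <- length(f$member_codes)
  u <- 1 - (1 - f$code_prob_given_carrier) * (1 - bg)
  e1 <- 1 - (1 - u)^m      # score prob given carrier
  e0 <- 1 - (1 - bg)^m     # score prob given non-carrier
  p0 <- f$carrier_prevalence
  p1 <- case_prevalence(p0, f$case_odds_ratio)
  pi1 <- p1 * e1 + (1 - p1) * e0
  pi0 <- p0 * e1 + (1 - p0) * e0
  list(case_score_prob = pi1, reference_score_prob = pi0,
       odds_ratio = pi1 * (1 - pi0) / ((1 - pi1) * pi0))
}

#' Expected per-code prevalence implied by a configuration
#'
#' @param config a [sim_config()].
#' @return Matrix (codes x arms "case"/"reference") of activation
#'   probabilities; since every active code is expressed on an in-window
#'   visit, these are also the expected binary-matrix column means.
#' @export
expected_code_prevalence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  V <- config$code_vocabulary
  bg <- config$background_code_prob
  keep <- matrix(1 - bg, nrow = length(V), ncol = 2,
                 dimnames = list(V, c("case", "reference")))
  for (f in config$factors_truth) {
    p0 <- f$carrier_prevalence
    p1 <- case_prevalence(p0, f$case_odds_ratio)
    j <- match(f$member_codes, V)
    keep[j, "case"] <- keep[j, "case"] *
      (1 - p1 * f$code_prob_given_carrier)
    keep[j, "reference"] <- keep[j, "reference"] *
      (1 - p0 * f$code_prob_given_carrier)
  }
  1 - keep
}

#' Generate a matched administrative-claims cohort with known ground truth
#'
#' Simulates visit-level records for `n_pairs` matched case-reference pairs.
#' Each patient receives `K = 1 + Poisson(visit_rate * years - 1)` history
#' visits uniformly inside the lookback window, one anchor visit on the index
#' date (carrying the event block for cases), and -- for references -- `K`
#' mirrored post-index visits so the visit-midpoint rule recovers the anchor
#' exactly. Case visit intensity within the spike half-width of the index date
#' is multiplied by `spike_multiplier`; spike visits carry only the peri-event
#' filler block. Latent carrier status is drawn per patient with case and
#' reference odds differing by each factor's `case_odds_ratio`; active codes
#' (factor-expressed or background) are scattered uniformly over the
#' patient's history visits, so every active code is observable in the
#' lookback window.
#'
#' @param config a [sim_config()].
#' @return List with elements `visits` (long-format visit table: `visit_id`,
#'   `patient_id`, `visit_date`, `setting`, `dx`; one row per diagnosis, `NA`
#'   dx for diagnosis-free visits), `pairing` (one row per matched pair with
#'   shared matching covariates), and `truth` (list: `carriers` long table of
#'   patient x factor carrier flags, `index_dates` named Date vector,
#'   `factor_or` data frame of planted and score-level true ORs).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  npat <- 2L * n
  case_ids <- sprintf("C%06d", seq_len(n))
  ref_ids <- sprintf("R%06d", seq_len(n))
  pat <- c(case_ids, ref_ids)
  is_case <- rep(c(TRUE, FALSE), each = n)

  L <- config$lookback_days
  w <- config$spike_half_width_days
  years <- L / 365

  day0 <- as.integer(config$index_date_range[1])
  day1 <- as.integer(config$index_date_range[2])
  t0 <- if (day1 > day0) {
    day0 + sample.int(day1 - day0 + 1L, npat, replace = TRUE) - 1L
  } else rep(day0, npat)

  # ---- visit skeleton ------------------------------------------------------
  K <- 1L + rpois(npat, max(config$visit_rate * years - 1, 0))
  H <- sum(K)
  hpat <- rep.int(seq_len(npat), K)
  hdate <- t0[hpat] - (sample.int(L - w, H, replace = TRUE) + w)

  ridx <- which(!is_case)
  Kr <- K[ridx]
  M <- sum(Kr)
  mpat <- rep.int(ridx, Kr)
  mdate <- t0[mpat] + (sample.int(L - w, M, replace = TRUE) + w)

  cidx <- which(is_case)
  lam_spike <- config$spike_multiplier * config$visit_rate / 365 * (2 * w + 1)
  S <- rpois(n, lam_spike)
  spat <- rep.int(cidx, S)
  sdate <- t0[spat] + (sample.int(2L * w + 1L, sum(S), replace = TRUE) -
                         w - 1L)

  lam_post <- config$visit_rate / 365 * (365 - w)
  P <- rpois(n, max(lam_post, 0))
  ppat <- rep.int(cidx, P)
  pdate <- t0[ppat] + (sample.int(365L - w, sum(P), replace = TRUE) + w)

  enc_pid <- c(hpat, mpat, seq_len(npat), spat, ppat)
  enc_date <- c(hdate, mdate, t0, sdate, pdate)
  n_enc <- length(enc_pid)
  enc_setting <- sample(c("emergency", "acute"), n_enc, replace = TRUE,
                        prob = c(0.82, 0.18))
  anchor_row <- H + M + seq_len(npat)
  spike_row <- H + M + npat + seq_along(spat)

  # ---- code activation -----------------------------------------------------
  V <- config$code_vocabulary
  d <- length(V)
  act <- matrix(runif(npat * d) < config$background_code_prob, npat, d)
  nf <- length(config$factors_truth)
  carrier <- matrix(FALSE, npat, max(nf, 1L))
  for (fi in seq_len(nf)) {
    f <- config$factors_truth[[fi]]
    p1 <- case_prevalence(f$carrier_prevalence, f$case_odds_ratio)
    pr <- ifelse(is_case, p1, f$carrier_prevalence)
    carr <- runif(npat) < pr
    carrier[, fi] <- carr
    ci <- which(carr)
    if (length(ci)) {
      j <- match(f$member_codes, V)
      expr <- matrix(runif(length(ci) * length(j)) <
                       f$code_prob_given_carrier, length(ci), length(j))
      act[ci, j] <- act[ci, j] | expr
    }
  }

  # ---- scatter active codes over in-window history visits ------------------
  aw <- which(act, arr.ind = TRUE)
  hfirst <- cumsum(K) - K + 1L
  vi <- integer(0)
  if (nrow(aw)) {
    vi <- hfirst[aw[, 1L]] +
      as.integer(floor(runif(nrow(aw)) * K[aw[, 1L]]))
  }

  dx_enc <- c(vi, anchor_row[cidx], spike_row)
  dx_code <- c(V[aw[, 2L]],
               rep(config$event_block, length(cidx)),
               rep(config$peri_event_block, length(spat)))
  bare <- setdiff(seq_len(n_enc), unique(dx_enc))
  row_enc <- c(dx_enc, bare)
  row_code <- c(dx_code, rep(NA_character_, length(bare)))

  visits <- data.frame(
    visit_id = row_enc,
    patient_id = pat[enc_pid[row_enc]],
    visit_date = as.Date(enc_date[row_enc], origin = "1970-01-01"),
    setting = enc_setting[row_enc],
    dx = row_code,
    stringsAsFactors = FALSE)
  o <- order(visits$patient_id, visits$visit_date, visits$visit_id,
             visits$dx, method = "radix")
  visits <- visits[o, , drop = FALSE]
  rownames(visits) <- NULL

  # ---- pairing + truth -----------------------------------------------------
  age <- pmin(pmax(round(rnorm(n, 36.2, 25.3)), 0), 105)
  pairing <- data.frame(
    case_id = case_ids,
    reference_id = ref_ids,
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.57, 0.43)),
    income_quintile = sample.int(5L, n, replace = TRUE),
    rural = rbinom(n, 1L, 0.16),
    stringsAsFactors = FALSE)

  carriers <- if (nf > 0L) {
    data.frame(
      patient_id = rep(pat, nf),
      factor_id = rep(seq_len(nf), each = npat),
      carrier = as.integer(carrier[, seq_len(nf)]),
      stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(0), factor_id = integer(0),
               carrier = integer(0))
  }
  factor_or <- if (nf > 0L) {
    data.frame(
      factor_id = seq_len(nf),
      carrier_odds_ratio = vapply(config$factors_truth,
                                  function(f) f$case_odds_ratio, 0),
      score_odds_ratio = vapply(seq_len(nf), function(i)
        true_factor_or(config, i)$odds_ratio, 0))
  } else {
    data.frame(factor_id = integer(0), carrier_odds_ratio = numeric(0),
               score_odds_ratio = numeric(0))
  }

  list(visits = visits,
       pairing = pairing,
       truth = list(
         carriers = carriers,
         index_dates = stats::setNames(
           as.Date(t0, origin = "1970-01-01"), pat),
         factor_or = factor_or))
}

#' Generate a global-null matched cohort
#'
#' Forces every planted factor's odds ratio to 1, so case and reference code
#' content are exchangeable draws from one generating process and every
#' per-code null hypothesis is true. The peri-index visit spike is retained
#' (it is a timing feature, not a code-content feature; spike visits carry
#' only the peri-event filler block, which lies outside the code vocabulary).
#'
#' @param config a [sim_config()].
#' @return List with `visits` and `pairing` tables (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  null_cfg <- config
  null_cfg$factors_truth <- lapply(config$factors_truth, function(f) {
    f$case_odds_ratio <- 1
    f
  })
  out <- generate_cohort(null_cfg)
  list(visits = out$visits, pairing = out$pairing)
}
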