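#' Default pipeline configuration
#'
#' A self-contained demonstration configuration: a synthetic cohort with
#' three planted comorbidity factors of moderate-to-strong effect plus
#' background coding noise, analyzed with the default five-year lookback,
#' automatic peri-index window detection, FDR 5% screening, 0.2 loading
#' cutoff, and AUC-based factor-count selection.
#'
#' @param n_pairs number of matched pairs.
#' @param seed master seed (generator and split assignment derive from it).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(n_pairs = 6000, seed = 20240401) {
  vocab <- default_code_vocabulary(60)
  list(
    simulate = list(
      n_pairs = n_pairs,
      code_vocabulary = vocab,
      background_code_prob = 0.03,
      visit_rate = 1,
      spike_multiplier = 8,
      seed = seed,
      factors = list(
        list(member_codes = vocab[1:6], carrier_prevalence = 0.30,
             code_prob_given_carrier = 0.55, case_odds_ratio = 3.0),
        list(member_codes = vocab[11:15], carrier_prevalence = 0.20,
             code_prob_given_carrier = 0.60, case_odds_ratio = 2.2),
        list(member_codes = vocab[21:26], carrier_prevalence = 0.12,
             code_prob_given_carrier = 0.60, case_odds_ratio = 4.0))),
    analysis = list(
      lookback_days = 1825L,
      exclusion_days = "auto",
      event_blocks = "S06",
      split_fractions = list(training = 0.5, validation = 0.25,
                             testing = 0.25),
      split_seed = seed + 1L,
      q = 0.05,
      test_variant = "auto",
      cutoff = 0.2,
      k = "auto",
      candidates = 1:8,
      cum_var_threshold = 0.8,
      font_range = c(10, 60)))
}

# Coerce the nested config (possibly read from YAML) into a sim_config.
config_to_sim <- function(sim) {
  factors <- lapply(sim$factors %||% list(), function(f)
    planted_factor(unlist(f$member_codes), f$carrier_prevalence,
                   f$code_prob_given_carrier, f$case_odds_ratio))
  sim_config(
    n_pairs = sim$n_pairs,
    code_vocabulary = unlist(sim$code_vocabulary %||%
                               default_code_vocabulary(60)),
    factors_truth = factors,
    background_code_prob = sim$background_code_prob %||% 0.02,
    visit_rate = sim$visit_rate %||% 1,
    lookback_days = sim$lookback_days %||% 1825L,
    spike_half_width_days = sim$spike_half_width_days %||% 30L,
    spike_multiplier = sim$spike_multiplier %||% 8,
    event_block = sim$event_block %||% "S06",
    peri_event_block = sim$peri_event_block %||% "R51",
    seed = sim$seed %||% 1L)
}

#' Run the full mining pipeline
#'
#' Chains simulate (or load) -> index dates -> peri-index window detection ->
#' split assignment -> code-matrix construction -> McNemar/BY screening on
#' training -> re-testing on validation -> principal-component factor model
#' with retention diagnostics and AUC-based selection -> binary factor
#' scores and matched odds ratios on testing -> factor table, word-cloud
#' weights, and cohort summary. All randomness derives from the seeds in the
#' configuration, so two runs with an identical configuration produce
#' byte-identical outputs.
#'
#' @param config nested configuration list (see
#'   [default_pipeline_config()]) or path to a YAML file with the same
#'   structure; supply `input$visits` / `input$pairing` paths instead of a
#'   `simulate` section to analyze existing tables.
#' @param output_dir optional directory; when given, all stage outputs are
#'   written there as CSV/JSON plus a plain-text run log.
#' @return (Invisibly) a list with every stage's result: `cohort`,
#'   `exclusion_days`, `matrix`, `screening`, `model`, `diagnostics`,
#'   `selection`, `factors`, `effects`, `factor_table`, `wordcloud`,
#'   `summary`, `log`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  an <- config$analysis
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    scfg <- config_to_sim(config$simulate)
    gen <- generate_cohort(scfg)
    visits <- gen$visits
    pairing <- gen$pairing
    truth <- gen$truth
    say("simulate: %d pairs, %d codes, %d planted factors, seed %d",
        scfg$n_pairs, length(scfg$code_vocabulary),
        length(scfg$factors_truth), scfg$seed)
  } else {
    visits <- read_visit_table(config$input$visits)
    pairing <- read_pairing_table(config$input$pairing)
    say("input: %s / %s", config$input$visits, config$input$pairing)
  }

  event_blocks <- unlist(an$event_blocks %||% "S06")
  index_dates <- assign_index_dates(visits, pairing, event_blocks)

  lookback <- an$lookback_days %||% 1825L
  exclusion <- an$exclusion_days %||% "auto"
  if (identical(exclusion, "auto")) {
    hist <- relative_day_histogram(visits, index_dates,
                                   patient_ids = pairing$case_id)
    exclusion <- detect_event_window(hist)
    say("window: detected peri-index half-width %d days", exclusion)
  } else {
    say("window: configured exclusion %d days", as.integer(exclusion))
  }

  fractions <- unlist(an$split_fractions %||%
                        c(training = 0.5, validation = 0.25,
                          testing = 0.25))
  split <- assign_splits(nrow(pairing), fractions,
                         seed = an$split_seed %||% 1L)
  cohort <- matched_cohort(pairing, index_dates, split)
  say("splits: %s", paste(sprintf("%s=%d", names(table(split)),
                                  as.integer(table(split))),
                          collapse = " "))

  mat <- build_code_matrix(visits, cohort, lookback_days = lookback,
                           exclusion_days = exclusion)
  say("matrix: %d patients x %d blocks", nrow(mat), ncol(mat))

  scr_cfg <- screening_config(q = an$q %||% 0.05,
                              test_variant = an$test_variant %||% "auto")
  screened <- screen_codes(mat, cohort, "training", scr_cfg)
  screened <- validate_codes(screened, mat, cohort, "validation", scr_cfg)
  say("screening: %d tested, %d BY-significant, %d with OR>1, %d validated",
      nrow(screened), sum(screened$by_significant),
      sum(screened$by_rejected), sum(screened$validated))

  validated <- screened$block[screened$validated]
  if (length(validated) < 2L)
    stop("fewer than two validated codes; factor analysis needs >= 2",
         call. = FALSE)
  train_ids <- c(split_ids(cohort, "training", "case"),
                 split_ids(cohort, "training", "reference"))
  corr <- correlation_matrix(mat[train_ids, , drop = FALSE], validated)
  model <- principal_component_factors(corr)
  diagnostics <- withCallingHandlers(
    retention_diagnostics(model$eigenvalues,
                          an$cum_var_threshold %||% 0.8),
    warning = function(w) invokeRestart("muffleWarning"))
  say("factors: %d codes, kaiser=%d, scree elbow=%d, k(cumvar)=%d",
      length(validated), diagnostics$kaiser, diagnostics$scree_elbow,
      diagnostics$k_cumulative)

  cutoff <- an$cutoff %||% 0.2
  k_cfg <- an$k %||% "auto"
  candidates <- unlist(an$candidates %||%
                         seq_len(min(8L, length(validated))))
  candidates <- candidates[candidates <= length(validated)]
  selection <- NULL
  if (identical(k_cfg, "auto")) {
    selection <- select_k_by_auc(model, candidates, mat, cohort, cutoff)
    k <- selection$k
    say("selection: k=%d by validation AUC (%s)", k,
        paste(sprintf("k=%s:%.4f", names(selection$auc), selection$auc),
              collapse = " "))
  } else {
    k <- as.integer(k_cfg)
    say("selection: k=%d (configured)", k)
  }
  factors <- assign_codes_to_factors(model, k, cutoff)
  say("membership: %s",
      paste(vapply(factors, function(f)
        sprintf("f%d:%d", f$factor_id, length(f$member_codes)), ""),
        collapse = " "))

  effects <- evaluate_factors(factors, mat, cohort, "testing")
  table_out <- build_factor_table(effects, factors)
  wc_freq <- wordcloud_weights(effects, "frequency",
                               unlist(an$font_range %||% c(10, 60)))
  wc_or <- wordcloud_weights(effects, "odds_ratio",
                             unlist(an$font_range %||% c(10, 60)))
  summary_out <- summarize_cohort(cohort, visits, lookback, exclusion)

  res <- list(visits = visits, pairing = pairing, truth = truth,
              cohort = cohort, exclusion_days = as.integer(exclusion),
              matrix = mat, screening = screened, model = model,
              diagnostics = diagnostics, selection = selection,
              factors = factors, effects = effects,
              factor_table = table_out,
              wordcloud = list(frequency = wc_freq, odds_ratio = wc_or),
              summary = summary_out, log = log_lines)
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  invisible(res)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the visit/pairing tables, split assignment, screening results,
#' loadings and scree table, factor definitions (JSON), testing-split effect
#' estimates, the rendered factor table, word-cloud weights (JSON), the
#' cohort summary, and a plain-text run log. Output is deterministic: no
#' timestamps, fixed column order, fixed number formatting.
#'
#' @param res result list from [run_pipeline()].
#' @param output_dir directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)
  write_visit_table(res$visits, path("visits.csv"))
  write_pairing_table(res$pairing, path("pairing.csv"))
  splits <- data.frame(case_id = res$cohort$pairs$case_id,
                       split = res$cohort$pairs$split)
  write.csv(splits, path("splits.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(res$truth))
    write.csv(res$truth$carriers, path("truth_carriers.csv"),
              row.names = FALSE, quote = FALSE)
  scr <- res$screening
  write.csv(format(scr, digits = 15, scientific = FALSE, trim = TRUE),
            path("screening.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(component = seq_along(res$model$eigenvalues),
                       eigenvalue = res$model$eigenvalues),
            path("scree.csv"), row.names = FALSE, quote = FALSE)
  write.csv(cbind(block = res$model$codes,
                  as.data.frame(res$model$loadings)),
            path("loadings.csv"), row.names = FALSE, quote = FALSE)
  defs <- lapply(res$factors, function(f)
    list(factor_id = f$factor_id,
         member_codes = as.list(f$member_codes),
         loadings = as.list(round(f$loadings, 6))))
  jsonlite::write_json(defs, path("factor_definitions.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.csv(res$effects, path("effects.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(res$factor_table, path("factor_table.csv"),
            row.names = FALSE, quote = TRUE)
  jsonlite::write_json(res$wordcloud$frequency,
                       path("wordcloud_frequency.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(res$wordcloud$odds_ratio,
                       path("wordcloud_odds_ratio.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  write.csv(res$summary$covariates, path("summary_covariates.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(cbind(arm = rownames(res$summary$visits), res$summary$visits),
            path("summary_visits.csv"), row.names = FALSE, quote = FALSE)
  writeLines(res$log, path("run_log.txt"))
  invisible(output_dir)
}
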