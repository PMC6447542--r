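#' Histogram of visit counts by day offset from the index date
#'
#' @param visits long-format visit table.
#' @param index_dates named `Date` vector per patient.
#' @param patient_ids patients to include (default: all in `index_dates`).
#' @param range integer vector of length 2: offsets to tabulate.
#' @return Named integer vector of encounter counts indexed by day offset
#'   (visit date minus index date; negative = pre-index).
#' @export
relative_day_histogram <- function(visits, index_dates,
                                   patient_ids = names(index_dates),
                                   range = c(-120L, 120L)) {
  enc <- unique(visits[visits$patient_id %in% patient_ids,
                       c("patient_id", "visit_id", "visit_date")])
  off <- as.integer(enc$visit_date) -
    as.integer(index_dates[enc$patient_id])
  grid <- seq.int(range[1], range[2])
  counts <- tabulate(match(off, grid), nbins = length(grid))
  stats::setNames(as.integer(counts), grid)
}

#' Detect the peri-index event-window half-width
#'
#' Operationalizes the visual inspection of the peri-index visit histogram as
#' a reproducible scan: the daily counts are smoothed with a centred 7-day
#' moving average and compared against a tolerance band around the baseline
#' region (offsets beyond +/-`baseline_from` days). The returned half-width is
#' the smallest `w` such that the smoothed frequency at every offset with
#' `w <= |offset| <= cap` stays inside the band; a flat histogram therefore
#' yields 0. The band is `median +/- 2 * max(MAD, sqrt(median / 7))`: median
#' and median absolute deviation of the raw daily counts in the baseline
#' region, with the tolerance floored at the Poisson count-noise standard
#' deviation of a 7-day average, so that noiseless constructed inputs are not
#' held to a zero-width band.
#'
#' @param counts named integer vector of daily visit counts indexed by day
#'   offset from the index date (must cover at least +/-`cap`, with a nonempty
#'   baseline region beyond `baseline_from`).
#' @param baseline_from offsets with `|offset| > baseline_from` form the
#'   baseline region (default 90).
#' @param cap maximum half-width considered (default 90); if even the smoothed
#'   frequency at +/-`cap` lies outside the band, a window-not-found error is
#'   raised (the caller may override the window via configuration).
#' @param ma_width moving-average width in days (odd; default 7).
#' @return Integer half-width in days (0 when no peak is present).
#' @export
detect_event_window <- function(counts, baseline_from = 90L, cap = 90L,
                                ma_width = 7L) {
  off <- as.integer(names(counts))
  if (is.null(names(counts)) || anyNA(off))
    stop("counts must be named by integer day offset", call. = FALSE)
  o <- order(off)
  off <- off[o]
  x <- as.numeric(counts[o])
  if (min(off) > -cap || max(off) < cap)
    stop(sprintf("histogram must cover at least +/-%d days", cap),
         call. = FALSE)
  half <- (ma_width - 1L) %/% 2L
  sm <- stats::filter(x, rep(1 / ma_width, ma_width), sides = 2)
  sm <- as.numeric(sm)
  base <- abs(off) > baseline_from
  if (!any(base))
    stop("baseline region beyond the cap is empty", call. = FALSE)
  med <- stats::median(x[base])
  dev <- stats::mad(x[base], center = med, constant = 1)
  tol <- 2 * max(dev, sqrt(max(med, 0) / ma_width))
  usable <- !is.na(sm) & abs(off) <= cap
  outside <- usable & abs(sm - med) > tol
  if (!any(outside)) return(0L)
  wmax <- max(abs(off[outside]))
  if (wmax >= cap)
    stop(sprintf(
      "window-not-found: smoothed peak still outside the baseline band at +/-%d days",
      cap), call. = FALSE)
  wmax + 1L
}
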