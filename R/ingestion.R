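#' Normalize raw diagnosis codes to three-character blocks
#'
#' Strips whitespace and punctuation (`.`, `-`), uppercases, and truncates to
#' the first three characters, collapsing full ICD-10-style codes (e.g.
#' `"S06.0"`) to their block (`"S06"`). The provisional research/temporary
#' blocks U98 and U99 are excluded by design and map to `NA` silently;
#' malformed inputs (fewer than three alphanumeric characters, or not
#' letter-digit-digit) also map to `NA` but raise a warning so the offending
#' records can be logged and skipped.
#'
#' @param raw character vector of raw code strings.
#' @return Character vector of blocks, `NA` where excluded or malformed.
#' @seealso [is_excluded_code()]
#' @examples
#' normalize_code(c("S06.0", "s020", "U98.1"))
#' @export
normalize_code <- function(raw) {
  out <- rep(NA_character_, length(raw))
  x <- toupper(gsub("[[:space:].\\-]", "", as.character(raw)))
  ok <- !is.na(x) & nchar(x) >= 3L
  blk <- substr(x[ok], 1L, 3L)
  valid <- grepl("^[A-Z][0-9][0-9]$", blk)
  out[ok][valid] <- blk[valid]
  bad <- !is.na(raw) & nzchar(trimws(raw)) & is.na(out) & !is_excluded_code(raw)
  if (any(bad)) {
    warning(sprintf("skipping %d malformed diagnosis code(s): %s",
                    sum(bad),
                    paste(utils::head(unique(raw[bad]), 5L),
                          collapse = ", ")),
            call. = FALSE)
  }
  out[is_excluded_code(raw)] <- NA_character_
  out
}

#' Is a raw code in an excluded provisional block?
#'
#' @param raw character vector of raw code strings.
#' @return Logical vector, `TRUE` for codes in blocks U98 or U99.
#' @export
is_excluded_code <- function(raw) {
  x <- toupper(gsub("[[:space:].\\-]", "", as.character(raw)))
  !is.na(x) & substr(x, 1L, 3L) %in% c("U98", "U99")
}

#' Select a patient's index date
#'
#' Cases anchor on the date of their earliest visit carrying any event block;
#' references anchor on the middle element of their date-sorted visit list
#' (for even visit counts, the earlier of the two middle visits, keeping the
#' index an actual visit date).
#'
#' @param visits data frame with at least `visit_id`, `visit_date`, `dx` for
#'   one patient (long format; several rows may share a `visit_id`).
#' @param role `"case"` or `"reference"`.
#' @param event_blocks character vector of case-defining blocks.
#' @return A `Date` of length 1.
#' @export
select_index_date <- function(visits, role = c("case", "reference"),
                              event_blocks = "S06") {
  role <- match.arg(role)
  if (nrow(visits) == 0L)
    stop("empty-history: patient has no visits", call. = FALSE)
  if (role == "case") {
    blk <- suppressWarnings(normalize_code(visits$dx))
    hit <- !is.na(blk) & blk %in% event_blocks
    if (!any(hit))
      stop("missing-event: case has no event-coded visit", call. = FALSE)
    return(min(visits$visit_date[hit]))
  }
  enc <- unique(visits[, c("visit_id", "visit_date")])
  dates <- sort(enc$visit_date)
  dates[floor((length(dates) + 1L) / 2L)]
}

# Vectorized index assignment for a full visit table.
assign_index_dates <- function(visits, pairing, event_blocks = "S06") {
  cases <- pairing$case_id
  refs <- pairing$reference_id
  blk <- suppressWarnings(normalize_code(visits$dx))
  ev <- visits[!is.na(blk) & blk %in% event_blocks, , drop = FALSE]
  case_idx <- vapply(split(as.integer(ev$visit_date), ev$patient_id), min, 0L)
  missing_case <- setdiff(cases, names(case_idx))
  if (length(missing_case))
    stop(sprintf("missing-event: %d case(s) have no event-coded visit",
                 length(missing_case)), call. = FALSE)
  rv <- unique(visits[visits$patient_id %in% refs,
                      c("patient_id", "visit_id", "visit_date")])
  ref_idx <- vapply(split(as.integer(rv$visit_date), rv$patient_id),
                    function(d) {
                      d <- sort(d)
                      d[floor((length(d) + 1L) / 2L)]
                    }, 0L)
  missing_ref <- setdiff(refs, names(ref_idx))
  if (length(missing_ref))
    stop(sprintf("empty-history: %d reference(s) have no visits",
                 length(missing_ref)), call. = FALSE)
  idx <- c(case_idx[cases], ref_idx[refs])
  stats::setNames(as.Date(idx, origin = "1970-01-01"), c(cases, refs))
}

#' Assign pairs to training/validation/testing splits
#'
#' Pairs (never individual members) are randomized to splits; largest-
#' remainder apportionment keeps realized counts within one pair of the
#' configured allocation.
#'
#' @param n_pairs number of pairs.
#' @param fractions named numeric vector summing to 1
#'   (default `c(training = 0.5, validation = 0.25, testing = 0.25)`).
#' @param seed integer seed for the permutation.
#' @return Character vector of split labels, one per pair.
#' @export
assign_splits <- function(n_pairs,
                          fractions = c(training = 0.5, validation = 0.25,
                                        testing = 0.25),
                          seed = 1L) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop_config("split_fractions", "must be named")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_config("split_fractions", "must sum to 1")
  counts <- apportion(n_pairs, fractions)
  labels <- rep(names(counts), counts)
  set.seed(seed)
  labels[order(sample.int(n_pairs))]
}

#' Assemble a matched cohort object
#'
#' @param pairing pairing table (`case_id`, `reference_id`, covariates).
#' @param index_dates named `Date` vector covering every patient, e.g. from
#'   [select_index_date()]; if `NULL`, computed from `visits`.
#' @param split character vector of per-pair split labels, e.g. from
#'   [assign_splits()].
#' @param visits long-format visit table (needed when `index_dates` is NULL).
#' @param event_blocks case-defining blocks for index-date computation.
#' @return An object of class `matched_cohort`: the pairing table with a
#'   `split` column plus the per-patient index dates.
#' @export
matched_cohort <- function(pairing, index_dates = NULL, split = NULL,
                           visits = NULL, event_blocks = "S06") {
  stopifnot(all(c("case_id", "reference_id") %in% names(pairing)))
  ids <- c(pairing$case_id, pairing$reference_id)
  if (anyDuplicated(ids))
    stop("each patient must appear in exactly one pair", call. = FALSE)
  if (is.null(index_dates)) {
    if (is.null(visits))
      stop("either index_dates or visits must be supplied", call. = FALSE)
    index_dates <- assign_index_dates(visits, pairing, event_blocks)
  }
  if (!all(ids %in% names(index_dates)))
    stop("index_dates must cover every patient in the pairing",
         call. = FALSE)
  pairs <- pairing
  pairs$split <- if (is.null(split)) NA_character_ else {
    stopifnot(length(split) == nrow(pairing))
    split
  }
  structure(list(pairs = pairs, index_dates = index_dates[ids]),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort: %d pairs\n", nrow(x$pairs)))
  if (!all(is.na(x$pairs$split)))
    print(table(x$pairs$split))
  invisible(x)
}

# Patient ids of one arm restricted to a split.
split_ids <- function(cohort, split, arm = c("case", "reference")) {
  arm <- match.arg(arm)
  sel <- if (is.null(split)) rep(TRUE, nrow(cohort$pairs)) else
    cohort$pairs$split == split
  if (!any(sel)) stop(sprintf("no pairs in split '%s'", split), call. = FALSE)
  if (arm == "case") cohort$pairs$case_id[sel] else
    cohort$pairs$reference_id[sel]
}

#' Build the patient-by-block binary code matrix
#'
#' Entry (p, b) is 1 iff patient p has at least one visit dated in the
#' half-open window `[index - lookback_days, index - exclusion_days)` whose
#' diagnosis normalizes to block b. The index date itself and the peri-index
#' exclusion band are therefore never counted. Patients in the cohort with no
#' qualifying visit contribute all-zero rows.
#'
#' @param visits long-format visit table.
#' @param cohort a [matched_cohort()].
#' @param lookback_days window length in days (default 1825 = five years).
#' @param exclusion_days peri-index exclusion in days (default 30).
#' @param canonical_blocks optional character vector of blocks that must
#'   appear on the code axis even if unobserved.
#' @return Integer matrix in \{0,1\} with patient ids as row names (cohort
#'   order: all cases, then all references) and blocks as column names;
#'   attributes `lookback_days` and `exclusion_days` record the window.
#' @export
build_code_matrix <- function(visits, cohort, lookback_days = 1825L,
                              exclusion_days = 30L,
                              canonical_blocks = NULL) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (!(lookback_days > exclusion_days && exclusion_days >= 0))
    stop("lookback_days must exceed exclusion_days (>= 0)", call. = FALSE)
  ids <- names(cohort$index_dates)
  idx <- as.integer(cohort$index_dates)

  v <- visits[!is.na(visits$dx) & visits$patient_id %in% ids, , drop = FALSE]
  blk <- normalize_code(v$dx)
  keep <- !is.na(blk)
  v <- v[keep, , drop = FALSE]
  blk <- blk[keep]

  pid <- match(v$patient_id, ids)
  off <- idx[pid] - as.integer(v$visit_date)
  inwin <- off > exclusion_days & off <= lookback_days
  pid <- pid[inwin]
  blk <- blk[inwin]

  axis <- sort(unique(c(blk, canonical_blocks)))
  mat <- matrix(0L, nrow = length(ids), ncol = length(axis),
                dimnames = list(ids, axis))
  if (length(pid))
    mat[cbind(pid, match(blk, axis))] <- 1L
  attr(mat, "lookback_days") <- as.integer(lookback_days)
  attr(mat, "exclusion_days") <- as.integer(exclusion_days)
  mat
}

#' Write / read the delimited visit and pairing tables
#'
#' The on-disk visit format is one row per encounter with columns
#' `patient_id, visit_date` (ISO-8601), `setting`, `dx_01` ... `dx_25`;
#' encounters carrying more than 25 diagnoses are split into same-day rows.
#' The pairing format is `case_id, reference_id, age, sex, income_quintile,
#' rural`.
#'
#' @param visits long-format visit table (as returned by [generate_cohort()]).
#' @param path file path.
#' @return `write_visit_table()` returns `path` invisibly;
#'   `read_visit_table()` returns the long-format table.
#' @name visit_io
NULL

#' @rdname visit_io
#' @export
write_visit_table <- function(visits, path) {
  key <- paste(visits$patient_id, visits$visit_id, sep = "\r")
  spl <- split(seq_len(nrow(visits)), key)
  rows <- lapply(spl, function(i) {
    dx <- visits$dx[i]
    dx <- dx[!is.na(dx)]
    chunks <- if (length(dx) == 0L) list(character(0)) else
      split(dx, (seq_along(dx) - 1L) %/% 25L)
    lapply(chunks, function(ch) {
      pad <- c(ch, rep("", 25L - length(ch)))
      c(visits$patient_id[i[1L]],
        format(visits$visit_date[i[1L]], "%Y-%m-%d"),
        visits$setting[i[1L]], pad)
    })
  })
  rows <- do.call(rbind, unlist(rows, recursive = FALSE))
  colnames(rows) <- c("patient_id", "visit_date", "setting",
                      sprintf("dx_%02d", 1:25))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$visit_date, method = "radix"), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname visit_io
#' @export
read_visit_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  dxcols <- grep("^dx_", names(df))
  long <- lapply(seq_len(nrow(df)), function(i) {
    dx <- unlist(df[i, dxcols], use.names = FALSE)
    dx <- dx[!is.na(dx) & nzchar(dx)]
    if (length(dx) == 0L) dx <- NA_character_
    data.frame(visit_id = i, patient_id = df$patient_id[i],
               visit_date = as.Date(df$visit_date[i]),
               setting = df$setting[i], dx = dx,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, long)
  rownames(out) <- NULL
  out
}

#' @rdname visit_io
#' @export
write_pairing_table <- function(pairing, path) {
  write.csv(pairing[, c("case_id", "reference_id", "age", "sex",
                        "income_quintile", "rural")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname visit_io
#' @export
read_pairing_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
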