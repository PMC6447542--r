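test_that("code normalization truncates, uppercases, and excludes U98/U99", {
  expect_identical(normalize_code("S06.0"), "S06")
  expect_identical(normalize_code("s020"), "S02")
  expect_identical(normalize_code(" I25 "), "I25")
  expect_identical(normalize_code("M54-1"), "M54")
  expect_true(is.na(normalize_code("U98.1")))
  expect_true(is.na(normalize_code("U99")))
  expect_true(is_excluded_code("U98.1"))
  expect_false(is_excluded_code("S06.0"))
  expect_warning(res <- normalize_code(c("A1", "S06.0")), "malformed")
  expect_identical(res, c(NA_character_, "S06"))
  expect_warning(expect_true(is.na(normalize_code("1234"))), "malformed")
})

test_that("index dates follow the earliest-event and visit-midpoint rules", {
  v <- make_visits("p1", c(0, 100, 400), c("I25", "S06.0", "S060"))
  expect_identical(select_index_date(v, "case"),
                   as.Date("2015-06-01") + 100)

  odd <- make_visits("p2", c(0, 50, 100))
  expect_identical(select_index_date(odd, "reference"),
                   as.Date("2015-06-01") + 50)
  even <- make_visits("p3", c(0, 10, 90, 100))
  expect_identical(select_index_date(even, "reference"),
                   as.Date("2015-06-01") + 10)

  expect_error(select_index_date(make_visits("p4", 0, "I25"), "case"),
               "missing-event")
  expect_error(select_index_date(make_visits("p5", numeric(0))[0, ], "case"),
               "empty-history")
})

test_that("window boundaries are half-open and binarization is idempotent", {
  origin <- as.Date("2015-06-01")
  pairing <- data.frame(case_id = "c1", reference_id = "r1", age = 40,
                        sex = "M", income_quintile = 3, rural = 0)
  idx <- setNames(as.Date(c(origin, origin)), c("c1", "r1"))
  mk <- function(day, code) {
    rbind(make_visits("c1", day, code), make_visits("r1", -500))
  }
  cohort <- matched_cohort(pairing, idx, split = "training")
  entry <- function(day) {
    m <- build_code_matrix(mk(day, "I25.9"), cohort,
                           lookback_days = 1825, exclusion_days = 30,
                           canonical_blocks = "I25")
    m["c1", "I25"]
  }
  expect_identical(entry(-29), 0L)   # inside the exclusion band
  expect_identical(entry(-30), 0L)   # exclusion boundary itself excluded
  expect_identical(entry(-31), 1L)
  expect_identical(entry(-1825), 1L) # lookback boundary included
  expect_identical(entry(-1826), 0L)
  expect_identical(entry(0), 0L)     # index date never counted

  # repeated coding of one block stays a single 1
  v3 <- rbind(make_visits("c1", c(-100, -200, -300), "I25"),
              make_visits("r1", -500))
  m3 <- build_code_matrix(v3, cohort)
  expect_identical(m3["c1", "I25"], 1L)

  # excluded blocks never reach the code axis
  vu <- rbind(make_visits("c1", c(-100, -101), c("U98.1", "I25")),
              make_visits("r1", -500))
  expect_false("U98" %in% colnames(build_code_matrix(vu, cohort)))
})

test_that("rebuilding from the matrix's own nonzero visits reproduces it", {
  fix <- tiny_planted_cohort(n_pairs = 300, seed = 8)
  m1 <- fix$matrix
  v <- fix$generated$visits
  blk <- suppressWarnings(normalize_code(v$dx))
  keep <- !is.na(blk) & blk %in% colnames(m1) &
    m1[cbind(match(v$patient_id, rownames(m1)), match(blk, colnames(m1)))] == 1L
  m2 <- build_code_matrix(v[keep, ], fix$cohort,
                          canonical_blocks = colnames(m1))
  expect_identical(m1[, colnames(m1)], m2[, colnames(m1)])
})

test_that("enlarging the exclusion window only flips entries 1 -> 0", {
  fix <- tiny_planted_cohort(n_pairs = 300, seed = 12)
  m30 <- build_code_matrix(fix$generated$visits, fix$cohort,
                           exclusion_days = 30)
  m400 <- build_code_matrix(fix$generated$visits, fix$cohort,
                            exclusion_days = 400,
                            canonical_blocks = colnames(m30))
  expect_true(all(m400[, colnames(m30)] <= m30))
})

test_that("patients without visit rows become all-zero rows", {
  pairing <- data.frame(case_id = "c1", reference_id = "r1", age = 1,
                        sex = "F", income_quintile = 1, rural = 0)
  idx <- setNames(as.Date(c("2015-06-01", "2015-06-01")), c("c1", "r1"))
  cohort <- matched_cohort(pairing, idx, split = "training")
  v <- make_visits("c1", -100, "I25")
  m <- build_code_matrix(v, cohort)
  expect_identical(sum(m["r1", ]), 0L)
  expect_identical(rownames(m), c("c1", "r1"))
})

test_that("split assignment is pair-level, seeded, and within one of target", {
  for (n in c(7L, 100L, 1001L)) {
    s <- assign_splits(n, seed = 4)
    tab <- table(s)
    target <- n * c(testing = 0.25, training = 0.5, validation = 0.25)
    expect_true(all(abs(tab[names(target)] - target) <= 1))
  }
  expect_identical(assign_splits(50, seed = 1), assign_splits(50, seed = 1))
  expect_error(assign_splits(10, fractions = c(training = 0.6,
                                               testing = 0.6)),
               "split_fractions")
})

test_that("visit tables round-trip through the wide 25-field CSV format", {
  fix <- tiny_planted_cohort(n_pairs = 40, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_visit_table(fix$generated$visits, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header[1:3], c("patient_id", "visit_date", "setting"))
  expect_length(header, 28)
  back <- read_visit_table(path)
  m2 <- build_code_matrix(back, fix$cohort,
                          canonical_blocks = colnames(fix$matrix))
  expect_identical(fix$matrix[, colnames(fix$matrix)],
                   m2[, colnames(fix$matrix)])

  # an encounter with >25 diagnoses is split into same-day rows
  many <- make_visits("c1", rep(-100, 30), sprintf("A%02d", 1:30))
  many$visit_id <- 1L
  p2 <- tempfile(fileext = ".csv")
  write_visit_table(many, p2)
  wide <- read.csv(p2, stringsAsFactors = FALSE)
  expect_identical(nrow(wide), 2L)
  back2 <- read_visit_table(p2)
  expect_setequal(back2$dx[!is.na(back2$dx)], sprintf("A%02d", 1:30))
})
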