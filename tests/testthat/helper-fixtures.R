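# Fixture builders and independent oracles shared across test files.

# A minimal visit table row set for one visitor, with sensible defaults for
# every column the feature schema can consume.
make_visits <- function(visitor_id = "A",
                        dates,
                        sbp = rep(120, length(dates)),
                        dbp = rep(70, length(dates)),
                        sex = "male",
                        age = 40 + seq_along(dates) - 1,
                        weight = rep(70, length(dates)),
                        height = rep(1.70, length(dates)),
                        ...) {
  n <- length(dates)
  df <- data.frame(
    visitor_id = visitor_id, visit_idx = seq_len(n),
    date = as.Date(dates), sex = sex, age = age,
    sbp = sbp, dbp = dbp, weight = weight, height = height,
    waist = 80, hip = 95, body_fat = 25,
    albumin = 4.5, globulin = 3.0, egfr = 95, hematocrit = 42,
    fev1 = 3.2, fvc = 4.0, mmef = 3.5, lymphocytes = 33, eosinophil = 2.5,
    hearing_right = 15, liver_abnormal = 0, cholesterol = 195, hdl = 50,
    glucose = 97, smoke = "No", alcohol = "No", exercise_freq = "None",
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# Independent brute-force oracle for the windowing rules: a literal scan of
# the pruning rule followed by explicit enumeration of every eligible
# output position. Returns per-visitor train/test sample structures.
bf_window_oracle <- function(dates, n1, n2, max_gap_years = 3) {
  m <- length(dates)
  start <- 1L
  if (m >= 2) {
    for (i in 2:m) {
      if (as.numeric(dates[i] - dates[i - 1]) > max_gap_years * 365.25)
        start <- i
    }
  }
  kept <- start:m
  M <- length(kept)
  if (M <= 1) return(list(train = list(), test = NULL))
  mk <- function(jpos) {
    lo <- max(1L, jpos - n1)
    list(input = kept[lo:(jpos - 1L)], output = kept[jpos])
  }
  test <- mk(M)
  if (M == 2) return(list(train = list(), test = test))
  all_pairs <- lapply(2:(M - 1L), mk)
  keep_n <- min(M - 2L, n2)
  list(train = all_pairs[seq.int(length(all_pairs) - keep_n + 1L,
                                 length(all_pairs))],
       test = test)
}

# Random multi-visitor cohort of bare visits (dates/BP only) for windowing
# property tests: gaps drawn to straddle the 3-year horizon.
random_bare_cohort <- function(n_visitors, seed) {
  set.seed(seed)
  out <- lapply(seq_len(n_visitors), function(i) {
    m <- sample(1:9, 1)
    gaps <- sample(c(200, 400, 700, 1100, 1200, 1500), m - 1, replace = TRUE)
    dates <- as.Date("2010-01-01") + c(0, cumsum(gaps)) +
      cumsum(c(0, rep(1, m - 1)))  # strictly increasing
    make_visits(sprintf("R%04d", i), dates,
                sbp = round(runif(m, 100, 150)),
                dbp = round(runif(m, 60, 95)))
  })
  do.call(rbind, out)
}

# Small cached default cohort shared by several test files.
shared_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(
      cohort_config(n_visitors = 800, seed = 7))
    coh
  }
})
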