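sch <- feature_schema()

test_that("derived factors evaluate their defining formulas", {
  v <- make_visits(dates = "2010-01-01", sbp = 120, dbp = 90,
                   weight = 81, height = 1.80)
  f <- derive_visit_features(v, sch)[1, ]
  expect_equal(f[["map"]], 100)
  expect_equal(f[["pulse_pressure"]], 30)
  expect_equal(f[["has_htn"]], 1)
  expect_equal(f[["bmi"]], 25)
  expect_equal(f[["whr"]], 80 / 95)
  expect_equal(f[["agr"]], 4.5 / 3.0)

  # SBP = DBP = x: MAP collapses to x and pulse pressure to 0
  v2 <- make_visits(dates = "2010-01-01", sbp = 110, dbp = 110)
  f2 <- derive_visit_features(v2, sch)[1, ]
  expect_equal(f2[["map"]], 110)
  expect_equal(f2[["pulse_pressure"]], 0)
})

test_that("missing inputs propagate to missing derived outputs", {
  v <- make_visits(dates = "2010-01-01", waist = NA, weight = NA)
  f <- derive_visit_features(v, sch)[1, ]
  expect_true(is.na(f[["whr"]]))
  expect_true(is.na(f[["bmi"]]))
  expect_false(is.na(f[["map"]]))
})

test_that("questionnaire responses are integer-coded by level", {
  v <- make_visits(dates = rep("2010-01-01", 3))
  v$date <- v$date + 0:2
  v$exercise_freq <- c("None", "Sometimes", "Regular")
  v$smoke <- c("No", "Yes", "No")
  f <- derive_visit_features(v, sch)
  expect_equal(f[, "exercise_freq"], c(0, 1, 2))
  expect_equal(f[, "smoke"], c(0, 1, 0))
  v$smoke[1] <- "Maybe"
  expect_error(derive_visit_features(v, sch), "outside configured levels")
})

test_that("hypertension label thresholds are inclusive", {
  expect_true(label_visit(130, 70))
  expect_false(label_visit(129, 79))
  expect_true(label_visit(110, 80))
  expect_error(label_visit(NA, 70), "present")
})

test_that("linear interpolation imputes over date with nearest-value ends", {
  d <- as.Date(c("2010-01-01", "2011-01-01", "2012-01-01"))
  expect_equal(impute_series(c(10, NA, 30), d), c(10, 20, 30),
               tolerance = 1e-12)
  expect_equal(impute_series(c(NA, NA, NA), d), c(NA, NA, NA))
  expect_equal(impute_series(c(10, 20, 30), d), c(10, 20, 30))
  # ends take the nearest observed value
  expect_equal(impute_series(c(NA, 20, NA), d), c(20, 20, 20))
  # interpolation is over date, not index: unequal gaps
  d2 <- as.Date(c("2010-01-01", "2010-01-02", "2010-01-05"))
  expect_equal(impute_series(c(0, NA, 40), d2), c(0, 10, 40),
               tolerance = 1e-12)
})

test_that("imputation recovers affine-in-date series exactly and never alters observed values", {
  set.seed(4)
  for (trial in 1:20) {
    m <- sample(4:9, 1)
    dates <- as.Date("2010-01-01") + cumsum(c(0, sample(50:900, m - 1, TRUE)))
    a <- runif(1, -2, 2); b <- runif(1, -5, 5)
    truth <- a + b * as.numeric(dates) / 365.25
    masked <- truth
    hide <- sample(2:(m - 1), sample(1:(m - 2), 1))
    masked[hide] <- NA
    imp <- impute_series(masked, dates)
    expect_equal(imp, truth, tolerance = 1e-9)
    expect_identical(imp[-hide], truth[-hide])
  }
})

test_that("questionnaire defaults fill only unanswered items", {
  v <- make_visits(dates = rep("2010-01-01", 2))
  v$date <- v$date + 0:1
  v$smoke <- c(NA, "Yes")
  v$exercise_freq <- c(NA, NA)
  out <- apply_questionnaire_defaults(v, sch)
  expect_equal(out$smoke, c("No", "Yes"))
  expect_equal(out$exercise_freq, c("None", "None"))

  broken <- sch
  broken$default[broken$name == "smoke"] <- NA
  expect_error(apply_questionnaire_defaults(v, broken), "no default")
})

test_that("window encoding pads in front and appends the presence indicator", {
  d <- 266
  for (k in 1:5) {
    vecs <- matrix(seq_len(k * d), nrow = k, byrow = TRUE)
    enc <- encode_window(vecs, n1 = 5)
    expect_length(enc, 5 * d + 5)
    presence <- enc[(5 * d + 1):(5 * d + 5)]
    expect_equal(presence, rep(c(0, 1), c(5 - k, k)))
    expect_equal(sum(presence), k)
    if (k < 5) expect_true(all(enc[seq_len((5 - k) * d)] == 0))
    # real blocks are the plain concatenation in visiting order
    expect_equal(enc[((5 - k) * d + 1):(5 * d)], as.numeric(t(vecs)))
  }
  expect_error(encode_window(matrix(0, 0, 3), 5), "1..n1")
  expect_error(encode_window(matrix(0, 6, 3), 5), "1..n1")
})

test_that("dataset encoding matches per-sample window encoding", {
  coh <- shared_cohort()
  ds <- assemble_dataset(coh, window_config())
  ds$visits <- impute_visits(ds$visits, sch)
  enc <- encode_dataset(ds, sch, 5, split = "test")
  expect_equal(ncol(enc$x), 5 * nrow(sch) + 5)
  expect_equal(colnames(enc$x), window_colnames(sch, 5))
  feat <- derive_visit_features(ds$visits, sch)
  i <- which.max(enc$samples$n_input)
  expect_equal(enc$x[i, ],
               setNames(encode_window(feat[enc$samples$input_rows[[i]], ,
                                           drop = FALSE], 5),
                        colnames(enc$x)))
  expect_equal(enc$y, as.integer(enc$samples$label))
})

test_that("imputation over a visit table fills only what it can", {
  v <- make_visits(dates = c("2010-01-01", "2011-01-01", "2012-01-01"))
  v$waist <- c(70, NA, 80)
  v$glucose <- c(NA, NA, NA)
  out <- impute_visits(v, sch)
  expect_equal(out$waist, c(70, 75, 80), tolerance = 1e-9)
  expect_true(all(is.na(out$glucose)))
})
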