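#' Configuration for the synthetic checkup cohort generator
#'
#' Assembles the generative parameters for [generate_cohort()]. The defaults
#' describe a routine-checkup population: visit counts with a mode at two
#' visits, inter-visit intervals of mostly one to two years with a tail
#' beyond three years (so gap pruning is exercised), anthropometry driven by
#' a slowly drifting BMI, and blood pressure that is first-order
#' autoregressive with additive age and BMI effects.
#'
#' Blood pressure at visit t follows
#' \deqn{SBP_t = b0 + \beta_{age} age_t + \beta_{bmi} BMI_t +
#'   \beta_{persist} SBP_{t-1} + \epsilon_t,}
#' and analogously for DBP with its own intercept and noise scale. The first
#' visit is drawn from the stationary distribution implied by the
#' coefficients. Companion anthropometric factors (waist and hip
#' circumference, body-fat percentage) are linear in BMI with sex-specific
#' slopes and intercepts, so their pooled correlation with BMI is strong and
#' sex-stratified slope recovery is meaningful.
#'
#' @param n_visitors number of visitors to simulate.
#' @param visit_count_probs probability vector over 1..K visits per visitor;
#'   must sum to 1.
#' @param interval_years support of the inter-visit gap distribution, in
#'   years (a small uniform day-level jitter is added on top).
#' @param interval_probs probabilities matching `interval_years`.
#' @param bmi_mean,bmi_sd mean and SD of baseline BMI (kg/m^2).
#' @param bmi_walk_sd SD of the per-visit BMI random-walk step.
#' @param companion_slopes named list of `c(male=, female=)` slopes of each
#'   companion factor on BMI.
#' @param companion_intercepts named list of matching intercepts.
#' @param companion_noise_sd named vector of residual SDs per companion
#'   factor.
#' @param beta_bmi,beta_age,beta_persist coefficients of the blood-pressure
#'   model (shared between SBP and DBP).
#' @param b0_sbp,b0_dbp intercepts of the SBP and DBP equations (mmHg).
#' @param noise_sd_sbp,noise_sd_dbp innovation SDs (mmHg).
#' @param missing_rate fraction of physical-exam cells set missing
#'   completely at random; blood pressure, sex, age and dates are never
#'   masked.
#' @param questionnaire_nonresponse fraction of questionnaire answers left
#'   blank (to exercise default-response handling).
#' @param seed integer seed; identical seeds yield identical cohorts.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_visitors = 1000,
                          visit_count_probs = c(0.30, 0.35, 0.15, 0.08,
                                                0.06, 0.03, 0.02, 0.01),
                          interval_years = c(1, 1.5, 2, 2.5, 3, 4, 5),
                          interval_probs = c(0.40, 0.20, 0.18, 0.10,
                                             0.05, 0.05, 0.02),
                          bmi_mean = 23.5, bmi_sd = 3.2, bmi_walk_sd = 0.5,
                          companion_slopes = list(
                            waist    = c(male = 2.4,  female = 2.1),
                            hip      = c(male = 1.7,  female = 1.95),
                            body_fat = c(male = 1.6,  female = 1.8)),
                          companion_intercepts = list(
                            waist    = c(male = 28,    female = 24),
                            hip      = c(male = 55,    female = 50),
                            body_fat = c(male = -15.6, female = -13.3)),
                          companion_noise_sd = c(waist = 2.5, hip = 2.2,
                                                 body_fat = 1.5),
                          beta_bmi = 0.8, beta_age = 0.2, beta_persist = 0.6,
                          b0_sbp = 19.4, b0_dbp = 1.8,
                          noise_sd_sbp = 8, noise_sd_dbp = 6,
                          missing_rate = 0.10,
                          questionnaire_nonresponse = 0.10,
                          seed = 1L) {
  # partial companion specifications are merged over the defaults so a
  # test can redefine a single factor without restating the others
  defaults <- list(
    slopes = list(waist = c(male = 2.4, female = 2.1),
                  hip = c(male = 1.7, female = 1.95),
                  body_fat = c(male = 1.6, female = 1.8)),
    intercepts = list(waist = c(male = 28, female = 24),
                      hip = c(male = 55, female = 50),
                      body_fat = c(male = -15.6, female = -13.3)),
    noise = c(waist = 2.5, hip = 2.2, body_fat = 1.5))
  companion_slopes <- utils::modifyList(defaults$slopes, companion_slopes)
  companion_intercepts <- utils::modifyList(defaults$intercepts,
                                            companion_intercepts)
  ns <- defaults$noise
  ns[names(companion_noise_sd)] <- companion_noise_sd
  companion_noise_sd <- ns
  cfg <- list(n_visitors = n_visitors,
              visit_count_probs = visit_count_probs,
              interval_years = interval_years,
              interval_probs = interval_probs,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_walk_sd = bmi_walk_sd,
              companion_slopes = companion_slopes,
              companion_intercepts = companion_intercepts,
              companion_noise_sd = companion_noise_sd,
              beta_bmi = beta_bmi, beta_age = beta_age,
              beta_persist = beta_persist,
              b0_sbp = b0_sbp, b0_dbp = b0_dbp,
              noise_sd_sbp = noise_sd_sbp, noise_sd_dbp = noise_sd_dbp,
              missing_rate = missing_rate,
              questionnaire_nonresponse = questionnaire_nonresponse,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  num <- unlist(cfg[c("visit_count_probs", "interval_years", "interval_probs",
                      "bmi_mean", "bmi_sd", "bmi_walk_sd",
                      "companion_slopes", "companion_intercepts",
                      "companion_noise_sd", "beta_bmi", "beta_age",
                      "beta_persist", "b0_sbp", "b0_dbp",
                      "noise_sd_sbp", "noise_sd_dbp", "missing_rate",
                      "questionnaire_nonresponse")])
  if (any(!is.finite(num)))
    stop("cohort_config: all numeric parameters must be finite")
  if (cfg$n_visitors < 1) stop("cohort_config: n_visitors must be >= 1")
  if (abs(sum(cfg$visit_count_probs) - 1) > 1e-8)
    stop("cohort_config: visit_count_probs must sum to 1")
  if (abs(sum(cfg$interval_probs) - 1) > 1e-8)
    stop("cohort_config: interval_probs must sum to 1")
  if (length(cfg$interval_years) != length(cfg$interval_probs))
    stop("cohort_config: interval_years and interval_probs lengths differ")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("cohort_config: missing_rate must be in [0, 1)")
  sds <- c(cfg$bmi_sd, cfg$bmi_walk_sd, cfg$companion_noise_sd,
           cfg$noise_sd_sbp, cfg$noise_sd_dbp)
  if (any(sds < 0)) stop("cohort_config: standard deviations must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic longitudinal checkup cohort
#'
#' Simulates a long-format visit table (one row per visitor-visit) with the
#' structure the downstream pipeline assumes: strictly increasing visit
#' dates per visitor, a BMI random walk, companion anthropometric factors
#' linear in BMI with sex-specific slopes, autoregressive blood pressure
#' with positive BMI and age effects, a block of BMI-independent laboratory
#' and physiological measurements, categorical questionnaire items with
#' non-response, and MCAR missingness in exam cells (blood pressure is
#' never missing). Weight and height are mutually consistent with BMI.
#'
#' @param config a [cohort_config()].
#' @return a data.frame, one row per visit, ordered by visitor then date,
#'   with attribute `"ground_truth"` holding the realized generative
#'   coefficients (see [cohort_ground_truth()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  nv <- config$n_visitors

  n_visits <- sample.int(length(config$visit_count_probs), nv,
                         replace = TRUE, prob = config$visit_count_probs)
  sex0   <- ifelse(stats::runif(nv) < 0.5, "male", "female")
  age0   <- pmin(pmax(stats::rnorm(nv, 42, 12), 20), 80)
  height0 <- ifelse(sex0 == "male",
                    stats::rnorm(nv, 1.70, 0.06),
                    stats::rnorm(nv, 1.58, 0.055))
  bmi0   <- stats::rnorm(nv, config$bmi_mean, config$bmi_sd)
  bmi0   <- pmax(bmi0, 15)
  date0  <- as.Date("2010-01-01") + floor(stats::runif(nv, 0, 730))

  vid <- sprintf("V%05d", seq_len(nv))
  row_visitor <- rep.int(seq_len(nv), n_visits)
  visit_idx <- sequence(n_visits)
  n <- length(row_visitor)

  # inter-visit gaps in days, with day-level jitter around the sampled years
  gap_years <- sample(config$interval_years, n, replace = TRUE,
                      prob = config$interval_probs)
  gap_days <- round(gap_years * 365.25 + stats::runif(n, -18, 18))
  gap_days[visit_idx == 1] <- 0
  offset_days <- stats::ave(gap_days, row_visitor, FUN = cumsum)
  date <- date0[row_visitor] + offset_days
  age <- age0[row_visitor] + offset_days / 365.25

  # BMI random walk per visitor
  step <- stats::rnorm(n, 0, config$bmi_walk_sd)
  step[visit_idx == 1] <- 0
  bmi <- bmi0[row_visitor] + stats::ave(step, row_visitor, FUN = cumsum)
  bmi <- pmax(bmi, 14)

  sex <- sex0[row_visitor]
  height <- height0[row_visitor]
  weight <- bmi * height^2

  male <- sex == "male"
  companion <- lapply(names(config$companion_slopes), function(f) {
    sl <- config$companion_slopes[[f]]
    ic <- config$companion_intercepts[[f]]
    ns <- config$companion_noise_sd[[f]]
    ifelse(male, ic[["male"]] + sl[["male"]] * bmi,
                 ic[["female"]] + sl[["female"]] * bmi) +
      stats::rnorm(n, 0, ns)
  })
  names(companion) <- names(config$companion_slopes)

  # blood pressure: AR(1) in prior BP plus linear age and BMI terms;
  # first visit drawn from the implied stationary distribution
  rho <- config$beta_persist
  statsd <- function(s) if (rho < 1) s / sqrt(1 - rho^2) else s
  mu_sbp <- (config$b0_sbp + config$beta_age * age + config$beta_bmi * bmi)
  mu_dbp <- (config$b0_dbp + config$beta_age * age + config$beta_bmi * bmi)
  sbp <- dbp <- numeric(n)
  first <- visit_idx == 1
  sbp[first] <- mu_sbp[first] / max(1 - rho, 1e-9) +
    stats::rnorm(sum(first), 0, statsd(config$noise_sd_sbp))
  dbp[first] <- mu_dbp[first] / max(1 - rho, 1e-9) +
    stats::rnorm(sum(first), 0, statsd(config$noise_sd_dbp))
  if (max(visit_idx) > 1) {
    prev_row <- seq_len(n) - 1L
    for (t in 2:max(visit_idx)) {
      i <- which(visit_idx == t)
      sbp[i] <- mu_sbp[i] + rho * sbp[prev_row[i]] +
        stats::rnorm(length(i), 0, config$noise_sd_sbp)
      dbp[i] <- mu_dbp[i] + rho * dbp[prev_row[i]] +
        stats::rnorm(length(i), 0, config$noise_sd_dbp)
    }
  }
  sbp <- pmax(sbp, 70)
  dbp <- pmax(dbp, 40)

  # BMI-independent exam block (age effects only, so none of these qualify
  # as BMI companions)
  egfr <- stats::rnorm(n, 95, 15) - 0.3 * (age - 40)
  hematocrit <- ifelse(male, stats::rnorm(n, 43, 4), stats::rnorm(n, 40, 4))
  fev1 <- pmax(stats::rnorm(n, 3.2, 0.6) - 0.02 * (age - 40), 0.5)
  fvc <- pmax(stats::rnorm(n, 4.0, 0.7) - 0.02 * (age - 40), 0.8)
  mmef <- pmax(stats::rnorm(n, 3.5, 0.9), 0.3)
  lymphocytes <- pmin(pmax(stats::rnorm(n, 33, 7), 5), 70)
  eosinophil <- pmax(stats::rnorm(n, 2.5, 1.5), 0)
  albumin <- stats::rnorm(n, 4.5, 0.25)
  globulin <- pmax(stats::rnorm(n, 2.9, 0.3), 1.5)
  hearing_right <- pmax(stats::rnorm(n, 15, 8) + 0.25 * (age - 40), 0)
  liver_abnormal <- as.numeric(
    stats::runif(n) < stats::plogis(-2.5 + 0.15 * (bmi - 24)))
  cholesterol <- stats::rnorm(n, 195, 35) + 0.3 * (age - 40)
  hdl <- ifelse(male, stats::rnorm(n, 48, 11), stats::rnorm(n, 55, 13))
  glucose <- stats::rnorm(n, 97, 18) + 0.2 * (age - 40)

  # questionnaire: categorical with non-response
  smoke <- ifelse(stats::runif(n) < ifelse(male, 0.25, 0.05), "Yes", "No")
  alcohol <- ifelse(stats::runif(n) < ifelse(male, 0.30, 0.10), "Yes", "No")
  exercise_freq <- sample(c("None", "Sometimes", "Regular"), n,
                          replace = TRUE, prob = c(0.45, 0.35, 0.20))
  nr <- config$questionnaire_nonresponse
  if (nr > 0) {
    smoke[stats::runif(n) < nr] <- NA
    alcohol[stats::runif(n) < nr] <- NA
    exercise_freq[stats::runif(n) < nr] <- NA
  }

  cohort <- data.frame(
    visitor_id = vid[row_visitor], visit_idx = visit_idx,
    date = date, sex = sex, age = age,
    sbp = sbp, dbp = dbp,
    weight = weight, height = height,
    waist = companion$waist, hip = companion$hip,
    body_fat = companion$body_fat,
    albumin = albumin, globulin = globulin,
    egfr = egfr, hematocrit = hematocrit,
    fev1 = fev1, fvc = fvc, mmef = mmef,
    lymphocytes = lymphocytes, eosinophil = eosinophil,
    hearing_right = hearing_right, liver_abnormal = liver_abnormal,
    cholesterol = cholesterol, hdl = hdl, glucose = glucose,
    smoke = smoke, alcohol = alcohol, exercise_freq = exercise_freq,
    stringsAsFactors = FALSE)

  # MCAR missingness in exam cells; BP, demographics and dates never masked
  if (config$missing_rate > 0) {
    for (col in setdiff(exam_columns(), c("sbp", "dbp"))) {
      mask <- stats::runif(n) < config$missing_rate
      cohort[[col]][mask] <- NA
    }
  }

  attr(cohort, "ground_truth") <- list(
    companion_slopes = config$companion_slopes,
    companion_intercepts = config$companion_intercepts,
    beta_bmi = config$beta_bmi, beta_age = config$beta_age,
    beta_persist = config$beta_persist,
    b0_sbp = config$b0_sbp, b0_dbp = config$b0_dbp,
    noise_sd_sbp = config$noise_sd_sbp, noise_sd_dbp = config$noise_sd_dbp,
    seed = config$seed)
  cohort
}

# physical-exam columns of the visit table (candidates for MCAR masking)
exam_columns <- function() {
  c("sbp", "dbp", "weight", "height", "waist", "hip", "body_fat",
    "albumin", "globulin", "egfr", "hematocrit", "fev1", "fvc", "mmef",
    "lymphocytes", "eosinophil", "hearing_right", "liver_abnormal",
    "cholesterol", "hdl", "glucose")
}

questionnaire_columns <- function() c("smoke", "alcohol", "exercise_freq")

#' Realized generative parameters of a synthetic cohort
#'
#' @param cohort a data.frame from [generate_cohort()].
#' @return the list of generative coefficients and companion slopes used.
#' @export
cohort_ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) stop("cohort carries no ground-truth attribute")
  gt
}

#' Fraction of visits meeting the hypertension label rule
#'
#' A visit is positive when SBP >= 130 mmHg or DBP >= 80 mmHg (both
#' thresholds inclusive).
#'
#' @param cohort a visit table with `sbp` and `dbp` columns.
#' @return fraction of positive visits.
#' @export
positive_prevalence <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  mean(label_visit(cohort$sbp, cohort$dbp))
}

#' Write a cohort to disk as CSV plus a ground-truth JSON
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "visits.csv")
  json <- file.path(dir, "ground_truth.json")
  utils::write.csv(cohort, csv, row.names = FALSE, na = "")
  jsonlite::write_json(cohort_ground_truth(cohort), json,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(visits = csv, ground_truth = json))
}

#' Read a cohort visit table written by [write_cohort()]
#'
#' @param path path to the visits CSV.
#' @return a visit data.frame with typed columns (dates parsed, empty cells
#'   as NA).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  df$date <- as.Date(df$date)
  df
}
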