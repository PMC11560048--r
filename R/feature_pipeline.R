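#' Hypertension label rule
#'
#' A visit is positive when systolic blood pressure is at least 130 mmHg or
#' diastolic blood pressure is at least 80 mmHg; both thresholds inclusive.
#'
#' @param sbp,dbp blood pressures in mmHg (vectors).
#' @return logical vector.
#' @export
label_visit <- function(sbp, dbp) {
  if (any(is.na(sbp)) || any(is.na(dbp)))
    stop("label_visit: blood pressure must be present")
  sbp >= 130 | dbp >= 80
}

#' Reference per-visit feature schema
#'
#' Defines the ordered per-visit feature vector: demographic and
#' physical-exam factors, derived factors (mean arterial pressure,
#' current-visit hypertension flag, pulse pressure, BMI, waist-hip ratio,
#' albumin-globulin ratio) and integer-coded questionnaire items with a
#' default response each. The per-visit dimension `d` is the number of
#' schema rows; it is schema-driven, not hard-coded.
#'
#' @param factors optional character vector restricting the schema to a
#'   subset of factor names (parents needed by derived factors must be
#'   included by the caller; unknown names are an error).
#' @return a data.frame of class `feature_schema` with columns `name`,
#'   `kind` ("exam", "derived", "questionnaire"), `source` (visit-table
#'   column, NA for derived), and `default` (questionnaire default
#'   response, NA otherwise), plus attributes `levels` (named list of
#'   category level vectors) and `d`.
#' @export
feature_schema <- function(factors = NULL) {
  sc <- data.frame(
    name = c("sbp", "dbp", "age", "sex_male",
             "weight", "height", "waist", "hip", "body_fat",
             "albumin", "globulin", "egfr", "hematocrit",
             "fev1", "fvc", "mmef", "lymphocytes", "eosinophil",
             "hearing_right", "liver_abnormal", "cholesterol", "hdl",
             "glucose",
             "map", "has_htn", "pulse_pressure", "bmi", "whr", "agr",
             "smoke", "alcohol", "exercise_freq"),
    kind = c(rep("exam", 23), rep("derived", 6), rep("questionnaire", 3)),
    source = c("sbp", "dbp", "age", "sex",
               "weight", "height", "waist", "hip", "body_fat",
               "albumin", "globulin", "egfr", "hematocrit",
               "fev1", "fvc", "mmef", "lymphocytes", "eosinophil",
               "hearing_right", "liver_abnormal", "cholesterol", "hdl",
               "glucose",
               NA, NA, NA, NA, NA, NA,
               "smoke", "alcohol", "exercise_freq"),
    default = c(rep(NA, 29), "No", "No", "None"),
    stringsAsFactors = FALSE)
  lv <- list(smoke = c("No", "Yes"), alcohol = c("No", "Yes"),
             exercise_freq = c("None", "Sometimes", "Regular"))
  if (!is.null(factors)) {
    unknown <- setdiff(factors, sc$name)
    if (length(unknown) > 0)
      stop("feature_schema: unknown factors: ",
           paste(unknown, collapse = ", "))
    sc <- sc[sc$name %in% factors, , drop = FALSE]
    rownames(sc) <- NULL
    lv <- lv[intersect(names(lv), sc$name)]
  }
  if (anyDuplicated(sc$name)) stop("feature_schema: duplicate factor names")
  attr(sc, "levels") <- lv
  attr(sc, "d") <- nrow(sc)
  class(sc) <- c("feature_schema", "data.frame")
  sc
}

#' Schema restricted to the Framingham risk-score factors
#'
#' Age, sex, total cholesterol, HDL cholesterol, smoking habit, systolic
#' blood pressure and glucose; the identical pipeline is rerun on this
#' reduced per-visit vector for the comparison experiment.
#'
#' @return a `feature_schema`.
#' @export
framingham_schema <- function() {
  feature_schema(c("age", "sex_male", "cholesterol", "hdl", "smoke",
                   "sbp", "glucose"))
}

#' Fill unanswered questionnaire items with their default responses
#'
#' @param visits visit table rows.
#' @param schema a [feature_schema()].
#' @return `visits` with every questionnaire column non-missing.
#' @export
apply_questionnaire_defaults <- function(visits, schema) {
  q <- schema[schema$kind == "questionnaire", , drop = FALSE]
  for (i in seq_len(nrow(q))) {
    if (is.na(q$default[i]))
      stop("apply_questionnaire_defaults: no default configured for ",
           q$name[i])
    col <- q$source[i]
    if (!col %in% names(visits)) next
    miss <- is.na(visits[[col]])
    visits[[col]][miss] <- q$default[i]
  }
  visits
}

#' Linear-interpolation imputation of one factor over a visitor's visits
#'
#' Interior missing values are replaced by linear interpolation over visit
#' date between the nearest non-missing neighbours; leading and trailing
#' missing values take the nearest observed value; a series with no
#' observed value stays entirely missing. Observed values are never
#' altered.
#'
#' @param values numeric values of the factor, one per visit.
#' @param dates visit dates (Date or numeric), same length, increasing.
#' @return the imputed numeric vector.
#' @export
impute_series <- function(values, dates) {
  obs <- which(!is.na(values))
  if (length(obs) == 0 || length(obs) == length(values)) return(values)
  if (length(obs) == 1) {
    values[] <- values[obs]
    return(values)
  }
  x <- as.numeric(dates)
  stats::approx(x[obs], values[obs], xout = x, rule = 2)$y
}

#' Impute exam values and default questionnaire responses for a visit table
#'
#' Runs [impute_series()] per visitor and per exam factor (over the
#' visitor's full pruned visit sequence, date-ordered) and
#' [apply_questionnaire_defaults()] for questionnaire items. Blood
#' pressures are required present upstream and are not touched.
#'
#' @param visits a pruned visit table (e.g. `assemble_dataset()$visits`).
#' @param schema a [feature_schema()].
#' @return the visit table with exam NAs interpolated where possible.
#' @export
impute_visits <- function(visits, schema) {
  exam_cols <- intersect(
    unique(schema$source[schema$kind == "exam"]),
    names(visits))
  exam_cols <- setdiff(exam_cols, c("sbp", "dbp", "sex", "age"))
  vidx <- split(seq_len(nrow(visits)), factor(visits$visitor_id,
                levels = unique(visits$visitor_id)))
  for (col in exam_cols) {
    v <- visits[[col]]
    if (!anyNA(v)) next
    for (rows in vidx) {
      if (!anyNA(v[rows])) next
      v[rows] <- impute_series(v[rows], visits$date[rows])
    }
    visits[[col]] <- v
  }
  apply_questionnaire_defaults(visits, schema)
}

#' Derive the per-visit feature matrix
#'
#' Maps visit-table rows to the schema's ordered numeric feature vector:
#' exam factors are taken as-is (sex encoded as an indicator for male),
#' questionnaire responses are integer-coded by their category levels
#' (first level = 0), and derived factors are computed from their parents:
#' mean arterial pressure SBP/3 + 2 DBP/3, the current-visit hypertension
#' flag, pulse pressure SBP - DBP, BMI weight/height^2, waist-hip ratio and
#' albumin-globulin ratio. Missing inputs propagate to missing outputs.
#'
#' @param visits visit-table rows.
#' @param schema a [feature_schema()].
#' @return numeric matrix, one row per visit, `d` columns named by factor.
#' @export
derive_visit_features <- function(visits, schema) {
  n <- nrow(visits)
  lv <- attr(schema, "levels")
  out <- matrix(NA_real_, n, nrow(schema),
                dimnames = list(NULL, schema$name))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    if (kind == "exam") {
      src <- schema$source[i]
      out[, i] <- if (nm == "sex_male") as.numeric(visits$sex == "male")
                  else visits[[src]]
    } else if (kind == "questionnaire") {
      src <- schema$source[i]
      codes <- match(visits[[src]], lv[[nm]]) - 1
      if (any(is.na(codes) & !is.na(visits[[src]])))
        stop("derive_visit_features: response outside configured levels ",
             "for ", nm)
      out[, i] <- codes
    } else if (kind == "derived") {
      out[, i] <- switch(nm,
        map = visits$sbp / 3 + 2 * visits$dbp / 3,
        has_htn = as.numeric(label_visit(visits$sbp, visits$dbp)),
        pulse_pressure = visits$sbp - visits$dbp,
        bmi = visits$weight / visits$height^2,
        whr = visits$waist / visits$hip,
        agr = visits$albumin / visits$globulin,
        stop("derive_visit_features: unknown derived factor ", nm))
    } else stop("derive_visit_features: unknown kind ", kind)
  }
  out
}

#' Encode an input window of per-visit vectors
#'
#' Concatenates up to `n1` per-visit feature vectors in visiting order,
#' prepends all-zero blocks for the missing slots, and appends an `n1`-long
#' presence indicator (0 for a prepended slot, 1 for a real visit). The
#' output length is always `n1 * d + n1`.
#'
#' @param vectors a matrix with one row per input visit (oldest first) and
#'   `d` columns, or a list of equal-length numeric vectors.
#' @param n1 number of visit slots.
#' @return numeric vector of length `n1 * d + n1`.
#' @export
encode_window <- function(vectors, n1) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  k <- nrow(vectors)
  d <- ncol(vectors)
  if (k < 1 || k > n1)
    stop("encode_window: number of input visits must be in 1..n1")
  c(rep(0, (n1 - k) * d), as.numeric(t(vectors)),
    rep(c(0, 1), c(n1 - k, k)))
}

#' Column names of the encoded window vector
#'
#' Slot `n1` holds the most recent input visit; prepended (padded) slots
#' are the lowest-numbered ones.
#'
#' @param schema a [feature_schema()].
#' @param n1 number of visit slots.
#' @return character vector of length `n1 * d + n1`.
#' @export
window_colnames <- function(schema, n1) {
  c(as.vector(vapply(seq_len(n1), function(s)
      paste0("v", s, ".", schema$name), character(nrow(schema)))),
    paste0("present.v", seq_len(n1)))
}

#' Encode every sample of a dataset into the window feature matrix
#'
#' @param dataset an `nv_dataset` from [assemble_dataset()] whose `visits`
#'   have been through [impute_visits()].
#' @param schema a [feature_schema()].
#' @param n1 number of visit slots.
#' @param split optionally restrict to "train" or "test" samples.
#' @return list with `x` (matrix, one row per sample, named columns),
#'   `y` (integer labels of the output visits) and `samples` (the matching
#'   sample rows).
#' @export
encode_dataset <- function(dataset, schema, n1 = 5, split = NULL) {
  s <- dataset$samples
  if (!is.null(split)) s <- s[s$split == split, , drop = FALSE]
  feat <- derive_visit_features(dataset$visits, schema)
  d <- ncol(feat)
  x <- matrix(0, nrow(s), n1 * d + n1,
              dimnames = list(NULL, window_colnames(schema, n1)))
  for (i in seq_len(nrow(s)))
    x[i, ] <- encode_window(feat[s$input_rows[[i]], , drop = FALSE], n1)
  list(x = x, y = as.integer(s$label), samples = s)
}
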