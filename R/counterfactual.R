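#' Fit BMI companion-factor models on the training visits
#'
#' For each candidate numeric exam factor, computes the Pearson
#' correlation with BMI pooled over all training input visits. Factors
#' with correlation strictly greater than 0.7 become companion factors and
#' get per-sex least-squares slope and intercept of the factor regressed
#' on BMI. Body weight is always modified proportionally with BMI (it is
#' BMI times squared height), so it is not listed here; derived factors
#' with companion parents (the waist-hip ratio) are recomputed from their
#' modified parents rather than projected.
#'
#' @param visits training visit rows (imputed), with `weight`, `height`,
#'   `sex` columns.
#' @param candidates candidate factor names; defaults to the numeric exam
#'   factors other than weight, height and the blood pressures.
#' @param r_threshold companion cutoff on the correlation (strict
#'   inequality).
#' @return a data.frame of class `companion_models` with one row per
#'   candidate: `factor`, `r`, `companion` (logical), and for companions
#'   the per-sex `slope_male`, `intercept_male`, `slope_female`,
#'   `intercept_female`.
#' @export
fit_bmi_companions <- function(visits,
                               candidates = c("waist", "hip", "body_fat",
                                              "albumin", "globulin", "egfr",
                                              "hematocrit", "fev1", "fvc",
                                              "mmef", "lymphocytes",
                                              "eosinophil", "hearing_right",
                                              "cholesterol", "hdl",
                                              "glucose"),
                               r_threshold = 0.7) {
  if (!all(c("weight", "height") %in% names(visits)))
    stop("fit_bmi_companions: visits must carry weight and height (BMI parents)")
  bmi <- visits$weight / visits$height^2
  candidates <- intersect(candidates, names(visits))
  rows <- lapply(candidates, function(f) {
    y <- visits[[f]]
    ok <- !is.na(bmi) & !is.na(y)
    r <- if (sum(ok) > 2) stats::cor(bmi[ok], y[ok]) else NA_real_
    row <- data.frame(factor = f, r = r, companion = !is.na(r) & r > r_threshold,
                      slope_male = NA_real_, intercept_male = NA_real_,
                      slope_female = NA_real_, intercept_female = NA_real_,
                      stringsAsFactors = FALSE)
    if (row$companion) {
      for (sx in c("male", "female")) {
        i <- ok & visits$sex == sx
        fit <- stats::lm.fit(cbind(1, bmi[i]), y[i])
        row[[paste0("slope_", sx)]] <- fit$coefficients[2]
        row[[paste0("intercept_", sx)]] <- fit$coefficients[1]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("companion_models", "data.frame")
  out
}

#' Project a companion factor under a BMI change
#'
#' Evaluates the linear projection `y_new = s * (bmi_new - bmi_ori) +
#' y_ori`, with `s` the sex-specific best-fit slope of the factor on BMI.
#'
#' @param s slope of the factor on BMI for the visit's sex.
#' @param bmi_ori,bmi_new original and modified BMI.
#' @param y_ori original factor value.
#' @return the projected factor value.
#' @export
project_factor <- function(s, bmi_ori, bmi_new, y_ori) {
  s * (bmi_new - bmi_ori) + y_ori
}

companion_slope <- function(companions, factor, sex) {
  i <- match(factor, companions$factor)
  companions[[paste0("slope_", sex)]][i]
}

#' Intervention scenario for virtual visits
#'
#' @param target_bmi BMI the last visit is reduced to (applies only when
#'   the last-visit BMI exceeds it).
#' @param k number of virtual visits appended.
#' @param gap_years gap between consecutive virtual visits.
#' @param advance_age whether age advances with the virtual-visit dates.
#'   Default FALSE: holding age fixed isolates the weight-control effect
#'   from the independent age-related risk increase (age is itself a risk
#'   factor, and advancing it by up to five years confounds the
#'   counterfactual contrast).
#' @param sham when TRUE, virtual visits are appended as unmodified copies
#'   of the last visit (no BMI, weight or companion change). This is the
#'   structural control: any reclassification under a sham scenario is
#'   threshold noise from the window restructuring itself, not a
#'   weight-control effect.
#' @return a list of class `scenario`.
#' @export
scenario <- function(target_bmi = 24, k = 1, gap_years = 1,
                     advance_age = FALSE, sham = FALSE) {
  if (target_bmi <= 0 || k < 1)
    stop("scenario: require target_bmi > 0 and k >= 1")
  structure(list(target_bmi = target_bmi, k = as.integer(k),
                 gap_years = gap_years, advance_age = advance_age,
                 sham = sham),
            class = "scenario")
}

#' Append weight-control virtual visits to a sample's input window
#'
#' Copies the last real input visit `k` times, each dated one gap later
#' than its predecessor, with BMI set to the scenario target, body weight
#' rescaled by the same ratio, companion factors projected along their
#' sex-specific slopes, and everything else carried over (derived factors
#' such as the waist-hip ratio are recomputed downstream from the modified
#' parents). The window is then trimmed from the front so at most `n1`
#' visits remain. The output visit and its label are never touched.
#'
#' @param input_visits the sample's input visit rows (imputed),
#'   date-ordered.
#' @param scn a [scenario()].
#' @param companions a `companion_models` fit (training set only).
#' @param n1 window capacity.
#' @return a list: `visits` (the modified input window) and `eligible`
#'   (FALSE when the last-visit BMI is at or below the target, in which
#'   case `visits` is the unchanged input).
#' @export
build_virtual_sample <- function(input_visits, scn, companions, n1 = 5) {
  if (scn$k > n1)
    stop("build_virtual_sample: k must not exceed the window capacity n1")
  last <- input_visits[nrow(input_visits), , drop = FALSE]
  bmi_ori <- last$weight / last$height^2
  if (is.na(bmi_ori) || bmi_ori <= scn$target_bmi)
    return(list(visits = input_visits, eligible = FALSE))
  ratio <- scn$target_bmi / bmi_ori

  virt <- last[rep(1L, scn$k), , drop = FALSE]
  step <- seq_len(scn$k)
  virt$date <- last$date + round(scn$gap_years * 365.25 * step)
  if (!is.null(virt$age) && scn$advance_age)
    virt$age <- last$age + scn$gap_years * step
  if (!scn$sham) {
    virt$weight <- last$weight * ratio
    comp <- companions[companions$companion, , drop = FALSE]
    for (f in comp$factor) {
      if (!f %in% names(virt)) next
      s <- companion_slope(companions, f, last$sex)
      virt[[f]] <- project_factor(s, bmi_ori, scn$target_bmi, last[[f]])
    }
  }
  out <- rbind(input_visits, virt)
  out <- out[seq.int(max(1L, nrow(out) - n1 + 1L), nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  list(visits = out, eligible = TRUE)
}

#' Reclassification under virtual-visit weight control
#'
#' Restricts the test set to samples the ensemble predicts positive whose
#' last input visit has BMI at or above the scenario target, separately
#' tallying true-positive and false-positive groups. For each number of
#' virtual visits k, rebuilds the eligible inputs via
#' [build_virtual_sample()], re-encodes and re-predicts, and reports the
#' count and fraction flipped to negative, plus the Matthews correlation
#' between the original and counterfactual predictions over the whole
#' test set.
#'
#' @param ensemble a fitted `nv_ensemble`.
#' @param dataset an `nv_dataset` whose visits have been through
#'   [impute_visits()].
#' @param schema the `feature_schema` the ensemble was trained on.
#' @param companions a `companion_models` fit from the training visits.
#' @param ks numbers of virtual visits to evaluate.
#' @param target_bmi intervention target BMI.
#' @param n1 window capacity.
#' @param advance_age,sham forwarded to [scenario()]; `sham = TRUE` runs
#'   the structural control (unmodified copies appended).
#' @return a list of class `reclassification_report`: `eligible`
#'   (counts: total predicted positive, eligible TP, eligible FP),
#'   `per_k` (data.frame: k, flipped counts and fractions for TP/FP/all),
#'   `mcc` (per k, before vs after over the full test set),
#'   `base_prediction` (the original test predictions).
#' @export
reclassification <- function(ensemble, dataset, schema, companions,
                             ks = 1:5, target_bmi = 24, n1 = 5,
                             advance_age = FALSE, sham = FALSE) {
  enc <- encode_dataset(dataset, schema, n1, split = "test")
  s <- enc$samples
  base <- predict_ensemble(ensemble, enc$x)
  pos <- base$final
  v <- dataset$visits
  last_row <- vapply(s$input_rows, function(r) r[length(r)], 1L)
  last_bmi <- v$weight[last_row] / v$height[last_row]^2
  elig <- pos & !is.na(last_bmi) & last_bmi >= target_bmi
  groups <- list(tp = elig & s$label, fp = elig & !s$label)

  if (!any(elig)) {
    return(structure(list(
      eligible = c(predicted_positive = sum(pos), tp = 0, fp = 0),
      per_k = data.frame(), mcc = numeric(0),
      note = "no eligible samples", base_prediction = base),
      class = "reclassification_report"))
  }

  idx <- which(elig)
  per_k <- list()
  mccs <- numeric(0)
  for (k in ks) {
    scn <- scenario(target_bmi = target_bmi, k = k,
                    advance_age = advance_age, sham = sham)
    xk <- matrix(0, length(idx), ncol(enc$x))
    for (j in seq_along(idx)) {
      i <- idx[j]
      vs <- build_virtual_sample(v[s$input_rows[[i]], , drop = FALSE],
                                 scn, companions, n1)$visits
      xk[j, ] <- encode_window(derive_visit_features(vs, schema), n1)
    }
    colnames(xk) <- colnames(enc$x)
    newpred <- predict_ensemble(ensemble, xk)$final
    after <- base$final
    after[idx] <- newpred
    flip <- base$final[idx] & !newpred
    flip_tp <- sum(flip & s$label[idx])
    flip_fp <- sum(flip & !s$label[idx])
    per_k[[length(per_k) + 1L]] <- data.frame(
      k = k,
      flipped_tp = flip_tp, flipped_fp = flip_fp,
      flipped = flip_tp + flip_fp,
      frac_tp = if (sum(groups$tp) > 0) flip_tp / sum(groups$tp) else NA_real_,
      frac_fp = if (sum(groups$fp) > 0) flip_fp / sum(groups$fp) else NA_real_,
      frac = (flip_tp + flip_fp) / length(idx))
    mccs <- c(mccs, mcc(base$final, after))
  }
  structure(list(
    eligible = c(predicted_positive = sum(pos),
                 tp = sum(groups$tp), fp = sum(groups$fp)),
    per_k = do.call(rbind, per_k),
    mcc = stats::setNames(mccs, paste0("k", ks)),
    base_prediction = base),
    class = "reclassification_report")
}
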