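#' Windowing configuration
#'
#' @param n1 maximum number of input visits per sample.
#' @param n2 maximum number of training input-output pairs per visitor.
#' @param max_gap_years pruning horizon: a visit whose gap to its prior
#'   visit exceeds this many years invalidates all prior visits.
#' @return a list of class `window_config`.
#' @export
window_config <- function(n1 = 5, n2 = 4, max_gap_years = 3) {
  if (n1 < 1 || n2 < 1 || max_gap_years <= 0)
    stop("window_config: require n1 >= 1, n2 >= 1, max_gap_years > 0")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 max_gap_years = max_gap_years),
            class = "window_config")
}

#' Drop visits before an oversized inter-visit gap
#'
#' Keeps the maximal suffix of a visitor's date-ordered visit sequence in
#' which every consecutive gap is at most `max_gap_years` (evaluated on
#' exact date arithmetic as gap > max_gap_years * 365.25 days). Equivalent
#' to discarding everything before the last oversized gap. Idempotent.
#'
#' @param record one visitor's visits, date-ordered (data.frame with a
#'   `date` column).
#' @param max_gap_years pruning horizon in years.
#' @return the surviving suffix of `record` (possibly empty).
#' @export
prune_gap_history <- function(record, max_gap_years = 3) {
  m <- nrow(record)
  if (m <= 1) return(record)
  d <- as.numeric(record$date)
  if (any(diff(d) <= 0))
    stop("prune_gap_history: visit dates must be strictly increasing")
  gaps <- diff(d)
  big <- which(gaps > max_gap_years * 365.25)
  if (length(big) == 0) return(record)
  record[(max(big) + 1L):m, , drop = FALSE]
}

#' Build training pairs and the test sample for one visitor
#'
#' With M gap-pruned visits: training pairs take each visit at position
#' j in 2..(M-1) as output with up to `n1` immediately preceding visits as
#' input, keeping only the last `min(M-2, n2)` pairs; the test sample takes
#' visit M as output with up to `n1` preceding visits as input. A visitor
#' with M = 2 contributes a test sample only; with M <= 1, nothing.
#'
#' @param record one visitor's pruned, date-ordered visits.
#' @param cfg a [window_config()].
#' @return list with `train` (list of samples) and `test` (a sample or
#'   NULL). Each sample is a list with `visitor_id`, `input` (local visit
#'   positions) and `output` (local position).
#' @export
build_samples <- function(record, cfg = window_config()) {
  m <- nrow(record)
  if (m <= 1) return(list(train = list(), test = NULL))
  vid <- record$visitor_id[1]
  mk <- function(j) list(visitor_id = vid,
                         input = max(1L, j - cfg$n1):(j - 1L),
                         output = j)
  test <- mk(m)
  if (m == 2) return(list(train = list(), test = test))
  outs <- 2:(m - 1L)
  keep <- utils::tail(outs, cfg$n2)
  list(train = lapply(keep, mk), test = test)
}

#' Assemble pooled train/test samples from a cohort visit table
#'
#' Applies [prune_gap_history()] then [build_samples()] to every visitor in
#' a long-format visit table and pools the results, along with a tally of
#' sample counts by number of input visits (the shape used to audit the
#' window construction).
#'
#' @param cohort long-format visit table (one row per visitor-visit) with
#'   at least `visitor_id`, `date`, `sbp`, `dbp` columns; rows for one
#'   visitor must be contiguous blocks (the generator and CSV reader
#'   guarantee this).
#' @param cfg a [window_config()].
#' @return a list of class `nv_dataset` with elements:
#'   \describe{
#'     \item{visits}{the pruned visit table (only surviving visits), with a
#'       `visit_row` key column.}
#'     \item{samples}{one row per sample: `visitor_id`, `split`
#'       ("train"/"test"), `n_input`, `output_row`, list-column
#'       `input_rows` (row keys into `visits`), output-visit `out_sbp`,
#'       `out_dbp`, `label`, plus `last_sbp`, `last_dbp` of the final input
#'       visit and `past_positive` (any input visit meets the label rule).}
#'     \item{tally}{table of sample counts by `n_input` and split.}
#'   }
#' @export
assemble_dataset <- function(cohort, cfg = window_config()) {
  if (nrow(cohort) == 0) {
    return(structure(list(visits = cohort,
                          samples = empty_samples_df(),
                          tally = table(n_input = integer(),
                                        split = character())),
                     class = "nv_dataset"))
  }
  ids <- cohort$visitor_id
  blocks <- rle(ids)$values
  if (anyDuplicated(blocks))
    stop("assemble_dataset: visitor ids appear in non-contiguous blocks ",
         "(duplicate records for the same visitor?)")
  idx_by_visitor <- split(seq_len(nrow(cohort)),
                          factor(ids, levels = blocks))

  pruned_rows <- vector("list", length(blocks))
  samp <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    rows <- idx_by_visitor[[k]]
    rec <- cohort[rows, , drop = FALSE]
    rec <- prune_gap_history(rec, cfg$max_gap_years)
    pruned_rows[[k]] <- rows[seq.int(length(rows) - nrow(rec) + 1L,
                                     length.out = nrow(rec))]
    samp[[k]] <- build_samples(rec, cfg)
  }

  keep <- unlist(pruned_rows, use.names = FALSE)
  visits <- cohort[keep, , drop = FALSE]
  visits$visit_row <- seq_len(nrow(visits))
  rownames(visits) <- NULL
  # map local visit positions to rows of the pruned table
  offset <- cumsum(c(0L, vapply(pruned_rows, length, 1L)))

  out <- list()
  for (k in seq_along(blocks)) {
    s <- samp[[k]]
    all_s <- c(s$train, if (!is.null(s$test)) list(s$test))
    if (length(all_s) == 0) next
    splits <- c(rep("train", length(s$train)),
                if (!is.null(s$test)) "test")
    for (i in seq_along(all_s)) {
      sm <- all_s[[i]]
      out[[length(out) + 1L]] <- list(
        visitor_id = sm$visitor_id, split = splits[i],
        input_rows = sm$input + offset[k], output_row = sm$output + offset[k])
    }
  }
  if (length(out) == 0) {
    samples <- empty_samples_df()
  } else {
    samples <- data.frame(
      visitor_id = vapply(out, `[[`, "", "visitor_id"),
      split = vapply(out, `[[`, "", "split"),
      n_input = vapply(out, function(s) length(s$input_rows), 1L),
      output_row = vapply(out, `[[`, 1L, "output_row"),
      stringsAsFactors = FALSE)
    samples$input_rows <- I(lapply(out, `[[`, "input_rows"))
    samples$out_sbp <- visits$sbp[samples$output_row]
    samples$out_dbp <- visits$dbp[samples$output_row]
    samples$label <- label_visit(samples$out_sbp, samples$out_dbp)
    last_row <- vapply(samples$input_rows, function(r) r[length(r)], 1L)
    samples$last_sbp <- visits$sbp[last_row]
    samples$last_dbp <- visits$dbp[last_row]
    samples$past_positive <- vapply(samples$input_rows, function(r) {
      any(label_visit(visits$sbp[r], visits$dbp[r]))
    }, TRUE)
  }
  tally <- table(n_input = factor(samples$n_input, levels = 1:cfg$n1),
                 split = factor(samples$split, levels = c("train", "test")))
  structure(list(visits = visits, samples = samples, tally = tally),
            class = "nv_dataset")
}

empty_samples_df <- function() {
  df <- data.frame(visitor_id = character(), split = character(),
                   n_input = integer(), output_row = integer(),
                   stringsAsFactors = FALSE)
  df$input_rows <- I(list())
  df$out_sbp <- df$out_dbp <- numeric()
  df$label <- df$past_positive <- logical()
  df$last_sbp <- df$last_dbp <- numeric()
  df
}

#' Write a sample manifest CSV for audit
#'
#' @param dataset an `nv_dataset` from [assemble_dataset()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_sample_manifest <- function(dataset, path) {
  v <- dataset$visits
  s <- dataset$samples
  man <- data.frame(
    visitor_id = s$visitor_id, split = s$split, n_input = s$n_input,
    input_dates = vapply(s$input_rows, function(r)
      paste(as.character(v$date[r]), collapse = ";"), ""),
    output_date = as.character(v$date[s$output_row]),
    label = as.integer(s$label),
    stringsAsFactors = FALSE)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
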