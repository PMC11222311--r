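# Glycemic variability indices from sparse (typically 4-hourly) 24-h series.
#
# All inputs are in mg/dL on the raw scale; rate/excursion indices that the
# clinical literature reports in mmol/L are converted internally.

# glucose molar mass 180.16 g/mol -> 18.016 mg/dL per mmol/L
MGDL_PER_MMOLL <- 18.016

#' Convert glucose from mg/dL to mmol/L
#'
#' Uses the molar mass of glucose (180.16 g/mol), i.e. 18.016 mg/dL per
#' mmol/L.
#'
#' @param value_mgdl Numeric vector of glucose values in mg/dL; must be
#'   non-negative.
#' @return Numeric vector in mmol/L.
#' @examples
#' mgdl_to_mmoll(180.16)  # 10
#' @export
mgdl_to_mmoll <- function(value_mgdl) {
  if (any(value_mgdl < 0, na.rm = TRUE)) {
    stop("glucose values must be non-negative (mg/dL)")
  }
  value_mgdl / MGDL_PER_MMOLL
}

#' Construct and validate a single-patient glucose series
#'
#' A glucose series is the set of readings charted for one patient during the
#' first 24 h of ICU stay. Rows are sorted by time defensively; after sorting
#' the times must be strictly increasing (no duplicated timestamps), all
#' values positive, and the time span at most 24 h.
#'
#' @param times Numeric vector, hours since ICU admission.
#' @param values_mgdl Numeric vector of glucose readings, mg/dL.
#' @param patient_id Optional identifier carried through for messages.
#' @return A `glucose_series` object (list with `times`, `values_mgdl`,
#'   `patient_id`).
#' @export
glucose_series <- function(times, values_mgdl, patient_id = NA) {
  if (length(times) != length(values_mgdl)) {
    stop("times and values_mgdl must have equal length")
  }
  keep <- !(is.na(times) | is.na(values_mgdl))
  times <- times[keep]
  values_mgdl <- values_mgdl[keep]
  if (length(times) < 2) {
    stop("glucose series needs at least 2 readings (patient ",
         patient_id, ")")
  }
  o <- order(times)
  times <- times[o]
  values_mgdl <- values_mgdl[o]
  if (any(diff(times) <= 0)) {
    stop("duplicated reading times for patient ", patient_id)
  }
  if (any(values_mgdl <= 0)) {
    stop("non-positive glucose value for patient ", patient_id)
  }
  if (max(times) - min(times) > 24) {
    stop("glucose series spans more than 24 h for patient ", patient_id)
  }
  structure(list(times = times, values_mgdl = values_mgdl,
                 patient_id = patient_id),
            class = "glucose_series")
}

as_series <- function(x) {
  if (inherits(x, "glucose_series")) x
  else glucose_series(x$times, x$values_mgdl, x$patient_id %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean blood glucose (MBG)
#'
#' Arithmetic mean of the readings, mg/dL.
#'
#' @param series A [glucose_series()].
#' @return MBG in mg/dL.
#' @export
compute_mbg <- function(series) {
  s <- as_series(series)
  mean(s$values_mgdl)
}

#' Mean absolute glucose change rate (MAG)
#'
#' Sum of absolute consecutive glucose differences divided by the total
#' elapsed time: `sum(|delta glucose|) / sum(delta t)`, with glucose in
#' mmol/L and time in hours.
#'
#' @param series A [glucose_series()].
#' @return MAG in mmol/L/h.
#' @export
compute_mag <- function(series) {
  s <- as_series(series)
  v <- mgdl_to_mmoll(s$values_mgdl)
  span <- max(s$times) - min(s$times)
  if (span <= 0) stop("zero total time span")
  sum(abs(diff(v))) / span
}

#' Glycemic lability index (GLI)
#'
#' Sum over consecutive reading pairs of the squared glucose difference
#' (mmol/L) divided by the elapsed hours between the two readings.
#'
#' @param series A [glucose_series()].
#' @return GLI in (mmol/L)^2 / h.
#' @export
compute_gli <- function(series) {
  s <- as_series(series)
  v <- mgdl_to_mmoll(s$values_mgdl)
  dh <- diff(s$times)
  if (any(dh <= 0)) stop("zero time gap between readings")
  sum(diff(v)^2 / dh)
}

#' Largest amplitude of glycemic excursion (LAGE)
#'
#' Maximum minus minimum reading, mg/dL.
#'
#' @param series A [glucose_series()].
#' @return LAGE in mg/dL.
#' @export
compute_lage <- function(series) {
  s <- as_series(series)
  max(s$values_mgdl) - min(s$values_mgdl)
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Mean of the absolute differences between adjacent local extrema of the
#' series that exceed one standard deviation of all readings. Conventions for
#' sparse series: values are converted to mmol/L first; the SD is the sample
#' (n-1) standard deviation of all readings; the first and last readings
#' count as extrema; an interior reading is an extremum iff both neighbours
#' lie strictly on the same side; runs of equal values (plateaus) are
#' collapsed to their first point; excursions must be strictly greater than
#' 1 SD to qualify; if none qualifies (including monotone and constant
#' series) MAGE is 0.
#'
#' @param series A [glucose_series()] with at least 3 readings.
#' @return MAGE in mmol/L.
#' @export
compute_mage <- function(series) {
  s <- as_series(series)
  if (length(s$values_mgdl) < 3) stop("insufficient readings for MAGE")
  v <- mgdl_to_mmoll(s$values_mgdl)
  sdev <- stats::sd(v)
  # collapse plateaus, keeping the first index of each run
  keep <- c(TRUE, diff(v) != 0)
  w <- v[keep]
  if (length(w) < 2) return(0)  # constant series
  d <- diff(w)
  # interior extrema: sign changes of consecutive differences; a monotone
  # series has no peak-valley pair, so MAGE is 0 by convention
  turn <- if (length(d) >= 2) which(d[-length(d)] * d[-1] < 0) + 1L
          else integer(0)
  if (length(turn) == 0) return(0)
  ext <- w[c(1L, turn, length(w))]
  exc <- abs(diff(ext))
  exc <- exc[exc > sdev]
  if (length(exc) == 0) 0 else mean(exc)
}

#' Compute all glycemic indices for one or many patients
#'
#' @param glucose Long-format data frame with columns `patient_id`, `time_h`,
#'   `glucose_mgdl`.
#' @return Data frame with one row per patient: `patient_id`, `n_obs`,
#'   `complete` (TRUE iff 6 readings), `baseline_mgdl` (first reading),
#'   `mbg_mgdl`, `mag_mmol_l_h`, `mage_mmol_l` (NA with fewer than 3
#'   readings), `gli_mmol2_h`, `lage_mgdl`.
#' @export
compute_indices <- function(glucose) {
  req <- c("patient_id", "time_h", "glucose_mgdl")
  if (!all(req %in% names(glucose))) {
    stop("glucose table needs columns ", paste(req, collapse = ", "))
  }
  ids <- unique(glucose$patient_id)
  parts <- split(glucose[c("time_h", "glucose_mgdl")],
                 factor(glucose$patient_id, levels = ids))
  rows <- lapply(seq_along(ids), function(i) {
    g <- parts[[i]]
    id <- ids[i]
    s <- glucose_series(g$time_h, g$glucose_mgdl, patient_id = id)
    n <- length(s$times)
    data.frame(
      patient_id = id,
      n_obs = n,
      complete = n >= 6,
      baseline_mgdl = s$values_mgdl[1],
      mbg_mgdl = compute_mbg(s),
      mag_mmol_l_h = compute_mag(s),
      mage_mmol_l = if (n >= 3) compute_mage(s) else NA_real_,
      gli_mmol2_h = compute_gli(s),
      lage_mgdl = compute_lage(s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default stratification cutpoints for the variability indices
#'
#' The dichotomization cutpoints used by the motivating cohort analysis:
#' MAG 0.77 mmol/L/h, MAGE 2.58 mmol/L, GLI 2.6 (mmol/L)^2/h, LAGE
#' 79.2 mg/dL (each index flagged high iff strictly greater), and the
#' hyperglycemia boundaries 140 and 200 mg/dL for baseline glucose and MBG.
#'
#' @return Named list of cutpoints.
#' @export
paper_thresholds <- function() {
  list(mag = 0.77, mage = 2.58, gli = 2.6, lage = 79.2,
       hyper_mild = 140, hyper_severe = 200)
}

hyper_stratum <- function(x, mild = 140, severe = 200) {
  cut(x, breaks = c(-Inf, mild, severe, Inf), right = FALSE,
      labels = c("no", "mild", "severe"))
}

#' Stratify glycemic indices
#'
#' Maps baseline glucose and MBG to the three-level hyperglycemia scale
#' (no `< 140`, mild `[140, 200)`, severe `>= 200` mg/dL) and flags
#' MAG/MAGE/GLI/LAGE as high when strictly above their cutpoint. Cutpoints
#' may be the fixed clinical defaults ([paper_thresholds()]) or recomputed
#' as medians of the supplied cohort.
#'
#' @param indices Output of [compute_indices()].
#' @param thresholds `"paper"` (fixed defaults), `"median"` (cohort medians
#'   for MAG/MAGE/GLI/LAGE), or a named list as from [paper_thresholds()].
#' @return `indices` with added columns `baseline_stratum`, `mbg_stratum`
#'   (factors no/mild/severe) and logical flags `mag_high`, `mage_high`,
#'   `gli_high`, `lage_high`, plus the cutpoints used as an attribute
#'   `"thresholds"`.
#' @export
stratify_indices <- function(indices, thresholds = "paper") {
  th <- if (identical(thresholds, "paper")) {
    paper_thresholds()
  } else if (identical(thresholds, "median")) {
    th0 <- paper_thresholds()
    th0$mag <- stats::median(indices$mag_mmol_l_h, na.rm = TRUE)
    th0$mage <- stats::median(indices$mage_mmol_l, na.rm = TRUE)
    th0$gli <- stats::median(indices$gli_mmol2_h, na.rm = TRUE)
    th0$lage <- stats::median(indices$lage_mgdl, na.rm = TRUE)
    th0
  } else if (is.list(thresholds)) {
    need <- c("mag", "mage", "gli", "lage", "hyper_mild", "hyper_severe")
    miss <- setdiff(need, names(thresholds))
    if (length(miss)) stop("missing threshold(s): ",
                           paste(miss, collapse = ", "))
    thresholds
  } else {
    stop("thresholds must be 'paper', 'median', or a named list")
  }
  indices$baseline_stratum <- hyper_stratum(indices$baseline_mgdl,
                                            th$hyper_mild, th$hyper_severe)
  indices$mbg_stratum <- hyper_stratum(indices$mbg_mgdl,
                                       th$hyper_mild, th$hyper_severe)
  indices$mag_high <- indices$mag_mmol_l_h > th$mag
  indices$mage_high <- indices$mage_mmol_l > th$mage
  indices$gli_high <- indices$gli_mmol2_h > th$gli
  indices$lage_high <- indices$lage_mgdl > th$lage
  attr(indices, "thresholds") <- th
  indices
}
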