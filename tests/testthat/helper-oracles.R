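# Independent oracles and small fixture builders used across the suite.

# brute-force MAGE: explicit neighbour scan for local extrema on the
# deduplicated series, then mean of adjacent-extremum excursions > 1 SD
oracle_mage <- function(values_mgdl) {
  v <- values_mgdl / 18.016
  sdev <- sd(v)
  w <- v[c(TRUE, diff(v) != 0)]
  if (length(w) < 2) return(0)
  is_ext <- rep(FALSE, length(w))
  is_ext[1] <- TRUE
  is_ext[length(w)] <- TRUE
  if (length(w) >= 3) {
    for (i in 2:(length(w) - 1)) {
      if ((w[i] > w[i - 1] && w[i] > w[i + 1]) ||
          (w[i] < w[i - 1] && w[i] < w[i + 1])) is_ext[i] <- TRUE
    }
  }
  if (!any(is_ext[-c(1, length(w))])) return(0)  # no interior extremum
  ext <- w[is_ext]
  exc <- abs(diff(ext))
  exc <- exc[exc > sdev]
  if (length(exc) == 0) 0 else mean(exc)
}

oracle_mag <- function(values_mgdl, times) {
  v <- values_mgdl / 18.016
  tot <- 0
  for (i in 2:length(v)) tot <- tot + abs(v[i] - v[i - 1])
  tot / (max(times) - min(times))
}

oracle_gli <- function(values_mgdl, times) {
  v <- values_mgdl / 18.016
  tot <- 0
  for (i in 2:length(v)) tot <- tot + (v[i] - v[i - 1])^2 / (times[i] - times[i - 1])
  tot
}

random_series <- function(n = 6, times = NULL) {
  if (is.null(times)) times <- sort(sample(seq(0, 24, by = 0.5), n))
  glucose_series(times, runif(n, 60, 300))
}

# delirium adjudication truth table by direct rule restatement
oracle_adjudicate <- function(rass, f1, f2, f3, f4) {
  if (rass < -3) return("coma_ineligible")
  if (f1 && f2 && (f3 || f4)) "delirium" else "no_delirium"
}

# minimal clean record set for exclusion tests
clean_records <- function(n = 5) {
  df <- data.frame(patient_id = seq_len(n), admission_index = 1L,
                   age = 68, icu_los_hours = 48,
                   coma_or_delirium_24h = FALSE, dementia = FALSE,
                   psychoses = FALSE, tbi = FALSE, reading_disorder = FALSE,
                   intellectual_disability = FALSE,
                   neurological_disease = FALSE, alcohol_drug_abuse = FALSE)
  df
}

# long-format glucose table from a matrix of per-patient readings
glucose_long <- function(Y, times = seq(0, 20, by = 4)) {
  data.frame(patient_id = rep(seq_len(nrow(Y)), each = ncol(Y)),
             time_h = rep(times, nrow(Y)),
             glucose_mgdl = as.vector(t(Y)))
}
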