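# End-to-end orchestration: simulate -> cohort -> indices -> trajectory ->
# associate -> interact, with a run manifest.

#' Reference contingency counts of the motivating cohort
#'
#' Exposure-by-outcome counts (columns: no-delirium, delirium) as published
#' for the motivating cohort of 1,951 diabetic CABG ICU patients, for
#' re-deriving the unadjusted odds ratios and chi-square statistics from
#' counts alone.
#'
#' @return Named list of count matrices: `baseline`, `mbg` (3 strata),
#'   `lage`, `gli`, `mag`, `mage` (low/high), `traj_class` (classes 1--4),
#'   `gender`.
#' @export
reference_cohort_counts <- function() {
  m <- function(x, labels) matrix(x, ncol = 2, byrow = TRUE,
                                  dimnames = list(labels,
                                                  c("no_pod", "pod")))
  list(
    baseline = m(c(462, 48, 1074, 95, 235, 37), c("no", "mild", "severe")),
    mbg = m(c(885, 79, 838, 84, 48, 17), c("no", "mild", "severe")),
    lage = m(c(1193, 99, 578, 81), c("low", "high")),
    gli = m(c(912, 63, 859, 117), c("low", "high")),
    mag = m(c(919, 56, 852, 124), c("low", "high")),
    mage = m(c(890, 85, 881, 95), c("low", "high")),
    traj_class = m(c(1570, 141, 116, 10, 19, 7, 66, 22),
                   paste0("class", 1:4)),
    gender = m(c(451, 57, 1320, 123), c("female", "male"))
  )
}

write_stage_csv <- function(x, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  c(manifest, path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a simulated cohort (or supplied
#' inputs), writing per-stage CSV outputs and a JSON run manifest listing
#' every file, the seed, and per-stage row counts. Any stage failure halts
#' the run with the stage named. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [sim_config()] controlling the simulation stage.
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector; subset of `c("simulate", "cohort",
#'   "indices", "trajectory", "associate", "interact")` in that order.
#' @param thresholds Passed to [stratify_indices()].
#' @param kmax Largest candidate class count for the trajectory stage.
#' @param n_restarts EM restarts per candidate K.
#' @param exposures Exposure columns for the association stage.
#' @param subgroups Subgroup names for [subgroup_analysis()] (run for the
#'   first exposure), or NULL.
#' @param pairs Interaction pairs as `"exposure:modifier"` strings.
#' @param planted_exclusions Passed to [generate_cohort()].
#' @return The manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("glycotraj_run_"),
                         stages = c("simulate", "cohort", "indices",
                                    "trajectory", "associate", "interact"),
                         thresholds = "paper",
                         kmax = 5,
                         n_restarts = 3,
                         exposures = c("mbg_stratum", "mag_cat", "gli_cat",
                                       "lage_cat", "mage_cat"),
                         subgroups = c("age", "sepsis"),
                         pairs = c("mag:inr", "gli:inr"),
                         planted_exclusions = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = character(0))
  run_stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(f(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      rows = if (is.data.frame(res)) nrow(res) else NA)
    res
  }

  sim <- records <- glucose <- idx <- traj <- tab <- NULL
  if ("simulate" %in% stages) {
    simfull <- run_stage("simulate", function()
      generate_cohort(config, planted_exclusions = planted_exclusions))
    records <- simfull$records
    glucose <- simfull$glucose
    manifest$files <- write_stage_csv(records, out_dir, "records.csv",
                                      manifest$files)
    manifest$files <- write_stage_csv(glucose, out_dir, "glucose.csv",
                                      manifest$files)
    manifest$files <- write_stage_csv(simfull$classes, out_dir,
                                      "true_classes.csv", manifest$files)
  } else {
    stop("run_pipeline currently requires the simulate stage as data source")
  }

  if ("cohort" %in% stages) {
    coh <- run_stage("cohort", function() build_cohort(records))
    log <- coh$log
    records <- coh$kept
    glucose <- glucose[glucose$patient_id %in% records$patient_id, ]
    manifest$files <- write_stage_csv(records, out_dir, "cohort.csv",
                                      manifest$files)
    manifest$files <- write_stage_csv(log, out_dir, "exclusion_log.csv",
                                      manifest$files)
  }

  if ("indices" %in% stages) {
    idx <- run_stage("indices", function()
      stratify_indices(compute_indices(glucose), thresholds))
    manifest$files <- write_stage_csv(idx, out_dir, "indices.csv",
                                      manifest$files)
  }

  classes <- NULL
  if ("trajectory" %in% stages) {
    traj <- run_stage("trajectory", function() {
      tr <- fit_trajectories(glucose, kmax = kmax, seed = config$seed,
                             n_restarts = n_restarts)
      if (is.null(tr$best)) stop("no class count passes selection")
      assign_classes(tr$best)
    })
    manifest$files <- write_stage_csv(traj, out_dir, "assignments.csv",
                                      manifest$files)
    classes <- data.frame(patient_id = traj$patient_id, class = traj$class)
  } else {
    manifest$stages[["trajectory"]] <- list(skipped = TRUE)
  }

  if (any(c("associate", "interact") %in% stages)) {
    if (is.null(idx)) stop("associate/interact stages need the indices stage")
    tab <- build_analysis_table(records, idx, classes)
  }

  if ("associate" %in% stages) {
    assoc <- run_stage("associate", function() {
      exps <- exposures
      if (!is.null(classes)) exps <- c(exps, "traj_class")
      do.call(rbind, lapply(exps, function(e) {
        out <- run_model_ladder(tab, e)
        out$exposure <- e
        out
      }))
    })
    manifest$files <- write_stage_csv(assoc, out_dir, "associations.csv",
                                      manifest$files)
    if (length(subgroups)) {
      sg <- do.call(rbind, lapply(subgroups, function(s)
        subgroup_analysis(tab, exposures[1], s)))
      manifest$files <- write_stage_csv(sg, out_dir, "subgroups.csv",
                                        manifest$files)
    }
  }

  if ("interact" %in% stages) {
    inter <- run_stage("interact", function() {
      th <- attr(idx, "thresholds")
      cp <- list(mag = th$mag, gli = th$gli, mbg = th$hyper_mild)
      do.call(rbind, lapply(pairs, function(p) {
        pm <- strsplit(p, ":", fixed = TRUE)[[1]]
        d <- dichotomize_for_interaction(tab, pm[1], pm[2], cutpoints = cp)
        adjust <- setdiff(model_spec(5),
                          if (pm[2] == "inr") "inr" else "egfr")
        r <- compute_reri_ap(d, adjust = adjust)
        data.frame(pair = p,
                   or10 = r$or_table$or[1], or01 = r$or_table$or[2],
                   or11 = r$or_table$or[3],
                   reri = r$reri, reri_lo = r$reri_ci[1],
                   reri_hi = r$reri_ci[2],
                   ap = r$ap, ap_lo = r$ap_ci[1], ap_hi = r$ap_ci[2])
      }))
    })
    manifest$files <- write_stage_csv(inter, out_dir, "interactions.csv",
                                      manifest$files)
  }

  manifest$files <- c(manifest$files, file.path(out_dir, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
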