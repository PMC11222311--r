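# Descriptive statistics, logistic-regression ladders, covariate screening,
# and subgroup analyses for the delirium outcome.

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`, upper-tail p-value.
#'
#' @param tab Matrix of counts (at least 2 x 2, non-negative).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Mann-Whitney (Wilcoxon rank-sum) Z test
#'
#' Normal approximation with tie correction and 0.5 continuity correction.
#' The sign convention reports `Z = (U1 - mu) / sigma` for the first group,
#' so a first group with smaller values gives a negative Z.
#'
#' @param x Values in group 1.
#' @param y Values in group 2.
#' @return List with `z`, `p_value`, `u` (U statistic of group 1).
#' @export
mann_whitney_z <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty group")
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) stop("degenerate rank variance (all values tied)")
  cc <- if (u1 == mu) 0 else 0.5 * sign(u1 - mu)
  z <- (u1 - mu - cc) / sqrt(sigma2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), u = u1)
}

#' Fit a logistic regression with odds ratios and Wald intervals
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial); per-term odds ratios with 95% Wald confidence
#' intervals `exp(b +/- 1.96 SE)` and Wald p-values. Errors on rank-deficient
#' designs (naming the aliased terms) and on separation (any |coefficient|
#' above 15 on the logit scale).
#'
#' @param formula Model formula with a binary response.
#' @param data Data frame.
#' @return Object of class `logit_fit`: `table` (term, estimate, se, or,
#'   ci_low, ci_high, p_value), `vcov`, `loglik`, `n_obs`, `converged`,
#'   `glm` (the underlying fit).
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      # separation is detected explicitly below; silence the symptom
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (any(abs(cf[-1]) > 15)) {
    stop("separation: coefficient(s) diverging for ",
         paste(names(cf)[-1][abs(cf[-1]) > 15], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  tab <- data.frame(
    term = names(cf),
    estimate = unname(cf),
    se = unname(se),
    or = exp(unname(cf)),
    ci_low = exp(unname(cf - 1.96 * se)),
    ci_high = exp(unname(cf + 1.96 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, vcov = stats::vcov(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = stats::nobs(fit), converged = fit$converged,
                 glm = fit),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("logistic fit, n = %d, logLik = %.2f\n", x$n_obs, x$loglik))
  print(transform(x$table,
                  or = round(or, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3),
                  estimate = round(estimate, 4), se = round(se, 4),
                  p_value = signif(p_value, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Expand an exposure-by-outcome count table into patient rows
#'
#' Turns an r x 2 contingency table (rows = exposure levels, columns =
#' no-event / event counts) into a per-patient data frame with an ordered
#' factor exposure (first row = reference) and binary outcome, ready for
#' [fit_logistic()].
#'
#' @param counts Matrix or data frame, r x 2, first column non-event counts.
#' @param levels Exposure level labels (defaults to rownames).
#' @return Data frame with columns `exposure`, `outcome`.
#' @export
expand_counts <- function(counts, levels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(levels)) levels <- paste0("level", seq_len(nrow(counts)))
  data.frame(
    exposure = factor(rep(rep(levels, 2), as.vector(counts)),
                      levels = levels),
    outcome = rep(c(0L, 1L), colSums(counts))
  )
}

# Nested adjustment sets of the five-model ladder.
MODEL_COVARIATES <- list(
  model1 = character(0),
  model2 = c("age", "hr", "spo2"),
  model3 = c("age", "hr", "spo2", "rdw", "hematocrit", "egfr", "inr", "pt",
             "bun", "bicarbonate", "na_meql"),
  model4 = c("age", "hr", "spo2", "rdw", "hematocrit", "egfr", "inr", "pt",
             "bun", "bicarbonate", "na_meql", "sofa", "cci"),
  model5 = c("age", "hr", "spo2", "rdw", "hematocrit", "egfr", "inr", "pt",
             "bun", "bicarbonate", "na_meql", "sofa", "cci", "sepsis",
             "ckd", "mechanical_ventilation", "vasopressor")
)

#' Adjustment covariates of one ladder model
#'
#' Model 1 is unadjusted; Model 2 adds age, heart rate and SpO2; Model 3
#' adds the laboratory panel (RDW, hematocrit, eGFR, INR, PT, BUN,
#' bicarbonate, sodium); Model 4 adds SOFA and CCI; Model 5 adds sepsis,
#' CKD, mechanical ventilation and vasopressor use.
#'
#' @param model_id Integer 1--5.
#' @return Character vector of covariate names.
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% 1:5) stop("model_id must be 1..5")
  MODEL_COVARIATES[[model_id]]
}

#' Run the nested logistic-model ladder for one exposure
#'
#' Fits one logistic regression per adjustment model (1 = unadjusted
#' through 5 = fully adjusted), dummy-coding the exposure against its first
#' factor level, and collects the exposure odds ratios.
#'
#' @param data Analysis data frame: binary `outcome` column, the exposure
#'   column, and the ladder covariates.
#' @param exposure Name of the exposure column (factor or logical; logicals
#'   are coded FALSE = reference).
#' @param models Integer vector of model ids (default 1:5).
#' @return Data frame with one row per exposure level x model: `model`,
#'   `level`, `or`, `ci_low`, `ci_high`, `p_value`, `n_obs`; plus attribute
#'   `"fits"` holding the `logit_fit` objects.
#' @export
run_model_ladder <- function(data, exposure, models = 1:5) {
  if (!exposure %in% names(data)) stop("missing exposure column: ", exposure)
  x <- data[[exposure]]
  if (is.logical(x)) data[[exposure]] <- factor(x, levels = c(FALSE, TRUE),
                                                labels = c("low", "high"))
  if (!is.factor(data[[exposure]])) data[[exposure]] <- factor(data[[exposure]])
  fits <- list()
  rows <- list()
  for (m in models) {
    covs <- model_spec(m)
    missing_covs <- setdiff(covs, names(data))
    if (length(missing_covs)) {
      stop("model ", m, " covariate(s) absent: ",
           paste(missing_covs, collapse = ", "))
    }
    fm <- stats::as.formula(paste("outcome ~", paste(
      c(exposure, covs), collapse = " + ")))
    fit <- fit_logistic(fm, data)
    fits[[paste0("model", m)]] <- fit
    tab <- fit$table
    keep <- startsWith(tab$term, exposure)
    lev <- sub(paste0("^", exposure), "", tab$term[keep])
    rows[[length(rows) + 1]] <- data.frame(
      model = m, level = lev, or = tab$or[keep],
      ci_low = tab$ci_low[keep], ci_high = tab$ci_high[keep],
      p_value = tab$p_value[keep], n_obs = fit$n_obs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Univariate covariate screening
#'
#' Fits one univariate logistic regression of the outcome on each candidate
#' and retains those with a likelihood-ratio p-value below `alpha` (no
#' multiplicity adjustment). Constant candidates are skipped with a warning.
#'
#' @param data Analysis data frame with binary `outcome`.
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Retention threshold (default 0.05).
#' @return Data frame `candidate`, `p_value`, `selected`.
#' @export
screen_covariates <- function(data, candidates, alpha = 0.05) {
  rows <- lapply(candidates, function(v) {
    if (!v %in% names(data)) stop("candidate absent: ", v)
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("skipping constant candidate: ", v)
      return(data.frame(candidate = v, p_value = NA_real_,
                        selected = FALSE))
    }
    d <- data[!is.na(x) & !is.na(data$outcome), c("outcome", v)]
    f1 <- stats::glm(stats::as.formula(paste("outcome ~", v)),
                     family = stats::binomial(), data = d)
    f0 <- stats::glm(outcome ~ 1, family = stats::binomial(), data = d)
    lr <- 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0)))
    df <- attr(stats::logLik(f1), "df") - attr(stats::logLik(f0), "df")
    p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
    data.frame(candidate = v, p_value = p, selected = p < alpha)
  })
  do.call(rbind, rows)
}

#' Table-1 style group comparison
#'
#' Continuous variables: per-group median (Q1, Q3) with the Mann-Whitney Z
#' test. Categorical variables: counts (%) with the Pearson chi-square test
#' (no continuity correction).
#'
#' @param data Data frame.
#' @param group_var Binary grouping column name.
#' @param continuous,categorical Character vectors of variable names.
#' @return List with data frames `continuous` and `categorical`.
#' @export
describe_cohort <- function(data, group_var, continuous = character(0),
                            categorical = character(0)) {
  g <- data[[group_var]]
  if (length(unique(g[!is.na(g)])) != 2) stop("group_var must be binary")
  glev <- sort(unique(g[!is.na(g)]))
  fmt_q <- function(x) sprintf("%.2f (%.2f, %.2f)",
                               stats::median(x, na.rm = TRUE),
                               stats::quantile(x, 0.25, na.rm = TRUE),
                               stats::quantile(x, 0.75, na.rm = TRUE))
  cont <- lapply(continuous, function(v) {
    x <- data[[v]]
    if (all(is.na(x))) {
      warning("all-missing variable skipped: ", v)
      return(NULL)
    }
    mw <- mann_whitney_z(x[g == glev[2] & !is.na(x)],
                         x[g == glev[1] & !is.na(x)])
    data.frame(variable = v,
               group1 = fmt_q(x[g == glev[1]]),
               group2 = fmt_q(x[g == glev[2]]),
               z = mw$z, p_value = mw$p_value, stringsAsFactors = FALSE)
  })
  cat_ <- lapply(categorical, function(v) {
    x <- data[[v]]
    if (all(is.na(x))) {
      warning("all-missing variable skipped: ", v)
      return(NULL)
    }
    tab <- table(x, g)
    ct <- chisq_test(tab)
    data.frame(variable = v,
               levels = paste(rownames(tab), collapse = "/"),
               group1 = paste(tab[, 1], collapse = "/"),
               group2 = paste(tab[, 2], collapse = "/"),
               chisq = ct$statistic, df = ct$df, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  list(continuous = do.call(rbind, cont),
       categorical = do.call(rbind, cat_))
}

# Default stratifier definitions: cutpoint rules matching the published
# subgroup analyses.
SUBGROUP_DEFS <- list(
  age = list(var = "age", cut = 65,
             labels = c("age<65", "age>=65"),
             split = function(x) x >= 65, drop = "age"),
  gender = list(var = "gender", labels = c("female", "male"),
                split = function(x) x == "male", drop = NULL),
  race = list(var = "race", labels = c("white", "other"),
              split = function(x) x != "white", drop = NULL),
  egfr = list(var = "egfr", cut = 60,
              labels = c("egfr>=60", "egfr<60"),
              split = function(x) x < 60, drop = "egfr"),
  inr = list(var = "inr", cut = 1.5,
             labels = c("inr<1.5", "inr>=1.5"),
             split = function(x) x >= 1.5, drop = "inr"),
  sepsis = list(var = "sepsis", labels = c("non-sepsis", "sepsis"),
                split = function(x) x == 1, drop = "sepsis"),
  vent = list(var = "mechanical_ventilation",
              labels = c("non-ventilation", "ventilation"),
              split = function(x) x == 1, drop = "mechanical_ventilation"),
  vasopressor = list(var = "vasopressor",
                     labels = c("non-vasopressor", "vasopressor"),
                     split = function(x) x == 1, drop = "vasopressor")
)

#' Subgroup association analysis
#'
#' Splits the cohort on a stratifying variable (age at 65 years, eGFR at
#' 60, INR at 1.5, or a binary flag) and refits the fully adjusted
#' (Model 5) exposure model within each stratum, dropping the stratifying
#' variable from the adjustment set. Strata in which the model is not
#' estimable (no events, separation, rank deficiency) are flagged rather
#' than raising an error.
#'
#' @param data Analysis data frame (see [run_model_ladder()]).
#' @param exposure Exposure column name.
#' @param subgroup One of `"age"`, `"gender"`, `"race"`, `"egfr"`, `"inr"`,
#'   `"sepsis"`, `"vent"`, `"vasopressor"`.
#' @return Data frame with one row per stratum x exposure level: `subgroup`,
#'   `stratum`, `n`, `events`, `level`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `note`.
#' @export
subgroup_analysis <- function(data, exposure, subgroup) {
  def <- SUBGROUP_DEFS[[subgroup]]
  if (is.null(def)) stop("unknown subgroup: ", subgroup)
  hi <- def$split(data[[def$var]])
  covs <- setdiff(model_spec(5), def$drop %||% character(0))
  fm <- stats::as.formula(paste("outcome ~", paste(
    c(exposure, covs), collapse = " + ")))
  rows <- list()
  for (s in 1:2) {
    d <- data[if (s == 1) !hi else hi, , drop = FALSE]
    n <- nrow(d)
    ev <- sum(d$outcome, na.rm = TRUE)
    if (ev == 0 || ev == n) {
      rows[[length(rows) + 1]] <- data.frame(
        subgroup = subgroup, stratum = def$labels[s], n = n, events = ev,
        level = NA_character_, or = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, note = "inestimable",
        stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(fit_logistic(fm, d), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        subgroup = subgroup, stratum = def$labels[s], n = n, events = ev,
        level = NA_character_, or = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_,
        note = paste("inestimable:", conditionMessage(fit)),
        stringsAsFactors = FALSE)
      next
    }
    tab <- fit$table
    keep <- startsWith(tab$term, exposure)
    rows[[length(rows) + 1]] <- data.frame(
      subgroup = subgroup, stratum = def$labels[s], n = n, events = ev,
      level = sub(paste0("^", exposure), "", tab$term[keep]),
      or = tab$or[keep], ci_low = tab$ci_low[keep],
      ci_high = tab$ci_high[keep], p_value = tab$p_value[keep],
      note = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Assemble the per-patient analysis table
#'
#' Merges records, stratified glycemic indices and (optionally) trajectory
#' classes into the one-row-per-patient frame the association and
#' interaction analyses consume. Exposure factors are coded with the
#' conventional reference levels (no hyperglycemia; low index; class 1).
#'
#' @param records Cohort records with `patient_id` and `pod`.
#' @param indices Output of [stratify_indices()].
#' @param classes Optional data frame `patient_id`, `class`.
#' @return Data frame with `outcome` (= `pod`), exposure factors
#'   `baseline_stratum`, `mbg_stratum`, `mag_cat`, `mage_cat`, `gli_cat`,
#'   `lage_cat`, `traj_class` (when classes given), and all record columns.
#' @export
build_analysis_table <- function(records, indices, classes = NULL) {
  d <- merge(records, indices, by = "patient_id")
  d$outcome <- d$pod
  two <- function(flag) factor(ifelse(flag, "high", "low"),
                               levels = c("low", "high"))
  d$mag_cat <- two(d$mag_high)
  d$mage_cat <- two(d$mage_high)
  d$gli_cat <- two(d$gli_high)
  d$lage_cat <- two(d$lage_high)
  if (!is.null(classes)) {
    d <- merge(d, classes, by = "patient_id")
    d$traj_class <- factor(paste0("class", d$class),
                           levels = paste0("class", sort(unique(d$class))))
  }
  d
}
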