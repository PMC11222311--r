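# Latent growth mixture model for 24-h glucose trajectories.
#
# Within class k a patient's readings follow
#   y_it = b0k + b1k t + b2k t^2 + b_i + e_it,
#   b_i ~ N(0, sigma_b^2), e_it ~ N(0, sigma^2),
# i.e. a quadratic mean curve per class with a shared patient-level random
# intercept. The marginal per-patient covariance is sigma_b^2 J + sigma^2 I,
# whose inverse and determinant are available in closed form, so the EM
# E-step needs no matrix decompositions. Patients are grouped by identical
# time grids for vectorization. The time covariate is centred at 12 h and
# scaled by 12 for conditioning; coefficients are reported on the hour scale.

time_basis <- function(t) {
  u <- (t - 12) / 12
  cbind(1, u, u^2)
}

# map coefficients on the scaled basis back to the hour scale
scaled_to_hours <- function(a) {
  Tm <- rbind(c(1, -1, 1), c(0, 1 / 12, -1 / 6), c(0, 0, 1 / 144))
  as.vector(Tm %*% a)
}

hours_jacobian <- function() {
  rbind(c(1, -1, 1), c(0, 1 / 12, -1 / 6), c(0, 0, 1 / 144))
}

# Split a long glucose table into grid groups: patients sharing a time grid
# are stacked into a Y matrix for vectorized likelihood evaluation.
prepare_lgmm_data <- function(glucose) {
  req <- c("patient_id", "time_h", "glucose_mgdl")
  if (!all(req %in% names(glucose))) {
    stop("glucose table needs columns ", paste(req, collapse = ", "))
  }
  glucose <- glucose[order(glucose$patient_id, glucose$time_h), ]
  sp <- split(glucose, glucose$patient_id)
  nobs <- vapply(sp, nrow, integer(1))
  if (any(nobs < 3)) {
    stop("every patient needs at least 3 readings to fit a quadratic curve")
  }
  sig <- vapply(sp, function(d) paste(d$time_h, collapse = ","), character(1))
  groups <- lapply(split(seq_along(sp), sig), function(ii) {
    t <- sp[[ii[1]]]$time_h
    list(
      idx = ii,
      times = t,
      X = time_basis(t),
      Y = do.call(rbind, lapply(sp[ii], function(d) d$glucose_mgdl))
    )
  })
  list(groups = groups, ids = names(sp), N = length(sp))
}

# log marginal density of each patient (rows) under each class (cols)
loglik_matrix <- function(groups, beta, sb2, s2, N, K) {
  L <- matrix(NA_real_, N, K)
  for (g in groups) {
    n <- length(g$times)
    lam <- sb2 / (s2 + n * sb2)
    logdet <- (n - 1) * log(s2) + log(s2 + n * sb2)
    M <- g$X %*% beta                       # n x K class mean curves
    ry2 <- rowSums(g$Y^2)
    ry1 <- rowSums(g$Y)
    for (k in seq_len(K)) {
      rss <- ry2 - 2 * (g$Y %*% M[, k]) + sum(M[, k]^2)
      s1 <- ry1 - sum(M[, k])
      quad <- (rss - lam * s1^2) / s2
      L[g$idx, k] <- -0.5 * (n * log(2 * pi) + logdet + quad)
    }
  }
  L
}

logsumexp_rows <- function(A) {
  m <- apply(A, 1, max)
  m + log(rowSums(exp(A - m)))
}

# One EM run from a hard initial assignment. Returns NULL if a class
# degenerates (mixing proportion < 1e-6).
em_run <- function(dat, K, init_class, max_iter = 500, tol = 1e-6) {
  groups <- dat$groups
  N <- dat$N
  W <- matrix(0, N, K)
  W[cbind(seq_len(N), init_class)] <- 1

  # initial parameters from the hard assignment
  pi_k <- pmax(colMeans(W), 1e-3)
  pi_k <- pi_k / sum(pi_k)
  beta <- update_beta(groups, W, m_ik = matrix(0, N, K))
  vc <- init_variances(groups, W, beta)
  sb2 <- vc$sb2; s2 <- vc$s2

  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    L <- loglik_matrix(groups, beta, sb2, s2, N, K)
    A <- sweep(L, 2, log(pi_k), `+`)
    ll <- sum(logsumexp_rows(A))
    if (ll < ll_old - 1e-6 * (1 + abs(ll_old))) {
      stop("EM log-likelihood decreased: bug in M-step")
    }
    ll_trace <- c(ll_trace, ll)
    W <- exp(A - logsumexp_rows(A))
    pi_new <- colMeans(W)
    if (any(pi_new < 1e-6)) return(NULL)  # degenerate class

    # posterior moments of the random intercept given class
    mv <- b_moments(groups, W, beta, sb2, s2, N, K)
    beta_new <- update_beta(groups, W, mv$m)
    s2_new <- update_s2(groups, W, beta_new, mv)
    sb2_new <- sum(W * (mv$m^2 + mv$v)) / N

    conv <- is.finite(ll_old) &&
      abs(ll - ll_old) < tol * (1 + abs(ll))
    pi_k <- pi_new; beta <- beta_new
    s2 <- max(s2_new, 1e-6); sb2 <- max(sb2_new, 0)
    ll_old <- ll
    if (conv) break
  }
  list(pi = pi_k, beta = beta, sb2 = sb2, s2 = s2, loglik = ll_old,
       posteriors = W, n_iter = iter, converged = iter < max_iter,
       ll_trace = ll_trace)
}

# E[b_i | class k] and Var[b_i | data] per grid size
b_moments <- function(groups, W, beta, sb2, s2, N, K) {
  m <- matrix(0, N, K)
  v <- numeric(N)
  for (g in groups) {
    n <- length(g$times)
    vg <- if (sb2 == 0) 0 else 1 / (1 / sb2 + n / s2)
    v[g$idx] <- vg
    M <- g$X %*% beta
    ry1 <- rowSums(g$Y)
    for (k in seq_len(K)) {
      s1 <- ry1 - sum(M[, k])
      m[g$idx, k] <- if (sb2 == 0) 0 else vg * s1 / s2
    }
  }
  list(m = m, v = v)
}

update_beta <- function(groups, W, m_ik) {
  K <- ncol(W)
  beta <- matrix(0, 3, K)
  for (k in seq_len(K)) {
    A <- matrix(0, 3, 3)
    cvec <- numeric(3)
    for (g in groups) {
      w <- W[g$idx, k]
      A <- A + sum(w) * crossprod(g$X)
      yw <- colSums(w * g$Y) - sum(w * m_ik[g$idx, k])
      cvec <- cvec + as.vector(crossprod(g$X, yw))
    }
    beta[, k] <- solve(A, cvec)
  }
  beta
}

update_s2 <- function(groups, W, beta, mv) {
  num <- 0
  den <- 0
  for (g in groups) {
    n <- length(g$times)
    M <- g$X %*% beta
    ry2 <- rowSums(g$Y^2)
    ry1 <- rowSums(g$Y)
    for (k in seq_len(ncol(W))) {
      w <- W[g$idx, k]
      rss <- ry2 - 2 * (g$Y %*% M[, k]) + sum(M[, k]^2)
      s1 <- ry1 - sum(M[, k])
      m <- mv$m[g$idx, k]
      num <- num + sum(w * (rss - 2 * m * s1 + n * (m^2 + mv$v[g$idx])))
    }
    den <- den + n * length(g$idx)
  }
  num / den
}

init_variances <- function(groups, W, beta) {
  resid_b <- numeric(0)
  resid_w <- numeric(0)
  cls <- apply(W, 1, which.max)
  for (g in groups) {
    M <- g$X %*% beta
    R <- g$Y - t(M[, cls[g$idx], drop = FALSE])
    mi <- rowMeans(R)
    resid_b <- c(resid_b, mi)
    resid_w <- c(resid_w, as.vector(R - mi))
  }
  list(sb2 = max(stats::var(resid_b), 1e-2),
       s2 = max(stats::var(resid_w), 1e-2))
}

# per-patient OLS quadratic coefficients for initialization
ols_coefficients <- function(dat) {
  out <- matrix(NA_real_, dat$N, 3)
  for (g in dat$groups) {
    H <- solve(crossprod(g$X), t(g$X))
    out[g$idx, ] <- g$Y %*% t(H)
  }
  out
}

#' Fit a latent growth mixture model to 24-h glucose series
#'
#' Maximizes the K-class mixture likelihood of quadratic growth curves with
#' a shared patient-level random intercept by EM (random intercept treated
#' as a second latent variable; closed-form E-step). Initialization clusters
#' per-patient OLS quadratic coefficients with k-means; additional restarts
#' perturb the assignment. The best restart by final log-likelihood is kept;
#' the run is deterministic given `seed`. Classes are relabelled by
#' descending mixing proportion for stable reporting.
#'
#' @param glucose Long-format data frame (`patient_id`, `time_h`,
#'   `glucose_mgdl`); every patient needs at least 3 readings.
#' @param K Number of classes (1--5 typical).
#' @param seed Integer seed for initialization.
#' @param n_restarts Number of EM starts.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` or `max_iter` iterations.
#' @return An object of class `lgmm_fit`: coefficients on the hour scale
#'   (`coefficients`, 3 x K: intercept mg/dL, slope mg/dL/h, quadratic
#'   mg/dL/h^2), `coef_se`, mixing proportions `pi`, variances `sigma_b2`,
#'   `sigma2`, `loglik`, `aic`, `bic`, `entropy`, `posteriors`,
#'   `map_class`, `class_shares`, `mean_posterior`, `n_params`, `n_patients`,
#'   `patient_ids`, `n_iter`, `converged`, `ll_trace`.
#' @export
fit_lgmm <- function(glucose, K, seed = 1L, n_restarts = 5,
                     max_iter = 500, tol = 1e-6) {
  if (K < 1) stop("K must be at least 1")
  dat <- prepare_lgmm_data(glucose)
  if (K > dat$N) stop("more classes than patients")
  set.seed(seed)
  coefs <- ols_coefficients(dat)

  inits <- vector("list", n_restarts)
  if (K == 1) {
    inits <- rep(list(rep(1L, dat$N)), max(1, n_restarts))
  } else {
    km <- stats::kmeans(coefs, centers = K, nstart = 5, iter.max = 50)
    inits[[1]] <- km$cluster
    for (r in seq_len(n_restarts)[-1]) {
      # perturb: reassign a random 25% of patients uniformly
      a <- km$cluster
      flip <- sample.int(dat$N, ceiling(dat$N / 4))
      a[flip] <- sample.int(K, length(flip), replace = TRUE)
      # ensure all classes present
      miss <- setdiff(seq_len(K), unique(a))
      if (length(miss)) a[sample.int(dat$N, length(miss))] <- miss
      inits[[r]] <- a
    }
  }

  best <- NULL
  n_degenerate <- 0
  for (init in inits) {
    fit <- em_run(dat, K, init, max_iter = max_iter, tol = tol)
    if (is.null(fit)) {
      n_degenerate <- n_degenerate + 1
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts degenerated; try fewer classes")
  }

  # order classes by descending mixing proportion
  ord <- order(best$pi, decreasing = TRUE)
  pi_k <- best$pi[ord]
  beta_s <- best$beta[, ord, drop = FALSE]
  W <- best$posteriors[, ord, drop = FALSE]

  map_class <- max.col(W, ties.method = "first")
  shares <- tabulate(map_class, nbins = K) / dat$N
  mean_post <- vapply(seq_len(K), function(k) {
    members <- map_class == k
    if (!any(members)) NA_real_ else mean(W[members, k])
  }, numeric(1))

  beta_h <- apply(beta_s, 2, scaled_to_hours)
  se_h <- coef_se_hours(dat, W, beta_s, best$sb2, best$s2)

  p <- 3 * K + (K - 1) + 2
  structure(list(
    K = K,
    coefficients = matrix(beta_h, nrow = 3,
                          dimnames = list(c("b0", "b1", "b2"),
                                          paste0("class", seq_len(K)))),
    coef_se = se_h,
    pi = pi_k,
    sigma_b2 = best$sb2,
    sigma2 = best$s2,
    loglik = best$loglik,
    aic = -2 * best$loglik + 2 * p,
    bic = -2 * best$loglik + p * log(dat$N),
    entropy = compute_entropy(W),
    posteriors = W,
    map_class = map_class,
    class_shares = shares,
    mean_posterior = mean_post,
    n_params = p,
    n_patients = dat$N,
    patient_ids = dat$ids,
    n_iter = best$n_iter,
    converged = best$converged,
    n_degenerate_restarts = n_degenerate,
    ll_trace = best$ll_trace
  ), class = "lgmm_fit")
}

# approximate curve-coefficient SEs from the weighted GLS information,
# transformed to the hour scale
coef_se_hours <- function(dat, W, beta_s, sb2, s2) {
  K <- ncol(W)
  Tm <- hours_jacobian()
  se <- matrix(NA_real_, 3, K,
               dimnames = list(c("b0", "b1", "b2"),
                               paste0("class", seq_len(K))))
  for (k in seq_len(K)) {
    info <- matrix(0, 3, 3)
    for (g in dat$groups) {
      n <- length(g$times)
      lam <- sb2 / (s2 + n * sb2)
      XtX <- crossprod(g$X)
      X1 <- colSums(g$X)
      Si <- (XtX - lam * tcrossprod(X1)) / s2
      info <- info + sum(W[g$idx, k]) * Si
    }
    V <- Tm %*% solve(info) %*% t(Tm)
    se[, k] <- sqrt(diag(V))
  }
  se
}

#' @export
print.lgmm_fit <- function(x, ...) {
  cat(sprintf("LGMM fit: K = %d classes, N = %d patients\n",
              x$K, x$n_patients))
  cat(sprintf("  logLik %.2f  AIC %.1f  BIC %.1f  entropy %.3f\n",
              x$loglik, x$aic, x$bic, x$entropy))
  cat("  mixing proportions:",
      paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("  curve coefficients (mg/dL; per h; per h^2):\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p log p) / (N log K)`: 1 for a perfectly sharp classification,
#' 0 when every posterior is uniform. For a single class the value is 1 by
#' convention.
#'
#' @param posteriors N x K matrix of class posterior probabilities.
#' @return Value in `[0, 1]`.
#' @export
compute_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (K == 1) return(1)
  N <- nrow(posteriors)
  plp <- posteriors * log(posteriors)
  plp[posteriors == 0] <- 0
  1 - sum(-plp) / (N * log(K))
}

#' MAP class assignment
#'
#' @param model An `lgmm_fit`.
#' @return Data frame `patient_id`, `class` (argmax posterior, ties toward
#'   the lower class index), `posterior` (probability of the assigned
#'   class).
#' @export
assign_classes <- function(model) {
  data.frame(
    patient_id = model$patient_ids,
    class = model$map_class,
    posterior = model$posteriors[cbind(seq_len(model$n_patients),
                                       model$map_class)],
    stringsAsFactors = FALSE
  )
}

#' Class-number selection by the four-condition protocol
#'
#' Candidate class counts are screened on three adequacy gates — relative
#' entropy above `entropy_min`, every class holding at least `min_share` of
#' patients (MAP assignment), and every class's mean posterior probability
#' above `min_posterior` — and the best survivor is the one with the
#' smallest BIC (ties: smaller AIC, then larger K; by the nesting direction
#' the largest log-likelihood criterion is monotone in K and is reported,
#' not used as a separate gate).
#'
#' @param models List of `lgmm_fit` objects (one per candidate K).
#' @param min_share Minimum MAP class share (default 0.01).
#' @param min_posterior Minimum mean posterior per class (default 0.70,
#'   strict).
#' @param entropy_min Minimum relative entropy (default 0.70, strict).
#' @return List of class `class_selection`: `table` (per-K fit statistics
#'   and gate outcomes) and `selected_K` (NA when no K passes).
#' @export
select_classes <- function(models, min_share = 0.01, min_posterior = 0.70,
                           entropy_min = 0.70) {
  tab <- do.call(rbind, lapply(models, function(m) {
    data.frame(
      K = m$K,
      loglik = m$loglik,
      aic = m$aic,
      bic = m$bic,
      entropy = m$entropy,
      min_share = min(m$class_shares),
      min_mean_posterior = min(m$mean_posterior, na.rm = TRUE),
      pass_entropy = m$entropy > entropy_min,
      pass_share = min(m$class_shares) >= min_share,
      pass_posterior = min(m$mean_posterior, na.rm = TRUE) > min_posterior
    )
  }))
  tab$pass_all <- tab$pass_entropy & tab$pass_share & tab$pass_posterior
  surv <- tab[tab$pass_all, , drop = FALSE]
  selected <- if (nrow(surv) == 0) NA_integer_ else {
    o <- order(surv$bic, surv$aic, -surv$K)
    surv$K[o[1]]
  }
  structure(list(table = tab, selected_K = selected),
            class = "class_selection")
}

#' @export
print.class_selection <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  if (is.na(x$selected_K)) cat("no K passes all selection conditions\n")
  else cat("selected K =", x$selected_K, "\n")
  invisible(x)
}

#' Fit candidate models for K = 1..kmax and select the class count
#'
#' @inheritParams fit_lgmm
#' @param kmax Largest candidate class count.
#' @param ... Passed to [select_classes()].
#' @return List with `models` (per-K `lgmm_fit`), `selection`
#'   (`class_selection`), and `best` (the selected fit, or NULL).
#' @export
fit_trajectories <- function(glucose, kmax = 5, seed = 1L, n_restarts = 5,
                             ...) {
  models <- lapply(seq_len(kmax), function(k)
    fit_lgmm(glucose, K = k, seed = seed + k, n_restarts = n_restarts))
  sel <- select_classes(models, ...)
  best <- if (is.na(sel$selected_K)) NULL else models[[sel$selected_K]]
  list(models = models, selection = sel, best = best)
}
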