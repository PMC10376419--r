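#' Fit a latent-variable model by diagonally weighted least squares
#'
#' Minimizes the DWLS discrepancy
#' `F(theta) = sum_k w_k (s_k - sigma_k(theta))^2` over the nonredundant
#' sample moments `s` (Pearson correlations among indicators, polyserial
#' correlations with the disease latent response, and the disease threshold)
#' with weights `w_k = 1 / asymptotic variance`. All variables are
#' standardized and latent variances are fixed to 1, so the free parameters
#' are the loadings, the lv1-lv2 correlation (two-latent case), the
#' latent-to-disease path coefficients, and the probit threshold.
#'
#' Fit statistics follow the conventional DWLS definitions:
#' `chi2 = (n - 1) F_min`; `GFI = 1 - F_min / F_baseline` where the baseline
#' model sets every model-implied moment to zero;
#' `AGFI = 1 - (1 - GFI) * m / df` with `m` moments and `df = m - #free`;
#' `RMSEA = sqrt(max((chi2 - df) / (df (n - 1)), 0))` (0 whenever
#' `chi2 <= df`). A saturated model (`df = 0`) reports `GFI` but `NA` for
#' AGFI/RMSEA.
#'
#' Optimization is quasi-Newton ([stats::nlminb()]) from `n_restarts`
#' deterministically jittered starts, convergence tolerance 1e-8 on F. The
#' latent sign is fixed by forcing each latent's first indicator loading
#' non-negative.
#'
#' @param spec an [`sem_spec`][build_sem_spec] (with or without a disease
#'   node).
#' @param mcor a [mixed_correlations()] / [as_mixed_corr()] object covering
#'   every indicator (and the disease moments if the spec has a disease
#'   node).
#' @param n sample size; defaults to `mcor$n`.
#' @param n_restarts number of jittered optimizer starts (default 5).
#' @return object of class `sem_fit`.
#' @export
fit_dwls <- function(spec, mcor, n = mcor$n, n_restarts = 5L) {
  stopifnot(inherits(spec, "sem_spec"), inherits(mcor, "mixed_corr"))
  ind <- unlist(spec$lv, use.names = FALSE)
  missing_ind <- setdiff(ind, mcor$vars)
  if (length(missing_ind))
    config_error(paste0("moments missing for indicator(s): ",
                        paste(missing_ind, collapse = ", ")))
  p <- length(ind)
  n_lv <- length(spec$lv)
  lv_of <- rep(seq_len(n_lv), lengths(spec$lv))
  has_d <- !is.null(spec$disease)
  if (has_d && is.null(mcor$cor_xd))
    config_error("spec has a disease node but mcor carries no disease moments")
  free_psi <- spec$correlated_latents && n_lv == 2

  R <- mcor$cor_xx[ind, ind]
  ut <- upper.tri(R)
  s <- R[ut]
  # weights are inverse sqrt(n)-scaled asymptotic variances (Gamma = n*avar),
  # so that chi2 = (n - 1) * F_min is on the chi-square scale
  w <- 1 / pmax(n * mcor$avar_xx[ind, ind][ut], 1e-10)
  if (has_d) {
    s <- c(s, mcor$cor_xd[ind], mcor$tau)
    w <- c(w, 1 / pmax(n * mcor$avar_xd[ind], 1e-10),
           1 / pmax(n * mcor$avar_tau, 1e-10))
  }
  m_moments <- length(s)

  # parameter packing: lambda[1..p], psi12?, beta[1..n_lv]?, tau?
  i_lam <- seq_len(p)
  i_psi <- if (free_psi) p + 1L else integer(0)
  i_beta <- if (has_d) (p + free_psi) + seq_len(n_lv) else integer(0)
  i_tau <- if (has_d) (p + free_psi + n_lv) + 1L else integer(0)
  n_par <- p + free_psi + has_d * (n_lv + 1L)

  implied <- function(th) {
    lam <- th[i_lam]
    Psi <- diag(1, n_lv)
    if (free_psi) Psi[1, 2] <- Psi[2, 1] <- th[i_psi]
    L <- matrix(0, p, n_lv)
    L[cbind(seq_len(p), lv_of)] <- lam
    Sxx <- L %*% Psi %*% t(L)
    sig <- Sxx[ut]
    pen <- 0
    if (has_d) {
      beta <- th[i_beta]
      v <- drop(Psi %*% beta)
      sig <- c(sig, drop(L %*% v), th[i_tau])
      expl <- sum(beta * v)
      if (expl > 0.98) pen <- 1e4 * (expl - 0.98)^2
    }
    list(sigma = sig, penalty = pen)
  }
  objective <- function(th) {
    im <- implied(th)
    sum(w * (s - im$sigma)^2) + im$penalty
  }

  # starts: anchor loadings to the mean absolute within-block correlation
  start <- numeric(n_par)
  for (l in seq_len(n_lv)) {
    jj <- which(lv_of == l)
    rbar <- if (length(jj) > 1) mean(abs(R[jj, jj][upper.tri(R[jj, jj])]))
            else 0.5
    lam0 <- sqrt(min(max(rbar, 0.05), 0.9))
    sgn <- sign(R[jj, jj[1]]); sgn[sgn == 0] <- 1
    start[jj] <- lam0 * sgn
  }
  if (free_psi) {
    jj1 <- which(lv_of == 1); jj2 <- which(lv_of == 2)
    start[i_psi] <- max(min(mean(R[jj1, jj2]) /
                              max(start[jj1[1]] * start[jj2[1]], 0.05),
                            0.9), -0.9)
  }
  if (has_d) {
    start[i_beta] <- 0.3
    start[i_tau] <- mcor$tau
  }
  lower <- rep(-0.995, n_par); upper <- rep(0.995, n_par)
  if (has_d) {
    lower[i_beta] <- -3; upper[i_beta] <- 3
    lower[i_tau] <- -3; upper[i_tau] <- 3
  }

  jitter_scale <- c(0, 0.15, -0.15, 0.3, -0.3, 0.5, -0.5)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    js <- jitter_scale[((r - 1L) %% length(jitter_scale)) + 1L]
    th0 <- pmin(pmax(start + js * cos(seq_len(n_par) * r), lower), upper)
    if (r == 1L) th0 <- start
    fit <- tryCatch(
      nlminb(th0, objective, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000,
                            rel.tol = 1e-12, abs.tol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$objective < best$objective - 1e-12))
      best <- fit
  }
  if (is.null(best))
    stop_mcibiome("mcibiome_nonconvergence_error",
                  "DWLS optimization failed in every restart")
  th <- best$par
  # sign convention: first indicator of each latent loads non-negatively
  for (l in seq_len(n_lv)) {
    jj <- which(lv_of == l)
    if (th[jj[1]] < 0) {
      th[jj] <- -th[jj]
      if (free_psi) th[i_psi] <- -th[i_psi]
      if (has_d) th[i_beta][l] <- -th[i_beta][l]
    }
  }
  F_min <- objective(th)
  F_baseline <- sum(w * s^2)
  df <- m_moments - n_par
  chi2 <- (n - 1) * F_min
  gfi <- 1 - F_min / F_baseline
  agfi <- if (df > 0) 1 - (1 - gfi) * m_moments / df else NA_real_
  rmsea <- if (df > 0) sqrt(max((chi2 - df) / (df * (n - 1)), 0))
           else NA_real_

  lam <- setNames(th[i_lam], ind)
  structure(list(
    spec = spec,
    loadings = lam,
    residual_variances = setNames(1 - lam^2, ind),
    latent_correlation = if (free_psi) th[i_psi] else NULL,
    path_coefficients = if (has_d) setNames(th[i_beta], names(spec$lv))
                        else NULL,
    threshold = if (has_d) th[i_tau] else NULL,
    F_min = F_min, chi2 = chi2, df = df, n_moments = m_moments,
    gfi = gfi, agfi = agfi, rmsea = rmsea,
    n = n, converged = best$convergence == 0,
    lv_of = setNames(names(spec$lv)[lv_of], ind)
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("DWLS latent-variable model fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  chi2 = %.3f on df = %d; GFI = %.3f, AGFI = %s, RMSEA = %s\n",
              x$chi2, x$df, x$gfi,
              if (is.na(x$agfi)) "NA" else sprintf("%.3f", x$agfi),
              if (is.na(x$rmsea)) "NA" else sprintf("%.3f", x$rmsea)))
  cat("  Standardized loadings:\n")
  print(round(x$loadings, digits))
  if (!is.null(x$latent_correlation))
    cat(sprintf("  lv1~~lv2 = %.3f\n", x$latent_correlation))
  if (!is.null(x$path_coefficients)) {
    cat("  Disease paths:",
        paste(sprintf("%s = %.3f", names(x$path_coefficients),
                      x$path_coefficients), collapse = ", "),
        sprintf("(threshold %.3f)\n", x$threshold))
  }
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) {
  c(object$loadings,
    if (!is.null(object$latent_correlation))
      c(psi_lv1_lv2 = object$latent_correlation),
    if (!is.null(object$path_coefficients))
      setNames(object$path_coefficients,
               paste0("path_", names(object$path_coefficients))),
    if (!is.null(object$threshold)) c(threshold = object$threshold))
}

#' @export
summary.sem_fit <- function(object, ...) {
  out <- list(
    loadings = data.frame(indicator = names(object$loadings),
                          latent = object$lv_of,
                          loading = unname(object$loadings),
                          residual_variance =
                            unname(object$residual_variances),
                          row.names = NULL),
    fit_indices = c(chi2 = object$chi2, df = object$df, gfi = object$gfi,
                    agfi = object$agfi, rmsea = object$rmsea),
    latent_correlation = object$latent_correlation,
    path_coefficients = object$path_coefficients)
  class(out) <- "summary.sem_fit"
  out
}

#' @export
print.summary.sem_fit <- function(x, ...) {
  print(x$loadings)
  cat("\nFit indices:\n"); print(round(x$fit_indices, 4))
  invisible(x)
}

fit_meets_targets <- function(fit, targets) {
  ok <- function(v) !is.null(v) && !is.na(v)
  ok(fit$gfi) && ok(fit$agfi) && ok(fit$rmsea) &&
    fit$gfi >= targets$gfi_min && fit$agfi >= targets$agfi_min &&
    fit$rmsea <= targets$rmsea_max
}

#' Default fit-index targets for indicator pruning
#'
#' GFI >= 0.94, AGFI >= 0.89, RMSEA <= 0.01 — the weaker of the two
#' published final models, overridable.
#' @export
default_fit_targets <- function() {
  list(gfi_min = 0.94, agfi_min = 0.89, rmsea_max = 0.01)
}

#' Greedy indicator pruning against fit-index targets
#'
#' Starting from a (possibly badly fitting) specification, repeatedly refits
#' the model with each currently removable indicator dropped in turn and
#' permanently removes the one whose refit maximizes the composite
#' `GFI + AGFI - RMSEA` (ties broken by indicator order), until the targets
#' are met or no indicator can be removed without a latent falling below
#' `min_per_lv`. Deterministic given the data; the full trajectory is
#' returned as a pruning log.
#'
#' @param spec starting [`sem_spec`][build_sem_spec].
#' @param mcor a [mixed_correlations()] object covering all indicators.
#' @param targets list with `gfi_min`, `agfi_min`, `rmsea_max`
#'   (see [default_fit_targets()]).
#' @param min_per_lv minimum indicators per latent (default 3).
#' @param n_restarts optimizer restarts per refit.
#' @return list with `spec` (pruned), `fit` (its `sem_fit`), `log`
#'   (data.frame: step, dropped, gfi, agfi, rmsea) and `met_targets`.
#'   If the targets are unreachable an error of class
#'   `mcibiome_pruning_error` is raised carrying the trajectory in
#'   `$trajectory`.
#' @export
prune_indicators <- function(spec, mcor, targets = default_fit_targets(),
                             min_per_lv = 3L, n_restarts = 5L) {
  fit <- fit_dwls(spec, mcor, n_restarts = n_restarts)
  log <- data.frame(step = integer(0), dropped = character(0),
                    gfi = numeric(0), agfi = numeric(0), rmsea = numeric(0),
                    stringsAsFactors = FALSE)
  step <- 0L
  while (!fit_meets_targets(fit, targets)) {
    removable <- unlist(lapply(names(spec$lv), function(l)
      if (length(spec$lv[[l]]) > min_per_lv) spec$lv[[l]] else character(0)))
    if (length(removable) == 0)
      stop_mcibiome("mcibiome_pruning_error",
                    "fit targets unreachable at the minimum indicator count",
                    trajectory = log, best_spec = spec, best_fit = fit)
    score <- -Inf; best_drop <- NULL; best_fit <- NULL
    for (cand in removable) {
      lv_try <- lapply(spec$lv, function(v) setdiff(v, cand))
      spec_try <- new_sem_spec(lv_try, disease = spec$disease,
                               correlated_latents = spec$correlated_latents)
      fit_try <- tryCatch(fit_dwls(spec_try, mcor, n_restarts = n_restarts),
                          error = function(e) NULL)
      if (is.null(fit_try)) next
      sc <- fit_try$gfi + ifelse(is.na(fit_try$agfi), 0, fit_try$agfi) -
        ifelse(is.na(fit_try$rmsea), 1, fit_try$rmsea)
      if (sc > score + 1e-12) {
        score <- sc; best_drop <- cand; best_fit <- fit_try
      }
    }
    if (is.null(best_drop))
      stop_mcibiome("mcibiome_pruning_error",
                    "no candidate refit converged during pruning",
                    trajectory = log, best_spec = spec, best_fit = fit)
    step <- step + 1L
    spec <- new_sem_spec(lapply(spec$lv, function(v) setdiff(v, best_drop)),
                         disease = spec$disease,
                         correlated_latents = spec$correlated_latents)
    fit <- best_fit
    log <- rbind(log, data.frame(step = step, dropped = best_drop,
                                 gfi = fit$gfi, agfi = fit$agfi,
                                 rmsea = fit$rmsea, stringsAsFactors = FALSE))
  }
  list(spec = spec, fit = fit, log = log, met_targets = TRUE)
}

#' Decide whether two latent variables should collapse into one
#'
#' Recommends `"collapse_to_one"` when the absolute fitted lv1-lv2
#' correlation is at or above `corr_threshold` (default 0.85) — the
#' situation where the two latents are nearly collinear, cause
#' multicollinearity in the downstream risk model, and a single latent
#' explains the disease as well. Ties at the threshold collapse.
#'
#' @param fit a two-latent `sem_fit`.
#' @param corr_threshold absolute-correlation cutoff.
#' @return `"keep_two"` or `"collapse_to_one"`.
#' @export
check_latent_collapse <- function(fit, corr_threshold = 0.85) {
  if (is.null(fit$latent_correlation))
    config_error("latent-collapse check needs a two-latent fit")
  if (abs(fit$latent_correlation) >= corr_threshold) "collapse_to_one"
  else "keep_two"
}

#' Empirical-Bayes (regression-method) factor scores
#'
#' Posterior-mean latent scores under the fitted normal measurement model:
#' for each standardized sample row `x`,
#' `score = Psi Lambda' (Lambda Psi Lambda' + Theta)^{-1} x`, with `Lambda`
#' the loading matrix, `Psi` the latent correlation matrix and `Theta` the
#' diagonal residual covariance.
#'
#' @param fit a converged `sem_fit` (typically of the measurement model).
#' @param x data matrix containing the fit's indicator columns.
#' @param standardize standardize columns (center/scale by their own
#'   mean/sd) before scoring; set to `FALSE` when `x` is already on the
#'   standardized scale of the fit.
#' @return samples x latents score matrix.
#' @export
factor_scores <- function(fit, x, standardize = TRUE) {
  stopifnot(inherits(fit, "sem_fit"))
  ind <- names(fit$loadings)
  x <- as.matrix(x)[, ind, drop = FALSE]
  if (standardize) x <- scale(x)
  n_lv <- length(fit$spec$lv)
  lv_idx <- match(fit$lv_of, names(fit$spec$lv))
  L <- matrix(0, length(ind), n_lv,
              dimnames = list(ind, names(fit$spec$lv)))
  L[cbind(seq_along(ind), lv_idx)] <- fit$loadings
  Psi <- diag(1, n_lv)
  if (!is.null(fit$latent_correlation))
    Psi[1, 2] <- Psi[2, 1] <- fit$latent_correlation
  Theta <- pmax(fit$residual_variances, 0)
  Sigma <- L %*% Psi %*% t(L) + diag(Theta, nrow = length(ind))
  if (rcond(Sigma) < 1e-12) {
    Sigma <- Sigma + diag(1e-8, nrow(Sigma))
    if (rcond(Sigma) < 1e-12)
      stop_mcibiome("mcibiome_numerical_error", sprintf(
        "implied covariance is numerically singular (rcond %.2e)",
        rcond(Sigma)))
  }
  A <- Psi %*% t(L) %*% solve(Sigma)     # n_lv x p
  scores <- x %*% t(A)
  colnames(scores) <- names(fit$spec$lv)
  scores
}

#' @export
predict.sem_fit <- function(object, newdata, standardize = TRUE, ...) {
  factor_scores(object, newdata, standardize = standardize)
}
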