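#' SMOTE synthetic minority oversampling
#'
#' Each synthetic point is `x + u * (nn - x)` with `u ~ Uniform(0, 1)` and
#' `nn` a randomly chosen one of `x`'s `k` nearest minority neighbours
#' (Euclidean). Base points are cycled through the minority set. Intended to
#' be applied inside each training fold only; the provenance attribute
#' records which minority rows each synthetic point was derived from.
#'
#' @param x minority-class matrix (points x features), >= 2 rows.
#' @param n_new number of synthetic points to generate.
#' @param k neighbourhood size (default 5, capped at `nrow(x) - 1`).
#' @param seed integer seed.
#' @return matrix of `n_new` synthetic points with attribute `provenance`
#'   (two-column matrix of source row indices).
#' @export
smote <- function(x, n_new, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 2) stop_mcibiome("mcibiome_resampling_error",
                           "SMOTE needs at least 2 minority samples")
  if (n_new <= 0)
    return(structure(x[0, , drop = FALSE],
                     provenance = matrix(integer(0), 0, 2)))
  k <- min(k, m - 1L)
  set.seed(seed)
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  nn_idx <- t(matrix(apply(D, 1, function(r) order(r)[seq_len(k)]),
                     nrow = k))
  base <- ((seq_len(n_new) - 1L) %% m) + 1L
  nb <- vapply(base, function(i) nn_idx[i, sample.int(k, 1L)], integer(1))
  u <- runif(n_new)
  out <- x[base, , drop = FALSE] + u * (x[nb, , drop = FALSE] -
                                          x[base, , drop = FALSE])
  rownames(out) <- paste0("smote_", seq_len(n_new))
  attr(out, "provenance") <- cbind(base = base, neighbour = nb)
  out
}

#' Empirical ROC curve and AUC
#'
#' ROC over all score thresholds; the trapezoid AUC, which equals the
#' tie-corrected normalized Mann-Whitney statistic of the scores.
#'
#' @param prob predicted probabilities (or any monotone risk score).
#' @param outcome binary outcome (1/"case" = positive).
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(prob, outcome) {
  y <- disease_to_binary(outcome)
  if (length(unique(y)) < 2) data_error("both outcome classes required")
  ord <- order(prob, decreasing = TRUE)
  y <- y[ord]; pr <- prob[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  # step through distinct thresholds
  keep <- c(which(diff(pr) != 0), length(pr))
  tpr <- c(0, cumsum(y == 1)[keep] / P)
  fpr <- c(0, cumsum(y == 0)[keep] / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, pr[keep]), tpr = tpr, fpr = fpr,
                 auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' SMOTE-balanced cross-validated logistic risk model
#'
#' The risk-estimation stage: maximum-likelihood logistic regression of the
#' binary outcome on the latent factor scores, evaluated by stratified
#' `n_folds`-fold cross-validation with SMOTE balancing of the minority
#' class applied inside each training fold only (never using test-fold
#' samples). The final reported model is refit on the SMOTE-balanced full
#' data. Both the pooled out-of-fold AUC and the apparent (resubstitution)
#' AUC are reported, labelled.
#'
#' @param scores samples x latents matrix of factor scores (explanatory
#'   variables).
#' @param outcome binary outcome (1/"case" = positive).
#' @param n_folds number of CV folds (default 10; reduced with a warning if
#'   a class cannot reach every fold's training set).
#' @param k SMOTE neighbourhood size (default 5).
#' @param seed integer seed controlling folds and SMOTE.
#' @return object of class `mci_risk_model`.
#' @export
fit_risk_cv <- function(scores, outcome, n_folds = 10L, k = 5L, seed = 1L) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("lv", seq_len(ncol(scores)))
  y <- disease_to_binary(outcome)
  if (length(unique(y)) < 2) data_error("both outcome classes required")
  n <- length(y)
  set.seed(seed)
  # stratified fold assignment
  folds <- integer(n)
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  # every training set must contain both classes
  while (n_folds > 2 && any(vapply(seq_len(n_folds), function(f)
    length(unique(y[folds != f])) < 2, logical(1)))) {
    warning("merging folds so each training set keeps both classes")
    n_folds <- n_folds - 1L
    folds[folds > n_folds] <- n_folds
  }

  balance <- function(X, yy, seed_off) {
    tab <- table(yy)
    if (length(tab) < 2 || tab[1] == tab[2]) return(list(X = X, y = yy))
    min_cls <- as.integer(names(which.min(tab)))
    n_new <- max(tab) - min(tab)
    Xm <- X[yy == min_cls, , drop = FALSE]
    syn <- smote(Xm, n_new, k = k, seed = seed + seed_off)
    list(X = rbind(X, syn), y = c(yy, rep(min_cls, nrow(syn))))
  }
  fit_glm <- function(X, yy) {
    df <- data.frame(y = yy, X, check.names = FALSE)
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ ., data = df, family = binomial(), control =
            list(maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    attr(fit, "separation") <- sep
    fit
  }

  oof <- rep(NA_real_, n)
  separation <- FALSE
  fold_ids <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    if (!length(test)) next
    train <- setdiff(seq_len(n), test)
    bal <- balance(scores[train, , drop = FALSE], y[train], seed_off = f)
    fit <- fit_glm(bal$X, bal$y)
    separation <- separation || attr(fit, "separation")
    oof[test] <- predict(fit, newdata = data.frame(
      scores[test, , drop = FALSE], check.names = FALSE), type = "response")
    fold_ids[[f]] <- test
  }
  bal_all <- balance(scores, y, seed_off = 0L)
  final <- fit_glm(bal_all$X, bal_all$y)
  separation <- separation || attr(final, "separation")
  apparent <- predict(final, newdata = data.frame(scores,
                                                  check.names = FALSE),
                      type = "response")
  structure(list(
    coefficients = coef(final),
    folds = fold_ids, n_folds = n_folds, seed = seed,
    outcome = y, oof_prob = oof, apparent_prob = apparent,
    roc_oof = roc_auc(oof, y), roc_apparent = roc_auc(apparent, y),
    auc_oof = roc_auc(oof, y)$auc, auc_apparent = roc_auc(apparent, y)$auc,
    separation = separation, model = final
  ), class = "mci_risk_model")
}

#' @export
print.mci_risk_model <- function(x, ...) {
  cat("SMOTE-balanced logistic risk model (", x$n_folds, "-fold CV)\n",
      sep = "")
  cat("  coefficients (log-odds):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  AUC: out-of-fold = %.3f, apparent = %.3f%s\n",
              x$auc_oof, x$auc_apparent,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' @export
coef.mci_risk_model <- function(object, ...) object$coefficients

#' @export
predict.mci_risk_model <- function(object, newdata, ...) {
  predict(object$model, newdata = data.frame(as.matrix(newdata),
                                             check.names = FALSE),
          type = "response")
}

#' @export
summary.mci_risk_model <- function(object, ...) {
  per_fold <- vapply(object$folds, function(idx) {
    if (length(unique(object$outcome[idx])) < 2) return(NA_real_)
    roc_auc(object$oof_prob[idx], object$outcome[idx])$auc
  }, numeric(1))
  out <- list(coefficients = object$coefficients, per_fold_auc = per_fold,
              auc_oof = object$auc_oof, auc_apparent = object$auc_apparent,
              separation = object$separation)
  class(out) <- "summary.mci_risk_model"
  out
}

#' @export
print.summary.mci_risk_model <- function(x, ...) {
  print(round(x$coefficients, 4))
  cat(sprintf("pooled out-of-fold AUC %.3f; apparent AUC %.3f\n",
              x$auc_oof, x$auc_apparent))
  cat("per-fold AUC:", paste(round(x$per_fold_auc, 3), collapse = " "), "\n")
  invisible(x)
}
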