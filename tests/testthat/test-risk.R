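test_that("SMOTE points lie on segments between minority neighbours", {
  x <- rbind(c(0, 0), c(1, 1))
  syn <- smote(x, n_new = 50, k = 1, seed = 3)
  expect_equal(nrow(syn), 50)
  # on the segment: both coordinates equal and within [0, 1]
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)
  expect_true(all(syn >= 0 & syn <= 1))
  # no synthetic points requested when already at target
  none <- smote(x, n_new = 0)
  expect_equal(nrow(none), 0)
  expect_error(smote(rbind(c(0, 0)), 5),
               class = "mcibiome_resampling_error")
})

test_that("SMOTE points are convex combinations of their recorded parents", {
  set.seed(10)
  x <- matrix(rnorm(30), 10, 3)
  syn <- smote(x, n_new = 100, k = 4, seed = 8)
  prov <- attr(syn, "provenance")
  for (i in seq_len(nrow(syn))) {
    a <- x[prov[i, 1], ]; b <- x[prov[i, 2], ]
    seg <- b - a
    t_hat <- if (sum(seg^2) > 0) sum((syn[i, ] - a) * seg) / sum(seg^2) else 0
    expect_true(t_hat >= -1e-9 && t_hat <= 1 + 1e-9)
    expect_lt(max(abs(syn[i, ] - (a + t_hat * seg))), 1e-9)
  }
})

test_that("trapezoid AUC equals the brute-force Mann-Whitney count", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c(0, 1), 3))$auc, 0.5)
  set.seed(20)
  for (rep in 1:5) {
    prob <- sample(round(runif(20), 2))   # ties included
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    pos <- prob[y == 1]; neg <- prob[y == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(prob, y)$auc, brute, tolerance = 1e-12)
  }
  # curve is monotone non-decreasing
  r2 <- roc_auc(runif(30), rbinom(30, 1, 0.4))
  expect_true(all(diff(r2$tpr) >= 0))
  expect_true(all(diff(r2$fpr) >= 0))
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "mcibiome_data_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  prob <- runif(30); y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  a1 <- roc_auc(prob, y)$auc
  expect_equal(roc_auc(qlogis(prob), y)$auc, a1)
  expect_equal(roc_auc(prob^3, y)$auc, a1)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  prob <- runif(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE)))
  expect_equal(roc_auc(prob, y)$auc, ref, tolerance = 1e-12)
})

test_that("cross-validated risk fit is deterministic and separable data gives AUC 1", {
  set.seed(23)
  scores <- matrix(c(rnorm(20, 3), rnorm(20, -3)), ncol = 1,
                   dimnames = list(NULL, "lv1"))
  y <- rep(c(1, 0), each = 20)
  fit <- fit_risk_cv(scores, y, seed = 5)
  expect_equal(fit$auc_oof, 1)
  expect_true(fit$separation)   # complete separation flagged, not fatal
  fit2 <- fit_risk_cv(scores, y, seed = 5)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$folds, fit2$folds)
  # folds partition the samples and are stratified
  all_idx <- sort(unlist(fit$folds))
  expect_equal(all_idx, 1:40)
  # predictions from the final model are probabilities
  pr <- predict(fit, scores)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("SMOTE balancing happens inside training folds only", {
  set.seed(24)
  scores <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "lv1"))
  y <- rep(c(1, 0), c(8, 22))
  fit <- fit_risk_cv(scores, y, n_folds = 5, seed = 2)
  # out-of-fold predictions exist for every sample exactly once
  expect_true(all(is.finite(fit$oof_prob)))
  expect_equal(sort(unlist(fit$folds)), 1:30)
  # per-fold summaries are computable
  s <- summary(fit)
  expect_length(s$per_fold_auc, fit$n_folds)
})
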