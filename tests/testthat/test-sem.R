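test_that("spec building follows the more->lv1 / less->lv2 assignment", {
  eff <- data.frame(
    taxon = paste0("t", 1:14),
    effect = c(rep(0.5, 8), rep(-0.5, 3), 0.05, -0.1, 0),
    stringsAsFactors = FALSE)
  eff <- classify_effects(eff)
  spec <- build_sem_spec(eff, mode = "two_lv")
  expect_equal(length(spec$lv$lv1), 8)
  expect_equal(length(spec$lv$lv2), 3)
  expect_equal(spec$disease, "disease_flg")
  one <- build_sem_spec(eff, mode = "one_lv")
  expect_null(one$lv$lv2)
  # identification guard
  eff2 <- classify_effects(data.frame(taxon = c("a", "b", "c"),
                                      effect = c(0.5, 0.5, -0.5)))
  expect_error(build_sem_spec(eff2, mode = "two_lv"),
               class = "mcibiome_spec_error")
  # a taxon cannot indicate two latents; disease cannot be an indicator
  expect_error(mcibiome:::new_sem_spec(list(lv1 = c("a", "b", "c"),
                                            lv2 = c("c", "d", "e"))),
               class = "mcibiome_spec_error")
  expect_error(mcibiome:::new_sem_spec(list(lv1 = c("a", "disease_flg", "b")),
                                       disease = "disease_flg"),
               class = "mcibiome_spec_error")
})

test_that("measurement extraction drops the disease node and is idempotent", {
  spec <- mcibiome:::new_sem_spec(list(lv1 = c("a", "b", "c"),
                                       lv2 = c("d", "e", "f")),
                                  disease = "disease_flg")
  m <- measurement_model(spec)
  expect_null(m$disease)
  expect_equal(m$lv, spec$lv)
  expect_true(m$correlated_latents)
  expect_equal(measurement_model(m), m)
})

test_that("mixed correlations recover a planted polyserial correlation", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  latent <- 0.5 * x + sqrt(0.75) * rnorm(n)
  d <- as.integer(latent > qnorm(0.6))      # 40% cases
  X <- cbind(a = x, b = rnorm(n))
  mc <- mixed_correlations(X, d)
  expect_equal(unname(mc$cor_xd["a"]), 0.5, tolerance = 0.05)
  expect_lt(abs(mc$cor_xd["b"]), 0.1)
  expect_equal(mc$tau, qnorm(1 - mean(d)))
  # 50/50 split puts the threshold at zero
  mc2 <- mixed_correlations(X, rep(c(0L, 1L), n / 2))
  expect_equal(mc2$tau, 0)
  # a constant column is named in the error
  Xc <- cbind(X, flat = 1)
  expect_error(mixed_correlations(Xc, d), "flat",
               class = "mcibiome_degenerate_error")
})

test_that("DWLS recovers a population one-factor model exactly", {
  R <- one_factor_popcorr(6, 0.8)
  fit <- fit_dwls(cfa_spec(colnames(R)), as_mixed_corr(R, n = 5000))
  expect_lt(max(abs(fit$loadings - 0.8)), 1e-4)
  expect_lt(fit$F_min, 1e-10)
  expect_gt(fit$gfi, 0.99)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$df, 6 * 5 / 2 - 6)
  expect_equal(unname(fit$residual_variances),
               1 - unname(fit$loadings)^2)
})

test_that("fit indices follow their formulas at the boundaries", {
  R <- one_factor_popcorr(6, 0.8)
  fit <- fit_dwls(cfa_spec(colnames(R)), as_mixed_corr(R, n = 500))
  # rmsea = 0 iff chi2 <= df
  expect_true(fit$chi2 <= fit$df)
  expect_equal(fit$rmsea, 0)
  # degrade the fit: two-factor truth forced into one factor
  R2 <- R
  R2[4:6, 1:3] <- R2[1:3, 4:6] <- 0.05
  fit2 <- fit_dwls(cfa_spec(colnames(R)), as_mixed_corr(R2, n = 500))
  expect_gt(fit2$chi2, fit2$df)
  expect_equal(fit2$rmsea,
               sqrt((fit2$chi2 - fit2$df) / (fit2$df * (500 - 1))),
               tolerance = 1e-12)
  expect_equal(fit2$agfi,
               1 - (1 - fit2$gfi) * fit2$n_moments / fit2$df,
               tolerance = 1e-12)
  expect_lt(fit2$gfi, fit$gfi)
})

test_that("the latent sign convention makes the first loading non-negative", {
  dat <- one_factor_data(300, 5, loading = 0.7, seed = 8)
  x <- dat$x
  x[, 1] <- -x[, 1]   # would pull the first loading negative
  fit <- fit_dwls(cfa_spec(colnames(x)), mixed_correlations(x))
  expect_gte(fit$loadings[1], 0)
  expect_true(all(fit$loadings[-1] < 0))
})

test_that("disease paths and thresholds are recovered from sampled data", {
  set.seed(77)
  n <- 3000
  z <- rnorm(n)
  X <- sapply(1:5, function(j) 0.75 * z + sqrt(1 - 0.75^2) * rnorm(n))
  colnames(X) <- paste0("t", 1:5)
  ystar <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  d <- as.integer(ystar > 0.25)
  fit <- fit_dwls(cfa_spec(colnames(X), disease = "disease_flg"),
                  mixed_correlations(X, d))
  expect_lt(max(abs(fit$loadings - 0.75)), 0.05)
  expect_lt(abs(fit$path_coefficients["lv1"] - 0.6), 0.07)
  expect_lt(abs(fit$threshold - 0.25), 0.07)
  expect_gt(fit$gfi, 0.95)
})

test_that("latent collapse triggers at and above the threshold", {
  fit <- structure(list(latent_correlation = 0.95), class = "sem_fit")
  expect_equal(check_latent_collapse(fit, 0.85), "collapse_to_one")
  fit$latent_correlation <- 0.3
  expect_equal(check_latent_collapse(fit, 0.85), "keep_two")
  fit$latent_correlation <- 0.85
  expect_equal(check_latent_collapse(fit, 0.85), "collapse_to_one")
  fit$latent_correlation <- -0.9
  expect_equal(check_latent_collapse(fit, 0.85), "collapse_to_one")
  expect_error(check_latent_collapse(structure(list(), class = "sem_fit")),
               class = "mcibiome_config_error")
})

test_that("pruning returns an unchanged spec when targets are already met", {
  R <- one_factor_popcorr(5, 0.8)
  res <- prune_indicators(cfa_spec(colnames(R)), as_mixed_corr(R, 1000))
  expect_equal(res$spec$lv$lv1, colnames(R))
  expect_equal(nrow(res$log), 0)
  expect_true(res$met_targets)
})

test_that("pruning fails with a trajectory when targets are unreachable", {
  set.seed(99)
  noise <- matrix(rnorm(200 * 3), 200, 3,
                  dimnames = list(NULL, c("n1", "n2", "n3")))
  mc <- mixed_correlations(noise)
  expect_error(prune_indicators(cfa_spec(colnames(noise)), mc,
                                targets = list(gfi_min = 0.9999,
                                               agfi_min = 0.9999,
                                               rmsea_max = 0)),
               class = "mcibiome_pruning_error")
  err <- tryCatch(prune_indicators(cfa_spec(colnames(noise)), mc,
                                   targets = list(gfi_min = 0.9999,
                                                  agfi_min = 0.9999,
                                                  rmsea_max = 0)),
                  mcibiome_pruning_error = function(e) e)
  expect_s3_class(err$trajectory, "data.frame")
  expect_s3_class(err$best_fit, "sem_fit")
})

test_that("factor scores obey the identity limit, linearity, and recovery", {
  # single indicator with loading 1, residual 0: score = the value itself
  fit1 <- structure(list(
    spec = mcibiome:::new_sem_spec(list(lv1 = "a")),
    loadings = c(a = 1), residual_variances = c(a = 0),
    latent_correlation = NULL, lv_of = c(a = "lv1")), class = "sem_fit")
  x <- matrix(c(-1.3, 0, 2.1), 3, 1, dimnames = list(NULL, "a"))
  sc <- factor_scores(fit1, x, standardize = FALSE)
  expect_equal(as.numeric(sc), as.numeric(x), tolerance = 1e-9)
  # all-zero row scores zero (linearity)
  dat <- one_factor_data(200, 8, loading = 0.8, seed = 14)
  fit <- fit_dwls(cfa_spec(colnames(dat$x)), mixed_correlations(dat$x))
  z0 <- rbind(rep(0, 8))
  colnames(z0) <- colnames(dat$x)
  expect_equal(as.numeric(factor_scores(fit, z0, standardize = FALSE)), 0)
  # recovery of the generating latent
  sc2 <- factor_scores(fit, dat$x)
  expect_gt(cor(sc2[, 1], dat$z), 0.9)
  # predict method is the same computation
  expect_equal(predict(fit, dat$x), sc2)
})
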