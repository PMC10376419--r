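#' Fit the full sex-stratified microbiota MCI risk analysis
#'
#' The end-to-end analysis on a genus-level count table and sample
#' metadata, run independently per stratum (mixed-sex, male, female):
#' \enumerate{
#'   \item cohort summary table (group n, sex chi-square, age/BMI and
#'     alpha-diversity Wilcoxon comparisons);
#'   \item beta diversity: Bray-Curtis distances, PERMANOVA (9999
#'     permutations by default) and NMDS ordination with stress;
#'   \item Dirichlet Monte-Carlo CLR ensemble and ALDEx2-style effect sizes
#'     with BH correction; taxa classified more/less abundant at
#'     `effect_threshold`;
#'   \item latent-variable model: more-abundant taxa indicate lv1,
#'     less-abundant lv2, both regressing on the disease flag; fit by DWLS,
#'     indicators pruned against GFI/AGFI/RMSEA targets; if the two latents
#'     correlate at or above `collapse_threshold`, the model collapses to a
#'     single lv1-only latent (the male branch of the published analysis);
#'   \item the measurement part is refit disease-blinded and empirical-Bayes
#'     factor scores are computed;
#'   \item SMOTE-balanced 10-fold cross-validated logistic regression of
#'     disease on the factor scores, with out-of-fold and apparent ROC/AUC.
#' }
#'
#' When the classification yields fewer than 3 usable indicators for a
#' required latent, the pipeline falls back to the top-ranked taxa by signed
#' effect so the downstream stages remain runnable (recorded in the stratum
#' log); [build_sem_spec()] itself is strict.
#'
#' @param counts samples x genera count matrix (see [read_count_table()]).
#' @param metadata sample metadata aligned or alignable with `counts`
#'   (see [read_sample_metadata()] and [align_samples()]).
#' @param strata `"all"` (mixed + male + female) or a subset of
#'   `c("mixed", "male", "female")`.
#' @param effect_threshold effect-size classification cutoff (default 0.2).
#' @param clr_instances Monte-Carlo instances for the CLR ensemble.
#' @param clr_prior Dirichlet pseudo-count.
#' @param clr_mode matrix handed to the latent-variable stage:
#'   `"mc-mean"` (ensemble mean, default), `"point"` (deterministic CLR) or
#'   `"single-instance"` (first MC instance).
#' @param sem_mode `"auto"` (two-latent model with automatic collapse),
#'   `"two_lv"`, or `"one_lv"`.
#' @param prune prune indicators against `fit_targets` (default TRUE).
#' @param fit_targets list with `gfi_min`, `agfi_min`, `rmsea_max`.
#' @param on_prune_failure `"best"` keeps the best spec found when targets
#'   are unreachable (logged); `"halt"` raises the pruning error.
#' @param collapse_threshold latent-correlation cutoff for the one-latent
#'   fallback.
#' @param n_permutations PERMANOVA permutations (default 9999).
#' @param nmds_k NMDS embedding dimension (default 2).
#' @param n_folds cross-validation folds (default 10).
#' @param seed master seed; each stratum derives its own sub-seed.
#' @return object of class `mci_risk` with one result set per stratum.
#' @export
mci_risk <- function(counts, metadata, strata = "all",
                     effect_threshold = 0.2,
                     clr_instances = 128L, clr_prior = 0.5,
                     clr_mode = c("mc-mean", "point", "single-instance"),
                     sem_mode = c("auto", "two_lv", "one_lv"),
                     prune = TRUE, fit_targets = default_fit_targets(),
                     on_prune_failure = c("best", "halt"),
                     collapse_threshold = 0.85,
                     n_permutations = 9999L, nmds_k = 2L,
                     n_folds = 10L, seed = 1L) {
  clr_mode <- match.arg(clr_mode)
  sem_mode <- match.arg(sem_mode)
  on_prune_failure <- match.arg(on_prune_failure)
  al <- align_samples(counts, metadata)
  counts <- al$counts; metadata <- al$metadata
  if (identical(strata, "all")) strata <- c("mixed", "male", "female")
  strata <- match.arg(strata, c("mixed", "male", "female"), several.ok = TRUE)
  opts <- list(effect_threshold = effect_threshold,
               clr_instances = as.integer(clr_instances),
               clr_prior = clr_prior, clr_mode = clr_mode,
               sem_mode = sem_mode, prune = prune,
               fit_targets = fit_targets,
               on_prune_failure = on_prune_failure,
               collapse_threshold = collapse_threshold,
               n_permutations = as.integer(n_permutations),
               nmds_k = as.integer(nmds_k), n_folds = as.integer(n_folds))
  res <- list()
  for (i in seq_along(strata)) {
    st <- strata[i]
    keep <- if (st == "mixed") rep(TRUE, nrow(metadata))
            else metadata$sex == st
    sub_seed <- (seed * 13L + i * 7919L) %% .Machine$integer.max
    res[[st]] <- run_stratum(counts[keep, , drop = FALSE],
                             metadata[keep, , drop = FALSE],
                             opts, seed = sub_seed, stratum = st)
  }
  structure(list(strata = res, options = opts, seed = seed,
                 call = match.call()),
            class = "mci_risk")
}

# one stratum of the analysis; every stage decision is appended to `log`
run_stratum <- function(counts, metadata, opts, seed, stratum = "mixed") {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  tab <- table(metadata$group)
  if (length(tab) < 2 || any(tab < 2))
    data_error(sprintf("stratum '%s': need >= 2 samples per group", stratum))
  y <- as.integer(metadata$group == "case")

  summary_tab <- cohort_summary(counts, metadata)
  d <- bray_curtis(counts)
  perma <- permanova(d, metadata$group,
                     n_permutations = opts$n_permutations, seed = seed)
  ord <- withCallingHandlers(
    nmds_ordination(d, k = opts$nmds_k, seed = seed),
    warning = function(w) {
      note("NMDS: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("PERMANOVA p = %.4g; NMDS stress = %.3f", perma$p_value, ord$stress)

  ens <- dirichlet_clr(counts, n_instances = opts$clr_instances,
                       prior = opts$clr_prior, seed = seed)
  effects <- classify_effects(
    aldex_effects(ens, metadata$group, seed = seed),
    threshold = opts$effect_threshold)
  note("%d taxa 'more', %d 'less' at |effect| > %.2f",
       sum(effects$class == "more"), sum(effects$class == "less"),
       opts$effect_threshold)

  clr_mat <- switch(opts$clr_mode,
                    "mc-mean" = ensemble_mean(ens),
                    "point" = clr_point_estimate(counts, opts$clr_prior),
                    "single-instance" = ens$instances[[1]])

  lv_sets <- lv_sets_with_fallback(effects, note)
  sem <- fit_sem_branch(lv_sets, clr_mat, y, opts, note)

  meas_spec <- measurement_model(sem$spec)
  ind <- unlist(meas_spec$lv, use.names = FALSE)
  mcor_blind <- mixed_correlations(clr_mat[, ind, drop = FALSE])
  meas_fit <- fit_dwls(meas_spec, mcor_blind)
  scores <- factor_scores(meas_fit, clr_mat)
  risk <- fit_risk_cv(scores, y, n_folds = opts$n_folds, seed = seed)
  note("risk model: out-of-fold AUC %.3f, apparent AUC %.3f",
       risk$auc_oof, risk$auc_apparent)

  list(stratum = stratum, n = unname(c(tab["case"], tab["control"])),
       summary = summary_tab, distances = d, permanova = perma,
       ordination = ord, effects = effects,
       sem = sem, measurement_fit = meas_fit,
       clr_center = colMeans(clr_mat[, ind, drop = FALSE]),
       clr_scale = apply(clr_mat[, ind, drop = FALSE], 2, sd),
       scores = scores, outcome = y, risk = risk,
       metadata = metadata, log = log)
}

# classification sets, rank-filled to >= 3 per needed class
lv_sets_with_fallback <- function(effects, note) {
  more <- effects$taxon[effects$class == "more"]
  less <- effects$taxon[effects$class == "less"]
  ord <- order(effects$effect, decreasing = TRUE)
  if (length(more) < 3) {
    more <- effects$taxon[head(ord, 3)]
    note("lv1: classification gave < 3 taxa; using top 3 by effect")
  }
  if (length(less) < 3) {
    less <- setdiff(effects$taxon[rev(ord)], more)[1:3]
    note("lv2: classification gave < 3 taxa; using bottom 3 by effect")
  }
  list(more = more, less = less)
}

fit_sem_branch <- function(lv_sets, clr_mat, y, opts, note) {
  prune_or_fit <- function(spec, mcor) {
    if (!opts$prune) {
      fit <- fit_dwls(spec, mcor)
      return(list(spec = spec, fit = fit, log = NULL,
                  met_targets = fit_meets_targets(fit, opts$fit_targets)))
    }
    tryCatch(
      prune_indicators(spec, mcor, targets = opts$fit_targets),
      mcibiome_pruning_error = function(e) {
        if (opts$on_prune_failure == "halt") stop(e)
        note("pruning: targets unreachable; keeping best spec found")
        list(spec = e$best_spec, fit = e$best_fit, log = e$trajectory,
             met_targets = FALSE)
      })
  }
  build <- function(mode) {
    lv <- list(lv1 = lv_sets$more)
    if (mode == "two_lv") lv$lv2 <- lv_sets$less
    new_sem_spec(lv, disease = "disease_flg")
  }
  run_mode <- function(mode) {
    spec <- build(mode)
    ind <- unlist(spec$lv, use.names = FALSE)
    mcor <- mixed_correlations(clr_mat[, ind, drop = FALSE], disease = y)
    c(prune_or_fit(spec, mcor), list(mode = mode))
  }
  mode <- if (opts$sem_mode == "auto") "two_lv" else opts$sem_mode
  out <- run_mode(mode)
  out$collapse <- "not_checked"
  if (opts$sem_mode == "auto" && mode == "two_lv") {
    out$collapse <- check_latent_collapse(out$fit, opts$collapse_threshold)
    note("latent correlation %.3f -> %s",
         out$fit$latent_correlation, out$collapse)
    if (out$collapse == "collapse_to_one") {
      two_lv <- out[c("spec", "fit", "log")]
      out <- run_mode("one_lv")
      out$collapse <- "collapse_to_one"
      out$two_lv_attempt <- two_lv
      note("refit as one-latent model (%d indicators)",
           length(out$spec$lv$lv1))
    }
  }
  out
}

#' @export
print.mci_risk <- function(x, ...) {
  cat("Sex-stratified microbiota MCI risk analysis (seed ", x$seed, ")\n",
      sep = "")
  for (st in names(x$strata)) {
    r <- x$strata[[st]]
    cat(sprintf(
      "  %-6s n = %d/%d | PERMANOVA p = %-7.4g | %d more, %d less | %s | AUC oof %.3f\n",
      st, r$n[1], r$n[2], r$permanova$p_value,
      sum(r$effects$class == "more"), sum(r$effects$class == "less"),
      r$sem$mode, r$risk$auc_oof))
  }
  invisible(x)
}

#' @export
summary.mci_risk <- function(object, ...) {
  rows <- lapply(object$strata, function(r) data.frame(
    stratum = r$stratum, n_case = r$n[1], n_control = r$n[2],
    permanova_p = r$permanova$p_value, nmds_stress = r$ordination$stress,
    n_more = sum(r$effects$class == "more"),
    n_less = sum(r$effects$class == "less"),
    sem_mode = r$sem$mode, sem_gfi = r$sem$fit$gfi,
    sem_agfi = r$sem$fit$agfi, sem_rmsea = r$sem$fit$rmsea,
    auc_oof = r$risk$auc_oof, auc_apparent = r$risk$auc_apparent,
    row.names = NULL))
  out <- do.call(rbind, rows)
  class(out) <- c("summary.mci_risk", "data.frame")
  out
}

#' @export
coef.mci_risk <- function(object, ...) {
  lapply(object$strata, function(r) r$risk$coefficients)
}

#' Predict MCI risk for new samples
#'
#' Applies a fitted stratum's disease-blinded measurement model and logistic
#' risk model to a new count table: deterministic CLR (same prior),
#' standardization by the training CLR location/scale, empirical-Bayes
#' factor scores, then the logistic model.
#'
#' @param object a fitted [mci_risk()] object.
#' @param newdata samples x genera count matrix with the training taxa.
#' @param stratum which stratum's model to apply (default the first).
#' @param ... unused.
#' @return named vector of predicted case probabilities.
#' @export
predict.mci_risk <- function(object, newdata,
                             stratum = names(object$strata)[1], ...) {
  r <- object$strata[[stratum]]
  if (is.null(r)) config_error(paste0("no fitted stratum '", stratum, "'"))
  clr <- clr_point_estimate(newdata, object$options$clr_prior)
  ind <- names(r$clr_center)
  z <- sweep(sweep(clr[, ind, drop = FALSE], 2, r$clr_center), 2,
             pmax(r$clr_scale, 1e-12), "/")
  sc <- factor_scores(r$measurement_fit, z, standardize = FALSE)
  predict(r$risk, sc)
}

#' @export
plot.mci_risk <- function(x, type = c("roc", "nmds"),
                          stratum = names(x$strata)[1], ...) {
  type <- match.arg(type)
  r <- x$strata[[stratum]]
  if (type == "roc") {
    roc <- r$risk$roc_oof
    plot(roc$fpr, roc$tpr, type = "l", lwd = 2,
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("%s: out-of-fold ROC (AUC = %.2f)", stratum,
                        roc$auc), ...)
    abline(0, 1, lty = 2, col = "grey")
  } else {
    co <- r$ordination$coordinates
    grp <- r$metadata$group
    plot(co[, 1], co[, 2], col = ifelse(grp == "case", "red", "blue"),
         pch = 19, xlab = "NMDS1", ylab = "NMDS2",
         main = sprintf("%s: NMDS (stress = %.2f, PERMANOVA p = %.3f)",
                        stratum, r$ordination$stress,
                        r$permanova$p_value), ...)
    # 95% normal confidence ellipses around each group centroid
    for (g in unique(grp)) {
      xy <- co[grp == g, , drop = FALSE]
      if (nrow(xy) > 2) {
        ctr <- colMeans(xy)
        ch <- chol(cov(xy) * qchisq(0.95, 2))
        th <- seq(0, 2 * pi, length.out = 120)
        ell <- cbind(cos(th), sin(th)) %*% ch
        lines(ell[, 1] + ctr[1], ell[, 2] + ctr[2],
              col = if (g == "case") "red" else "blue", lty = 2)
      }
    }
    legend("topright", legend = c("case", "control"), pch = 19,
           col = c("red", "blue"), bty = "n")
  }
  invisible(x)
}

#' Simulate a cohort and run the full analysis with truth diagnostics
#'
#' Generates a synthetic sexed cohort (or a single stratum), runs
#' [mci_risk()], and appends recovery diagnostics per sex: the fraction of
#' planted lv1/lv2 taxa whose effect sign matches the plant, the absolute
#' correlation between factor scores and the true latent score, and the
#' out-of-fold AUC with a no-signal flag when it is within 0.1 of chance.
#'
#' @param male_config,female_config [mci_sim_config()] objects.
#' @param null_labels permute group labels (null study) before analysis.
#' @param ... passed to [mci_risk()].
#' @return list of class `mci_simulation`: `fit` (the `mci_risk` object),
#'   `data`, `recovery` (data.frame per sex stratum).
#' @export
simulate_mci_study <- function(
    male_config = mci_sim_config(n_case = 11L, n_control = 17L, seed = 101L),
    female_config = mci_sim_config(n_case = 18L, n_control = 23L,
                                   seed = 202L),
    null_labels = FALSE, ...) {
  dat <- simulate_sexed_cohort(male_config, female_config)
  if (null_labels) {
    set.seed(male_config$seed + female_config$seed)
    for (sx in c("male", "female")) {
      idx <- which(dat$metadata$sex == sx)
      dat$metadata$group[idx] <- sample(dat$metadata$group[idx])
    }
  }
  fit <- mci_risk(dat$counts, dat$metadata[, c("sample_id", "sex", "group")],
                  ...)
  cfgs <- list(male = male_config, female = female_config)
  rec <- lapply(intersect(names(fit$strata), c("male", "female")),
                function(sx) {
    r <- fit$strata[[sx]]
    cfg <- cfgs[[sx]]
    taxa <- colnames(dat$counts)
    eff <- setNames(r$effects$effect, r$effects$taxon)
    sign_ok <- c(eff[taxa[cfg$lv1_taxa]] > 0, eff[taxa[cfg$lv2_taxa]] < 0)
    z_true <- dat$metadata$z_true[dat$metadata$sex == sx]
    score_cor <- abs(cor(r$scores[, 1], z_true))
    data.frame(stratum = sx,
               sign_agreement = mean(sign_ok),
               score_truth_cor = score_cor,
               auc_oof = r$risk$auc_oof,
               no_signal = abs(r$risk$auc_oof - 0.5) <= 0.1,
               row.names = NULL)
  })
  structure(list(fit = fit, data = dat, recovery = do.call(rbind, rec)),
            class = "mci_simulation")
}

#' @export
print.mci_simulation <- function(x, ...) {
  print(x$fit)
  cat("Recovery diagnostics:\n")
  print(x$recovery, row.names = FALSE)
  invisible(x)
}

#' Run the analysis from a YAML configuration file
#'
#' Config keys: `counts` and `metadata` (paths), `output_dir`, plus any
#' argument of [mci_risk()] (e.g. `strata`, `seed`, `effect_threshold`,
#' `sem_mode`). Writes the result bundle with [write_bundle()] when
#' `output_dir` is set.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @return the fitted `mci_risk` object, invisibly if a bundle was written.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("counts", "metadata"))
    if (is.null(cfg[[key]]))
      config_error(paste0("config lacks required key '", key, "'"))
  counts <- read_count_table(cfg$counts)
  metadata <- read_sample_metadata(cfg$metadata)
  args <- cfg[setdiff(names(cfg), c("counts", "metadata", "output_dir"))]
  args <- args[names(args) %in% names(formals(mci_risk))]
  fit <- do.call(mci_risk, c(list(counts = counts, metadata = metadata),
                             args))
  if (!is.null(cfg$output_dir)) {
    write_bundle(fit, cfg$output_dir)
    return(invisible(fit))
  }
  fit
}

#' Write the per-stratum result bundle to disk
#'
#' For each stratum: cohort summary TSV, effect table TSV, ordination
#' coordinates TSV, factor scores TSV, SEM fit + pruning log JSON, risk
#' model + ROC JSON; plus a run-metadata JSON (seed, options, package
#' version).
#'
#' @param fit an [mci_risk()] object.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_bundle <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (st in names(fit$strata)) {
    r <- fit$strata[[st]]
    pre <- file.path(dir, st)
    wt(r$summary, paste0(pre, "_summary.tsv"))
    wt(r$effects, paste0(pre, "_effects.tsv"))
    wt(data.frame(sample_id = rownames(r$ordination$coordinates) %||%
                    r$metadata$sample_id, r$ordination$coordinates,
                  stress = r$ordination$stress), paste0(pre, "_nmds.tsv"))
    wt(data.frame(sample_id = r$metadata$sample_id, r$scores,
                  check.names = FALSE), paste0(pre, "_scores.tsv"))
    sem_out <- list(
      mode = r$sem$mode, collapse = r$sem$collapse,
      spec = sem_spec_text(r$sem$spec),
      loadings = as.list(r$sem$fit$loadings),
      latent_correlation = r$sem$fit$latent_correlation,
      path_coefficients = as.list(r$sem$fit$path_coefficients %||% list()),
      chi2 = r$sem$fit$chi2, df = r$sem$fit$df, gfi = r$sem$fit$gfi,
      agfi = r$sem$fit$agfi, rmsea = r$sem$fit$rmsea,
      met_targets = r$sem$met_targets,
      pruning_log = r$sem$log, stage_log = r$log)
    p <- paste0(pre, "_sem.json"); write_results_json(sem_out, p)
    files <- c(files, p)
    risk_out <- list(
      coefficients = as.list(r$risk$coefficients),
      per_fold_auc = unname(summary(r$risk)$per_fold_auc),
      auc_oof = r$risk$auc_oof, auc_apparent = r$risk$auc_apparent,
      separation = r$risk$separation,
      permanova = list(pseudo_F = r$permanova$pseudo_F,
                       p_value = r$permanova$p_value),
      roc = list(fpr = r$risk$roc_oof$fpr, tpr = r$risk$roc_oof$tpr,
                 auc = r$risk$roc_oof$auc))
    p <- paste0(pre, "_risk.json"); write_results_json(risk_out, p)
    files <- c(files, p)
  }
  meta <- list(seed = fit$seed, options = fit$options,
               package_version = as.character(utils::packageVersion("mcibiome")),
               strata = names(fit$strata))
  p <- file.path(dir, "run_metadata.json")
  write_results_json(meta, p)
  files <- c(files, p)
  invisible(files)
}
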