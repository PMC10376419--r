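#' ALDEx2-style standardized effect sizes from a CLR ensemble
#'
#' For every taxon and every Monte-Carlo CLR instance:
#' \itemize{
#'   \item `diff_btw` = median(CLR in cases) - median(CLR in controls);
#'   \item `dispersion` = the larger of the two within-group median absolute
#'     differences, each computed between a sample and a randomly chosen
#'     other sample of the same group (one random pairing per instance);
#'   \item instance effect = `diff_btw / dispersion` (dispersion floored at
#'     machine epsilon).
#' }
#' The reported effect is the median over instances; `diff_btw` and
#' `dispersion` are likewise medians over instances. The per-taxon p-value is
#' the mean over instances of the two-sided Wilcoxon rank-sum p (normal
#' approximation with tie correction, no continuity correction), and `q_bh`
#' is its Benjamini-Hochberg adjustment across taxa.
#'
#' @param ens a [dirichlet_clr()] ensemble.
#' @param labels two-level group labels ("case"/"control"; the first level in
#'   `case_level` is the numerator group). Both groups need >= 2 samples.
#' @param case_level label treated as the case group (default `"case"`).
#' @param seed seed for the within-group random pairings.
#' @return data.frame of class `taxon_effects` with columns `taxon`,
#'   `effect`, `diff_btw`, `dispersion`, `p_wilcoxon`, `q_bh`, `class`
#'   (filled with "none"; see [classify_effects()]).
#' @export
aldex_effects <- function(ens, labels, case_level = "case", seed = 1L) {
  stopifnot(inherits(ens, "clr_ensemble"))
  labels <- as.character(labels)
  X1 <- ens$instances[[1]]
  if (length(labels) != nrow(X1))
    config_error("labels must have one entry per sample")
  is_case <- labels == case_level
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 < 2 || n0 < 2)
    data_error("both groups need at least 2 samples")
  p <- ncol(X1)
  K <- ens$n_instances
  set.seed(seed)
  eff <- dbt <- dsp <- pw <- matrix(NA_real_, K, p)
  idx_case <- which(is_case); idx_ctrl <- which(!is_case)
  for (k in seq_len(K)) {
    X <- ens$instances[[k]]
    med_case <- apply(X[idx_case, , drop = FALSE], 2, median)
    med_ctrl <- apply(X[idx_ctrl, , drop = FALSE], 2, median)
    diff_btw <- med_case - med_ctrl
    # within-group spread: |x_i - x_{pair(i)}| for one random pairing per
    # instance; partners are drawn in global sample order so the estimator
    # is exactly invariant to which group is called "case"
    partner <- vapply(seq_len(nrow(X)), function(i) {
      idx <- if (is_case[i]) idx_case else idx_ctrl
      idx[-match(i, idx)][sample.int(length(idx) - 1L, 1L)]
    }, integer(1))
    disp_case <- apply(abs(X[idx_case, , drop = FALSE] -
                             X[partner[idx_case], , drop = FALSE]), 2, median)
    disp_ctrl <- apply(abs(X[idx_ctrl, , drop = FALSE] -
                             X[partner[idx_ctrl], , drop = FALSE]), 2, median)
    disp <- pmax(pmax(disp_case, disp_ctrl), .Machine$double.eps)
    eff[k, ] <- diff_btw / disp
    dbt[k, ] <- diff_btw
    dsp[k, ] <- disp
    pw[k, ] <- wilcoxon_matrix(X, is_case)
  }
  out <- data.frame(
    taxon = colnames(X1) %||% paste0("taxon_", seq_len(p)),
    effect = apply(eff, 2, median),
    diff_btw = apply(dbt, 2, median),
    dispersion = apply(dsp, 2, median),
    p_wilcoxon = colMeans(pw),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$q_bh <- bh_adjust(out$p_wilcoxon)
  out$class <- "none"
  class(out) <- c("taxon_effects", "data.frame")
  out
}

# vectorized two-sided rank-sum p over matrix columns (normal approximation,
# tie-corrected, no continuity correction)
wilcoxon_matrix <- function(X, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case); n <- n1 + n0
  apply(X, 2, function(x) {
    r <- rank(x)
    W <- sum(r[is_case]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (W - n1 * n0 / 2) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' Classify taxa as more/less abundant by effect-size threshold
#'
#' Taxa with effect above `threshold` are classified `"more"` abundant in
#' cases, below `-threshold` `"less"`, otherwise `"none"`. The published
#' rule uses threshold 0.2.
#'
#' @param effects a `taxon_effects` data.frame.
#' @param threshold positive effect-size cutoff (default 0.2).
#' @return the same data.frame with `class` filled.
#' @export
classify_effects <- function(effects, threshold = 0.2) {
  if (threshold <= 0) config_error("threshold must be > 0")
  effects$class <- ifelse(effects$effect > threshold, "more",
                          ifelse(effects$effect < -threshold, "less", "none"))
  effects
}

#' Two-sided Wilcoxon rank-sum test without continuity correction
#'
#' Thin wrapper over [stats::wilcox.test()] matching `paired = FALSE,
#' correct = FALSE`: the normal approximation with tie correction and no
#' continuity correction. With `exact = TRUE` (allowed for n1 + n2 <= 10 and
#' no ties) the exact enumeration p-value is returned instead.
#'
#' @param x,y numeric samples.
#' @param exact use the exact distribution (small n, no ties).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = FALSE) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(
    wilcox.test(x, y, paired = FALSE, exact = exact, correct = FALSE)$p.value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]
#' (monotone, order-preserving).
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with Yates continuity correction by default (the base
#' R default for 2x2 tables), df = 1.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = TRUE) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0)) data_error("cell counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    data_error("zero margin in 2x2 table")
  ct <- suppressWarnings(chisq.test(m, correct = yates))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Cohort summary statistics (group comparison table)
#'
#' The standard case-control cohort table: per-group n, the sex-by-group
#' chi-square (Yates-corrected), and mean +/- SD with Wilcoxon rank-sum
#' p-values (no continuity correction) for age, BMI and the four
#' alpha-diversity indices.
#'
#' @param counts samples x taxa count matrix.
#' @param metadata aligned metadata (`sample_id`, `sex`, `group`, optional
#'   `age`, `bmi`).
#' @return data.frame of class `cohort_summary` with one row per variable.
#' @export
cohort_summary <- function(counts, metadata) {
  stopifnot(nrow(counts) == nrow(metadata))
  is_case <- metadata$group == "case"
  alpha <- alpha_diversity(counts)
  vars <- list(shannon = alpha$shannon, simpson = alpha$simpson,
               richness = as.numeric(alpha$richness), pielou = alpha$pielou)
  if (!is.null(metadata$age)) vars <- c(list(age = metadata$age), vars)
  if (!is.null(metadata$bmi)) vars <- c(list(bmi = metadata$bmi), vars)
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    data.frame(
      variable = v,
      case_mean = mean(x[is_case], na.rm = TRUE),
      case_sd = sd(x[is_case], na.rm = TRUE),
      control_mean = mean(x[!is_case], na.rm = TRUE),
      control_sd = sd(x[!is_case], na.rm = TRUE),
      p_value = wilcoxon_rank_sum(x[is_case], x[!is_case]),
      test = "wilcoxon", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(unique(metadata$sex)) == 2) {
    tab <- table(factor(metadata$sex, c("male", "female")),
                 factor(metadata$group, c("case", "control")))
    cs <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    out <- rbind(out, data.frame(
      variable = "sex_male_female", case_mean = tab[1, 1],
      case_sd = tab[2, 1], control_mean = tab[1, 2], control_sd = tab[2, 2],
      p_value = cs$p_value, test = "chi_square_yates",
      stringsAsFactors = FALSE))
  }
  attr(out, "n") <- c(case = sum(is_case), control = sum(!is_case))
  class(out) <- c("cohort_summary", "data.frame")
  out
}
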