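#' Build a latent-variable model specification from classified effects
#'
#' Implements the assignment rule of the risk-estimation method: every taxon
#' classified `"more"` abundant in cases becomes an indicator of latent
#' variable 1 (lv1), every `"less"` abundant taxon an indicator of lv2, and
#' both latents regress on the binary disease indicator. In `one_lv` mode
#' only the lv1 block is used (the fallback taken when the two latents are
#' nearly collinear). Identification follows the standardized convention:
#' latent variances fixed to 1, observed variables standardized, the disease
#' flag modelled as an ordered (probit-threshold) indicator.
#'
#' @param effects a classified `taxon_effects` data.frame (see
#'   [classify_effects()]).
#' @param mode `"two_lv"` or `"one_lv"`.
#' @param disease name of the disease indicator (default `"disease_flg"`).
#' @param min_per_lv minimum indicators per latent for identification
#'   (default 3).
#' @return object of class `sem_spec`: list with `lv` (named list of
#'   indicator vectors), `disease`, `correlated_latents`.
#' @export
build_sem_spec <- function(effects, mode = c("two_lv", "one_lv"),
                           disease = "disease_flg", min_per_lv = 3L) {
  mode <- match.arg(mode)
  more <- effects$taxon[effects$class == "more"]
  less <- effects$taxon[effects$class == "less"]
  if (length(more) < min_per_lv)
    stop_mcibiome("mcibiome_spec_error", sprintf(
      "lv1 needs >= %d 'more' taxa, found %d", min_per_lv, length(more)))
  lv <- list(lv1 = more)
  if (mode == "two_lv") {
    if (length(less) < min_per_lv)
      stop_mcibiome("mcibiome_spec_error", sprintf(
        "lv2 needs >= %d 'less' taxa, found %d", min_per_lv, length(less)))
    lv$lv2 <- less
  }
  new_sem_spec(lv, disease = disease)
}

new_sem_spec <- function(lv, disease = NULL, correlated_latents = TRUE) {
  stopifnot(is.list(lv), length(lv) >= 1)
  if (anyDuplicated(unlist(lv)))
    stop_mcibiome("mcibiome_spec_error",
                  "a taxon may indicate at most one latent variable")
  if (!is.null(disease) && disease %in% unlist(lv))
    stop_mcibiome("mcibiome_spec_error",
                  "the disease indicator cannot also be a latent indicator")
  structure(list(lv = lv, disease = disease,
                 correlated_latents = correlated_latents && length(lv) > 1),
            class = "sem_spec")
}

#' Extract the measurement part of a model specification
#'
#' Drops the disease indicator and its structural paths, keeping the
#' latent-indicator (measurement) structure and, in the two-latent case, the
#' latent correlation. Used to refit the model in the disease-blinded
#' setting before factor scoring. Idempotent.
#'
#' @param spec an `sem_spec`.
#' @return an `sem_spec` with no disease node.
#' @export
measurement_model <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  new_sem_spec(spec$lv, disease = NULL,
               correlated_latents = spec$correlated_latents || length(spec$lv) > 1)
}

#' @export
print.sem_spec <- function(x, ...) {
  for (l in names(x$lv))
    cat(l, "=~", paste(x$lv[[l]], collapse = " + "), "\n")
  if (!is.null(x$disease))
    cat(x$disease, "~", paste(names(x$lv), collapse = " + "), "\n")
  if (x$correlated_latents && length(x$lv) == 2)
    cat(names(x$lv)[1], "~~", names(x$lv)[2], "\n")
  invisible(x)
}

#' Serialize / parse a model spec
#' @param spec an `sem_spec`.
#' @return `sem_spec_text()` returns the human-readable lavaan-style syntax
#'   as a character string.
#' @export
sem_spec_text <- function(spec) {
  paste(utils::capture.output(print(spec)), collapse = "\n")
}

# ---------------------------------------------------------------------------
# mixed Pearson / polyserial correlation input for DWLS

#' Mixed Pearson-polyserial correlations for the latent-variable stage
#'
#' Computes the moment input of the DWLS fit: Pearson correlations among the
#' (standardized) CLR columns; for a binary disease flag, the two-step
#' maximum-likelihood polyserial correlation between each column and the
#' normal latent response assumed to underlie the flag, with the probit
#' threshold fixed at `qnorm(control proportion)`; and diagonal asymptotic
#' variances used as inverse DWLS weights (normal-theory `(1 - r^2)^2 / n`
#' for Pearson terms, inverse observed information for polyserial terms with
#' a documented `1/n` fallback, delta-method for the threshold).
#'
#' @param x numeric matrix (samples x variables) with column names.
#' @param disease binary vector (0/1, logical, or case/control factor where
#'   `"case"` = 1), or NULL for a measurement-only (CFA) input.
#' @return object of class `mixed_corr`.
#' @export
mixed_correlations <- function(x, disease = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop_mcibiome("mcibiome_degenerate_error",
                  paste0("constant column: ",
                         paste(colnames(x)[sds == 0], collapse = ", ")))
  n <- nrow(x)
  z <- scale(x)
  R <- cor(z)
  avar_R <- (1 - R^2)^2 / n
  out <- list(cor_xx = R, avar_xx = avar_R, n = n, vars = colnames(x))
  if (!is.null(disease)) {
    d <- disease_to_binary(disease)
    if (length(unique(d)) < 2)
      data_error("disease flag must contain both classes")
    p_case <- mean(d)
    tau <- qnorm(1 - p_case)
    ps <- vapply(seq_len(ncol(z)), function(j)
      polyserial_ml(z[, j], d, tau), numeric(2))
    out$cor_xd <- setNames(ps[1, ], colnames(x))
    out$avar_xd <- setNames(ps[2, ], colnames(x))
    out$tau <- tau
    out$avar_tau <- p_case * (1 - p_case) / (n * dnorm(tau)^2)
  }
  class(out) <- "mixed_corr"
  out
}

disease_to_binary <- function(disease) {
  if (is.factor(disease) || is.character(disease)) {
    d <- as.character(disease)
    as.integer(d %in% c("case", "mci", "MCI", "1", "TRUE"))
  } else as.integer(disease != 0)
}

# two-step ML polyserial: threshold tau fixed from the margin, rho by
# profile likelihood; returns c(rho, avar)
polyserial_ml <- function(z, d, tau) {
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr1 <- pnorm((rho * z - tau) / s)    # P(d = 1 | z)
    pr <- ifelse(d == 1, pr1, 1 - pr1)
    -sum(log(pmax(pr, 1e-12)))
  }
  opt <- optimize(nll, c(-0.995, 0.995))
  rho <- opt$minimum
  h <- tryCatch(optimHess(rho, nll), error = function(e) NULL)
  avar <- if (!is.null(h) && is.finite(h) && h > 0) 1 / as.numeric(h)
          else 1 / length(z)
  c(rho, avar)
}

#' Wrap a ready-made correlation matrix as DWLS input
#'
#' For population-level (no sampling noise) fits and oracles: all weights
#' equal (`avar = 1/n`).
#'
#' @param R correlation matrix with dimnames.
#' @param n nominal sample size used for the chi-square scaling.
#' @param cor_xd optional named vector of variable-disease correlations.
#' @param tau optional disease threshold.
#' @return a `mixed_corr` object.
#' @export
as_mixed_corr <- function(R, n, cor_xd = NULL, tau = NULL) {
  out <- list(cor_xx = R, avar_xx = matrix(1 / n, nrow(R), ncol(R),
                                           dimnames = dimnames(R)),
              n = n, vars = colnames(R))
  if (!is.null(cor_xd)) {
    out$cor_xd <- cor_xd
    out$avar_xd <- setNames(rep(1 / n, length(cor_xd)), names(cor_xd))
    out$tau <- tau %||% 0
    out$avar_tau <- 1 / n
  }
  class(out) <- "mixed_corr"
  out
}
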