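#' Per-sample alpha-diversity indices at the genus level
#'
#' Shannon entropy (nats), Gini-Simpson index (1 - sum p^2), richness
#' (number of genera with a nonzero count) and Pielou evenness
#' (Shannon / ln richness; `NA` when richness is 1). Computed on raw counts,
#' i.e. on per-sample proportions, via vegan.
#'
#' @param counts samples x taxa count matrix; every sample total must be > 0.
#' @return data.frame with columns `sample_id`, `shannon`, `simpson`,
#'   `richness`, `pielou`.
#' @export
alpha_diversity <- function(counts) {
  if (any(rowSums(counts) <= 0)) data_error("all-zero sample in count table")
  shannon <- vegan::diversity(counts, index = "shannon")
  simpson <- vegan::diversity(counts, index = "simpson")
  richness <- rowSums(counts > 0)
  pielou <- ifelse(richness > 1, shannon / log(richness), NA_real_)
  data.frame(sample_id = rownames(counts) %||% seq_len(nrow(counts)),
             shannon = as.numeric(shannon), simpson = as.numeric(simpson),
             richness = as.integer(richness), pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(A, B) = 1 - 2 sum_i min(A_i, B_i) / (sum A + sum B)` on counts,
#' computed via [vegan::vegdist()].
#'
#' @param counts samples x taxa count matrix with positive sample totals.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(counts) {
  if (any(rowSums(counts) <= 0)) data_error("all-zero sample in count table")
  vegan::vegdist(counts, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal's NMDS (stress-1, monotone regression) via [vegan::metaMDS()],
#' best of `n_restarts` random starts; coordinates are centred.
#'
#' @param d a `dist` object (e.g. from [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param n_restarts random starts (default 20).
#' @param seed integer seed for reproducible configurations.
#' @param maxit maximum iterations per start.
#' @return list of class `mci_ordination`: `coordinates` (samples x k),
#'   `stress` (Kruskal stress-1, 0-1 scale), `k`, `converged`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 20, seed = 1L,
                            maxit = 300) {
  n <- attr(d, "Size")
  if (k >= n) config_error("k must be smaller than the number of samples")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = maxit, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  ))
  coords <- scale(fit$points, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge in any restart; best configuration returned")
  structure(list(coordinates = coords, stress = fit$stress, k = k,
                 n_restarts = n_restarts, converged = isTRUE(fit$converged)),
            class = "mci_ordination")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Anderson's pseudo-F on a dissimilarity matrix:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `F = (SS_between / (g - 1)) / (SS_within / (N - g))`.
#' The p-value is `(1 + #{permuted F >= observed F}) / (1 + n_permutations)`
#' under label permutation. With `exhaustive = TRUE` all distinct label
#' assignments are enumerated instead and the p-value is the exact
#' permutation tail probability.
#'
#' @param d a `dist` object.
#' @param labels group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_permutations number of random permutations (default 9999).
#' @param seed integer seed.
#' @param exhaustive enumerate all permutations (two-group designs only).
#' @return list of class `mci_permanova`: `pseudo_F`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(d, labels, n_permutations = 9999, seed = 1L,
                      exhaustive = FALSE) {
  labels <- as.character(labels)
  n <- attr(d, "Size")
  if (length(labels) != n) config_error("labels must match the matrix size")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    data_error("PERMANOVA needs >= 2 groups with >= 2 samples each")
  D2 <- as.matrix(d)^2
  g <- length(tab)

  f_stat <- function(lab) {
    ss_t <- sum(D2[upper.tri(D2)]) / n
    ss_w <- 0
    for (lv in names(tab)) {
      idx <- which(lab == lv)
      ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((ss_t - ss_w) / (g - 1)) / (ss_w / (n - g))
  }

  f_obs <- f_stat(labels)
  if (exhaustive) {
    if (g != 2) config_error("exhaustive enumeration supports 2 groups only")
    lv <- names(tab)
    combs <- utils::combn(n, tab[[1]])
    f_perm <- apply(combs, 2, function(idx) {
      lab <- rep(lv[2], n); lab[idx] <- lv[1]; f_stat(lab)
    })
    # the observed assignment is one of the enumerated ones
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- ncol(combs)
  } else {
    set.seed(seed)
    f_perm <- replicate(n_permutations, f_stat(sample(labels)))
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = n_perm,
                 exhaustive = exhaustive),
            class = "mci_permanova")
}

#' @export
print.mci_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d %spermutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations,
              if (x$exhaustive) "exhaustive " else ""))
  invisible(x)
}

#' @export
print.mci_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: k = %d, stress = %.4f (%s)\n", x$k, x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
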