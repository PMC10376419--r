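#' Centred log-ratio point estimate
#'
#' Deterministic CLR of a count matrix: for each sample `x`,
#' `clr_i = ln(x_i + prior) - mean_j ln(x_j + prior)`. Rows of the result sum
#' to zero, and the prior-free transform is invariant to per-sample scaling.
#'
#' @param counts samples x taxa matrix (or a single vector).
#' @param prior pseudo-count added to every cell; must be > 0 unless all
#'   counts are positive.
#' @return real matrix of the same shape, natural-log units.
#' @export
clr_point_estimate <- function(counts, prior = 0.5) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  if (prior <= 0 && any(counts <= 0))
    data_error("prior must be > 0 when zero counts are present")
  lx <- log(counts + prior)
  sweep(lx, 1, rowMeans(lx))
}

#' Dirichlet Monte-Carlo CLR ensemble
#'
#' The ALDEx2-style transform: for each Monte-Carlo instance, each sample's
#' composition is drawn from `Dirichlet(counts + prior)` and CLR-transformed.
#' The ensemble of instances carries the technical (sequencing) uncertainty
#' of the composition through all downstream per-taxon statistics.
#'
#' @param counts samples x taxa count matrix.
#' @param n_instances number of Monte-Carlo instances (>= 1); default 128.
#' @param prior Dirichlet pseudo-count, default 0.5.
#' @param seed integer seed; ensembles are reproducible from it.
#' @return object of class `clr_ensemble`: list with `instances` (list of
#'   samples x taxa CLR matrices), `n_instances`, `prior`, `seed`.
#' @export
dirichlet_clr <- function(counts, n_instances = 128L, prior = 0.5, seed = 1L) {
  if (n_instances < 1) config_error("n_instances must be >= 1")
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  set.seed(seed)
  n <- nrow(counts); p <- ncol(counts)
  alpha <- counts + prior
  instances <- vector("list", n_instances)
  for (k in seq_len(n_instances)) {
    g <- matrix(rgamma(n * p, shape = alpha, rate = 1), n, p)
    lg <- log(g)
    inst <- lg - rowMeans(lg)
    dimnames(inst) <- dimnames(counts)
    instances[[k]] <- inst
  }
  structure(list(instances = instances, n_instances = as.integer(n_instances),
                 prior = prior, seed = as.integer(seed)),
            class = "clr_ensemble")
}

#' Element-wise mean of a CLR ensemble
#'
#' Averages the Monte-Carlo instances into one matrix; row sums remain zero.
#' This is the deterministic single-matrix CLR handed to the latent-variable
#' stage (see the `clr_mode` option of [mci_risk()]).
#'
#' @param ens a `clr_ensemble`.
#' @return samples x taxa real matrix.
#' @export
ensemble_mean <- function(ens) {
  stopifnot(inherits(ens, "clr_ensemble"))
  Reduce(`+`, ens$instances) / ens$n_instances
}

#' @export
print.clr_ensemble <- function(x, ...) {
  d <- dim(x$instances[[1]])
  cat("CLR ensemble:", x$n_instances, "instances of", d[1], "samples x",
      d[2], "taxa (prior ", x$prior, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
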