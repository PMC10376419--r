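# shared fixtures, all generated in code

# small deterministic count matrix
tiny_counts <- function(n = 6, p = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(rpois(n * p, 50), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("g", seq_len(p))))
  storage.mode(m) <- "integer"
  m
}

# one-factor standardized-ish data: x_j = loading * z + noise
one_factor_data <- function(n, p, loading = 0.8, seed = 1,
                            prefix = "t") {
  set.seed(seed)
  z <- rnorm(n)
  x <- sapply(seq_len(p), function(j)
    loading * z + sqrt(1 - loading^2) * rnorm(n))
  colnames(x) <- paste0(prefix, seq_len(p))
  list(x = x, z = z)
}

one_factor_popcorr <- function(p, loading = 0.8, prefix = "t") {
  R <- tcrossprod(rep(loading, p))
  diag(R) <- 1
  dimnames(R) <- list(paste0(prefix, seq_len(p)), paste0(prefix, seq_len(p)))
  R
}

cfa_spec <- function(taxa, disease = NULL) {
  mcibiome:::new_sem_spec(list(lv1 = taxa), disease = disease)
}
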