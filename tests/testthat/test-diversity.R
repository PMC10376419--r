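test_that("alpha-diversity indices match closed forms", {
  m <- rbind(uniform = rep(5L, 10), single = c(42L, rep(0L, 9)),
             mixed = c(50L, 25L, 25L, rep(0L, 7)))
  colnames(m) <- paste0("g", 1:10)
  a <- alpha_diversity(m)
  expect_equal(a$shannon[1], log(10), tolerance = 1e-9)
  expect_equal(a$pielou[1], 1, tolerance = 1e-9)
  expect_equal(a$simpson[1], 0.9, tolerance = 1e-9)
  expect_equal(a$richness, c(10L, 1L, 3L))
  expect_equal(a$shannon[2], 0)
  expect_equal(a$simpson[2], 0)
  expect_true(is.na(a$pielou[2]))
  # proportions (0.5, 0.25, 0.25): H = 1.0397
  expect_equal(a$shannon[3], 1.039721, tolerance = 1e-5)
  expect_error(alpha_diversity(rbind(m, zero = rep(0L, 10))),
               class = "mcibiome_data_error")
})

test_that("Bray-Curtis has the expected boundary values and range", {
  m <- rbind(a = c(2L, 0L), b = c(0L, 2L), c = c(1L, 1L), d = c(1L, 1L))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["c", "d"], 0)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("NMDS recovers an exact 2-D configuration and handles duplicates", {
  set.seed(7)
  pts <- matrix(rnorm(8), 4, 2)
  d <- dist(pts)
  ord <- suppressWarnings(nmds_ordination(d, k = 2, n_restarts = 5, seed = 1))
  expect_lt(ord$stress, 0.01)
  expect_lt(max(abs(colMeans(ord$coordinates))), 1e-6)
  # duplicated sample maps to near-identical coordinates
  m <- tiny_counts(5, 8, seed = 13)
  m <- rbind(m, dup = m[1, ])
  ordd <- suppressWarnings(nmds_ordination(bray_curtis(m), k = 2, seed = 2))
  co <- ordd$coordinates
  diam <- max(dist(co))
  expect_lt(sqrt(sum((co[1, ] - co[6, ])^2)), 1e-3 * diam)
})

test_that("NMDS stress is non-increasing in the embedding dimension", {
  set.seed(42)
  x <- matrix(rnorm(10 * 6), 10, 6)
  d <- dist(x)
  stresses <- sapply(1:3, function(k)
    suppressWarnings(nmds_ordination(d, k = k, n_restarts = 10,
                                     seed = 3))$stress)
  expect_true(all(diff(stresses) <= 1e-6))
})

test_that("PERMANOVA matches exhaustive enumeration and vegan's pseudo-F", {
  set.seed(5)
  m <- tiny_counts(6, 10, seed = 5)
  labels <- rep(c("a", "b"), each = 3)
  d <- bray_curtis(m)
  res <- permanova(d, labels, exhaustive = TRUE)
  # independent brute force over all 20 label splits
  D2 <- as.matrix(d)^2
  fstat <- function(lab) {
    ssw <- sum(sapply(unique(lab), function(l) {
      i <- which(lab == l); sum(D2[i, i]) / 2 / length(i)
    }))
    sst <- sum(D2) / 2 / 6
    ((sst - ssw) / 1) / (ssw / 4)
  }
  combs <- combn(6, 3)
  fs <- apply(combs, 2, function(i) {
    lab <- rep("b", 6); lab[i] <- "a"; fstat(lab)
  })
  expect_equal(res$pseudo_F, fstat(labels), tolerance = 1e-12)
  expect_equal(res$p_value, mean(fs >= fstat(labels) - 1e-12))
  expect_equal(res$n_permutations, 20)
  # pseudo-F agrees with the adonis formulation in vegan
  av <- vegan::adonis2(d ~ grp, data = data.frame(grp = labels),
                       permutations = 99)
  expect_equal(res$pseudo_F, av$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates planted clusters and is label-name invariant", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
             matrix(rnorm(20, 5, 0.05), 10, 2))
  d <- dist(x)
  lab <- rep(c("g1", "g2"), each = 10)
  res <- permanova(d, lab, n_permutations = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  res2 <- permanova(d, rep(c("zzz", "aaa"), each = 10),
                    n_permutations = 999, seed = 1)
  expect_equal(res$p_value, res2$p_value)
  expect_equal(res$pseudo_F, res2$pseudo_F)
  expect_error(permanova(d, rep("one", 20)), class = "mcibiome_data_error")
})
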