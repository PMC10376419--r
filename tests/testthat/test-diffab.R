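test_that("label swap negates every effect size exactly", {
  cfg <- mci_sim_config(n_case = 10, n_control = 12, n_taxa = 25,
                        lv1_taxa = 1:3, lv2_taxa = 4:6, seed = 6)
  d <- simulate_cohort(cfg)
  ens <- dirichlet_clr(d$counts, n_instances = 24, seed = 3)
  grp <- d$metadata$group
  swapped <- ifelse(grp == "case", "control", "case")
  e1 <- aldex_effects(ens, grp, seed = 7)
  e2 <- aldex_effects(ens, swapped, case_level = "control", seed = 7)
  expect_equal(e1$effect, e2$effect, tolerance = 1e-12)
  e3 <- aldex_effects(ens, swapped, seed = 7)
  expect_equal(e1$effect, -e3$effect, tolerance = 1e-12)
  expect_equal(e1$diff_btw, -e3$diff_btw, tolerance = 1e-12)
})

test_that("effects are invariant to a constant shift of one taxon's CLR values", {
  m <- tiny_counts(12, 6, seed = 9)
  ens <- dirichlet_clr(m, n_instances = 16, seed = 1)
  grp <- rep(c("case", "control"), each = 6)
  e1 <- aldex_effects(ens, grp, seed = 4)
  shifted <- ens
  shifted$instances <- lapply(ens$instances, function(x) {
    x[, 2] <- x[, 2] + 5; x
  })
  e2 <- aldex_effects(shifted, grp, seed = 4)
  expect_equal(e1$effect, e2$effect, tolerance = 1e-10)
})

test_that("classification follows the +/-0.2 rule", {
  eff <- data.frame(taxon = c("a", "b", "c", "d"),
                    effect = c(0.25, -0.25, 0.1, 0.2),
                    stringsAsFactors = FALSE)
  out <- classify_effects(eff, threshold = 0.2)
  expect_equal(out$class, c("more", "less", "none", "none"))
  expect_error(classify_effects(eff, threshold = 0),
               class = "mcibiome_config_error")
})

test_that("rank-sum p matches the uncorrected normal approximation and exact enumeration", {
  # U = 0, sigma^2 = n1 n2 (n+1)/12 -> z = -1.549, p = 0.1213
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 0.1213353,
               tolerance = 1e-6)
  expect_equal(wilcoxon_rank_sum(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1)
  # exact option against brute-force enumeration of all rank assignments
  x <- c(0.3, 1.7); y <- c(2.5, 0.9)
  p_exact <- wilcoxon_rank_sum(x, y, exact = TRUE)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[1:2]) - 3
  us <- apply(combn(4, 2), 2, function(i) sum(rank(pooled)[i]) - 3)
  p_brute <- mean(abs(us - 2) >= abs(u_obs - 2))
  expect_equal(p_exact, p_brute)
  # the vectorized internal agrees with wilcox.test column-wise
  X <- matrix(rnorm(40), 10, 4)
  is_case <- rep(c(TRUE, FALSE), each = 5)
  pv <- mcibiome:::wilcoxon_matrix(X, is_case)
  ref <- apply(X, 2, function(col)
    wilcox.test(col[is_case], col[!is_case], exact = FALSE,
                correct = FALSE)$p.value)
  expect_equal(unname(pv), unname(ref), tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(30)
  q <- bh_adjust(p)
  # brute-force step-up with monotonicity enforcement
  ord <- order(p)
  q_brute <- p[ord] * 30 / seq_len(30)
  q_brute <- rev(cummin(rev(q_brute)))[order(ord)]
  expect_equal(q, pmin(q_brute, 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("2x2 chi-square reproduces printed and hand-computed values", {
  # published sex-by-group table: male 11/17, female 18/23
  res <- chi_square_2x2(11, 17, 18, 23)
  expect_equal(res$p_value, 0.894, tolerance = 5e-4)
  res_no <- chi_square_2x2(11, 17, 18, 23, yates = FALSE)
  expect_equal(res_no$statistic, 0.1456, tolerance = 1e-3)
  expect_equal(res_no$p_value, 0.703, tolerance = 1e-3)
  prop <- chi_square_2x2(10, 20, 10, 20, yates = FALSE)
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), class = "mcibiome_data_error")
})

test_that("cohort summary reports group stats with the right tests", {
  cfg <- mci_sim_config(n_case = 8, n_control = 9, n_taxa = 20,
                        lv1_taxa = 1:3, lv2_taxa = 4:5, seed = 12)
  d <- simulate_sexed_cohort(cfg, mci_sim_config(
    n_case = 8, n_control = 9, n_taxa = 20, lv1_taxa = 1:3,
    lv2_taxa = 4:5, seed = 13))
  cs <- cohort_summary(d$counts, d$metadata)
  expect_true(all(c("shannon", "simpson", "richness", "pielou",
                    "sex_male_female") %in% cs$variable))
  expect_true(all(cs$p_value > 0 & cs$p_value <= 1))
  expect_equal(attr(cs, "n"), c(case = 16L, control = 18L))
  expect_equal(cs$test[cs$variable == "sex_male_female"],
               "chi_square_yates")
})
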