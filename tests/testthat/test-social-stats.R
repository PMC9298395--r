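test_that("workload composite: sum, 2/3 normalization, half-up rounding", {
  expect_equal(workload_composite(c(2, 1, 3, 0), "single-10min"), 6L)
  expect_equal(workload_composite(c(6, 9, 12), "triple-15min"), 6L)
  expect_equal(workload_composite(c(1, 1, 2), "triple-15min"), 1L)  # 8/9 -> 1
  expect_equal(workload_composite(c(0, 0, 0, 0), "single-10min"), 0L)
  # half-up (not banker's): normalized 2.5 rounds to 3, not 2
  expect_equal(workload_composite(c(3.75, 3.75, 3.75), "triple-15min"), 3L)
  expect_error(workload_composite(c(-1, 2), "single-10min"), "nonnegative")
  expect_error(workload_composite(c(1, 2), "triple-15min"), "three")
})

test_that("2x2 chi-square equals the closed form and flags zero margins", {
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    got <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "margin")
})

test_that("one-sample t: moments form equals raw-sample form", {
  set.seed(22)
  x <- rnorm(30, 1, 2)
  a <- one_sample_t(x, mu0 = 0.5)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = length(x), mu0 = 0.5)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(one_sample_t(c(1, 2, 3), mu0 = 2)$t, 0)
  expect_equal(one_sample_t(c(1, 2, 3), mu0 = 2)$p_value, 1)
  expect_error(one_sample_t(c(2, 2, 2), mu0 = 0), "sd")
})

test_that("Dunnett's C intervals: symmetry and equal-variance structure", {
  x <- c(1, 2, 3, 4, 5)
  res <- dunnett_c(list(a = x, b = x))
  expect_equal(res$mean_diff, 0)
  expect_equal(res$lower, -res$upper)
  expect_false(res$significant)
  # equal variance and n: identical half-widths for all pairs
  set.seed(23)
  base <- rnorm(10)
  smp <- list(a = base, b = base + 1, c = base + 3)
  r3 <- dunnett_c(smp)
  hw <- (r3$upper - r3$lower) / 2
  expect_equal(max(hw) - min(hw), 0, tolerance = 1e-10)
  expect_warning(dunnett_c(list(a = c(1, 1), b = c(1, 1))), "zero variance")
})

test_that("Dunnett's C covers the true difference conservatively (k = 2)", {
  # 4000 replicates (scaled from 10000 for runtime); criterion >= 93%
  set.seed(24)
  n <- 15
  hits <- replicate(4000, {
    a <- rnorm(n, 0, 1); b <- rnorm(n, 1, 2)
    ci <- dunnett_c(list(a = a, b = b), alpha = 0.05)
    ci$lower <= -1 && -1 <= ci$upper
  })
  expect_gte(mean(hits), 0.93)
})

test_that("bootstrap comparison with n_reps = 1 is one ANOVA + Dunnett run", {
  set.seed(25)
  vals <- rnorm(60); cats <- rep(c("x", "y", "z"), each = 20)
  res <- bootstrap_category_comparison(vals, cats, n_reps = 1, seed = 77)
  # replay the single bootstrap draw
  set.seed(77)
  idx <- sample.int(60, 60, replace = TRUE)
  vb <- vals[idx]; cb <- cats[idx]
  ref <- dunnett_c(split(vb, factor(cb, c("x", "y", "z"))))
  expect_equal(res$mean_diff, ref$mean_diff, tolerance = 1e-12)
  expect_equal(res$avg_lo, ref$lower, tolerance = 1e-12)
  expect_equal(res$avg_hi, ref$upper, tolerance = 1e-12)
  p_ref <- anova(lm(vb ~ factor(cb)))$`Pr(>F)`[1]
  expect_equal(unique(res$avg_p), p_ref, tolerance = 1e-12)
})

test_that("bootstrap comparison separates a 3-sigma mean gap", {
  set.seed(26)
  vals <- c(rnorm(50, 0, 1), rnorm(50, 3, 1))
  cats <- rep(c("near", "far"), each = 50)
  res <- bootstrap_category_comparison(vals, cats, n_reps = 50, seed = 8)
  expect_true(all(res$significant))
  expect_lt(res$avg_p, 0.001)
})

test_that("Gehan-Wilcoxon: null, separation, and rank invariance", {
  t0 <- c(1, 2, 3, 4, 5)
  res <- km_gehan(c(t0, t0), rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # complete separation, n = 20 each
  set.seed(27)
  ta <- runif(20, 1, 10); tb <- runif(20, 20, 30)
  res2 <- km_gehan(c(ta, tb), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_lt(res2$p_value, 0.01)
  # doubling all times leaves the statistic unchanged
  res3 <- km_gehan(2 * c(ta, tb), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_equal(res3$statistic, res2$statistic, tolerance = 1e-12)
  expect_error(km_gehan(c(1, 2), c(0, 1), c("a", "b")), "event")
})

test_that("summary tables conserve counts and degrade gracefully", {
  cfg <- simulation_config(n_groups = 4, seed = 33)
  sim <- simulate_population(cfg)
  fb <- estimate_allele_frequencies(sim$dataset, "naive")
  par <- assign_parentage(sim$dataset, fb)
  dem <- demography_report(sim$dataset, fb, parentage = par,
                           n_null = 300, seed = 33)
  tabs <- summarize_structure(dem, par)
  # immigration rows sum to the non-offspring member count
  expect_equal(sum(tabs$immigration[, 2:4]),
               sum(dem$status != "offspring"))
  # empty parentage: zero produced counts, denominators intact
  empty <- par[0, ]
  sk0 <- summarize_structure(dem, empty)$skew
  expect_true(all(sk0$produced_subgroup == 0 & sk0$produced_other == 0))
  expect_equal(sk0$members_subgroup,
               summarize_structure(dem, par)$skew$members_subgroup)
})
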