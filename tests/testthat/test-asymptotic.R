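test_that("simulated bridges are pinned and have the bridge covariance", {
  set.seed(51)
  draws <- replicate(20000, simulate_bridge(8, 1)[, 1])
  expect_true(all(draws[1, ] == 0))
  expect_true(all(draws[9, ] == 0))
  # Var B(1/2) = 1/4; Cov(B(1/4), B(3/4)) = 1/4 * (1 - 3/4) = 1/16
  v_mid <- var(draws[5, ])
  expect_lt(abs(v_mid - 0.25), 3 * 0.25 * sqrt(2 / 20000))
  cv <- cov(draws[3, ], draws[7, ])
  se_cv <- sqrt((3 / 16 * 3 / 16 + (1 / 16)^2) / 20000)
  expect_lt(abs(cv - 1 / 16), 3 * se_cv)
})

test_that("kolmogorov_sup_cdf matches known values and Monte Carlo", {
  expect_equal(kolmogorov_sup_cdf(-1), 0)
  expect_equal(kolmogorov_sup_cdf(50), 1)
  expect_lt(abs(kolmogorov_sup_cdf(1.358) - 0.95), 5e-4)
  ref <- build_reference("dm", k = 1, grid_n = 1500, n_sim = 20000, seed = 52)
  p_mc <- mean(ref$values <= 0.5)
  # grid discreteness biases the simulated sup slightly downward
  expect_lt(abs(p_mc - kolmogorov_sup_cdf(0.5)), 0.02)
})

test_that("null references are reproducible and correctly shaped", {
  r1 <- build_reference("maxlm", k = 2, grid_n = 100,
                        trim = trim_spec("fraction", 0.1),
                        n_sim = 2000, seed = 53)
  r2 <- build_reference("maxlm", k = 2, grid_n = 100,
                        trim = trim_spec("fraction", 0.1),
                        n_sim = 2000, seed = 53)
  expect_identical(r1$values, r2$values)
  expect_false(is.unsorted(r1$values))
  expect_true(all(r1$values >= 0))
  expect_warning(build_reference("dm", 1, 50, n_sim = 500, seed = 1), "coarse")
})

test_that("compiled reference equals the R simulation path draw-for-draw", {
  set.seed(54)
  cppv <- sctperm:::bridge_stat_reference_cpp(25L, 40L, 3L, 3L, 4L, 36L)
  set.seed(54)
  rv <- replicate(25, {
    maxlm_statistic(make_efp(simulate_bridge(40, 3)),
                    trim_spec("fraction", 0.1))$value
  })
  expect_equal(cppv, rv, tolerance = 1e-12)
  set.seed(55)
  cppd <- sctperm:::bridge_stat_reference_cpp(25L, 40L, 2L, 1L, 1L, 39L)
  set.seed(55)
  rd <- replicate(25, dm_statistic(make_efp(simulate_bridge(40, 2)))$value)
  expect_equal(cppd, rd, tolerance = 1e-12)
  set.seed(56)
  cppc <- sctperm:::bridge_stat_reference_cpp(25L, 40L, 2L, 2L, 1L, 39L)
  set.seed(56)
  rc <- replicate(25, cvm_statistic(make_efp(simulate_bridge(40, 2)))$value)
  expect_equal(cppc, rc, tolerance = 1e-12)
})

test_that("CvM reference mean is k/6 and maxLM references grow with k", {
  c1 <- build_reference("cvm", k = 1, grid_n = 500, n_sim = 10000, seed = 57)
  expect_lt(abs(mean(c1$values) - 1 / 6), 3 * sd(c1$values) / sqrt(10000))
  m1 <- build_reference("maxlm", k = 1, grid_n = 200,
                        trim = trim_spec("fraction", 0.1),
                        n_sim = 5000, seed = 58)
  m2 <- build_reference("maxlm", k = 2, grid_n = 200,
                        trim = trim_spec("fraction", 0.1),
                        n_sim = 5000, seed = 59)
  # stochastic dominance: quantile-wise ordering away from the extreme tails
  qs <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(quantile(m2$values, qs) >= quantile(m1$values, qs)))
})

test_that("asymptotic p values are exceedance proportions with matching metadata", {
  ref <- build_reference("dm", k = 1, grid_n = 100, n_sim = 2000, seed = 60)
  obs <- function(v) structure(list(name = "DM", value = v, n = 100, k = 1),
                               class = "sct_statistic")
  expect_equal(asymptotic_pvalue(obs(max(ref$values) + 1), ref), 0)
  expect_equal(asymptotic_pvalue(obs(min(ref$values)), ref), 1)
  med <- median(ref$values)
  expect_lt(abs(asymptotic_pvalue(obs(med), ref) - 0.5), 1 / 2000 + 1e-12)
  bad <- structure(list(name = "CvM", value = 1, n = 100, k = 1),
                   class = "sct_statistic")
  expect_error(asymptotic_pvalue(bad, ref), "mismatch")
  bad2 <- structure(list(name = "DM", value = 1, n = 100, k = 2),
                    class = "sct_statistic")
  expect_error(asymptotic_pvalue(bad2, ref), "mismatch")
})

test_that("p values of fresh bridge draws against a reference are uniform", {
  ref <- build_reference("maxlm", k = 2, grid_n = 100,
                         trim = trim_spec("fraction", 0.1),
                         n_sim = 20000, seed = 61)
  set.seed(62)
  fresh <- sctperm:::bridge_stat_reference_cpp(2000L, 100L, 2L, 3L, 10L, 90L)
  p <- vapply(fresh, function(x) mean(ref$values >= x), numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("references roundtrip through the JSON cache", {
  ref <- build_reference("maxlm", k = 2, grid_n = 50,
                         trim = trim_spec("count", 5, 5),
                         n_sim = 1000, seed = 63)
  path <- tempfile(fileext = ".json")
  save_reference(ref, path)
  back <- load_reference(path)
  expect_equal(back$values, ref$values)
  expect_equal(back$k, ref$k)
  expect_equal(unclass(back$trim), unclass(ref$trim), ignore_attr = TRUE)
})
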