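test_that("H0 GGM generator draws sparse SPD precision matrices", {
  set.seed(81)
  n_edges <- replicate(1000, nrow(generate_ggm_h0(5, n = 1)$spec$edges))
  # 10 node pairs at edge probability 0.2
  expect_lt(abs(mean(n_edges) - 2), 3 * sqrt(10 * 0.2 * 0.8 / 1000))
  min_eig <- replicate(1000, {
    K <- sctperm:::make_sparse_precision(6, 0.2)$precision
    min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  })
  expect_true(all(min_eig > 0))
})

test_that("empty graph gives independent columns", {
  set.seed(82)
  d <- generate_ggm_h0(4, 4000, edge_prob = 0)
  expect_equal(d$spec$precision, diag(4))
  cors <- cor(d$data)
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(4000))
})

test_that("linear H0 generator is a pure-noise design independent of v", {
  set.seed(83)
  d <- generate_linear_h0(4, 1000)
  fit <- fit_linear(d$design, d$response)
  expect_lt(max(abs(fit$theta)), 4 / sqrt(1000))
  expect_lt(max(abs(colSums(fit$scores))), 1e-6 * 1000)
  r <- d$response - as.vector(cbind(1, d$design) %*% fit$beta)
  expect_lt(abs(cor(r, d$v)), 4 / sqrt(1000))
})

test_that("alternative generator reduces to H0 at delta = 0 and shifts one edge otherwise", {
  set.seed(84)
  d0 <- generate_ggm_alternative(5, 100, delta_theta = 0)
  expect_equal(d0$spec_lower$precision, d0$spec_upper$precision)

  set.seed(85)
  # a lone force-added edge: the +0.5 shift is always SPD-feasible, so the
  # group-wise MLE difference must converge to the nominal delta
  d <- generate_ggm_alternative(5, 20000, edge_prob = 0, delta_theta = 0.5)
  e <- d$changed_edges[1, ]
  lower <- d$v < quantile(d$v, 0.5)
  pcor_hat <- function(Y, j, l) {
    K <- solve(cov(Y))
    -K[j, l] / sqrt(K[j, j] * K[l, l])
  }
  diff_hat <- pcor_hat(d$data[!lower, ], e[1], e[2]) -
    pcor_hat(d$data[lower, ], e[1], e[2])
  true_diff <- d$spec_upper$partial_cor[e[1], e[2]] -
    d$spec_lower$partial_cor[e[1], e[2]]
  expect_equal(true_diff, 0.5, tolerance = 1e-12)
  expect_lt(abs(diff_hat - 0.5), 0.06)
})

test_that("alternative generator force-adds an edge when the base graph is empty", {
  set.seed(86)
  d <- generate_ggm_alternative(4, 50, edge_prob = 0, delta_theta = 0.3)
  expect_equal(nrow(d$changed_edges), 1L)
  e <- d$changed_edges[1, ]
  expect_equal(d$spec_upper$partial_cor[e[1], e[2]] -
                 d$spec_lower$partial_cor[e[1], e[2]], 0.3,
               tolerance = 1e-12)
})

test_that("type-I study runner returns calibrated, reproducible results", {
  s1 <- run_type1_study("ggm", k_or_p = 3, n = 80, n_reps = 20,
                        methods = "permutation", n_perm = 199, seed = 9)
  s2 <- run_type1_study("ggm", k_or_p = 3, n = 80, n_reps = 20,
                        methods = "permutation", n_perm = 199, seed = 9)
  expect_identical(s1$p_values, s2$p_values)
  expect_equal(dim(s1$p_values), c(20L, 1L))
  expect_true(all(s1$p_values > 0 & s1$p_values <= 1))
  df <- as.data.frame(s1)
  expect_equal(nrow(df), 20L)
  expect_named(df, c("rep", "method", "p_value"))

  sl <- run_type1_study("linear", k_or_p = 2, n = 60, n_reps = 10,
                        methods = "asymptotic", n_sim = 2000, seed = 10)
  expect_equal(dim(sl$p_values), c(10L, 1L))
})

test_that("power grows with the size of the parameter shift", {
  lo <- run_power_study(k_or_p = 4, n = 150, delta_theta = 0,
                        n_reps = 60, methods = "permutation",
                        n_perm = 199, seed = 11)
  hi <- run_power_study(k_or_p = 4, n = 150, delta_theta = 0.8,
                        n_reps = 60, methods = "permutation",
                        n_perm = 199, seed = 11)
  expect_lt(lo$rejection_rate["permutation"], 0.18)  # ~ alpha under the null
  expect_gt(hi$rejection_rate["permutation"],
            lo$rejection_rate["permutation"])
})
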