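test_that("score columns sum to zero at the MLE for both models", {
  set.seed(101)
  for (r in 1:10) {
    n <- sample(40:120, 1)
    q <- sample(2:5, 1)
    X <- matrix(rnorm(n * q), n, q)
    y <- X %*% rnorm(q) + rnorm(n)
    fit <- fit_linear(X, y)
    expect_lt(max(abs(colSums(fit$scores))), 1e-6 * n)

    p <- sample(2:6, 1)
    d <- generate_ggm_h0(p, n = max(n, 5 * p))
    fitg <- fit_ggm(d$data)
    expect_lt(max(abs(colSums(fitg$scores))), 1e-6 * nrow(d$data))
  }
})

test_that("linear-model scores match finite differences of the log-density", {
  set.seed(42)
  n <- 200; q <- 5
  X <- cbind(1, matrix(rnorm(n * (q - 1)), n, q - 1))
  y <- X %*% runif(q, -1, 1) + rnorm(n)
  fit <- fit_linear(X, y, intercept = FALSE)
  s2 <- fit$sigma2
  for (i in c(1, 57, 200)) {
    f <- function(beta)
      -0.5 * log(2 * pi * s2) - (y[i] - sum(X[i, ] * beta))^2 / (2 * s2)
    expect_lt(max(abs(num_grad(f, fit$beta) - fit$scores[i, ])), 1e-6)
  }
})

test_that("GGM scores match finite differences of the per-observation log-density", {
  set.seed(43)
  n <- 100; p <- 3
  d <- generate_ggm_h0(p, n)
  fit <- fit_ggm(d$data)
  for (i in c(1, 50, 100)) {
    f <- function(th) mvn_logdens_param(th, d$data[i, ], p)
    g <- num_grad(f, unname(fit$theta))
    expect_lt(max(abs(g - fit$scores[i, ])), 1e-4)
  }
})

test_that("GGM parameter layout is means, diagonals, then row-major off-diagonals", {
  set.seed(44)
  d <- generate_ggm_h0(3, 60)
  fit <- fit_ggm(d$data)
  expect_identical(names(fit$theta),
                   c("mu_y1", "mu_y2", "mu_y3",
                     "K_y1.y1", "K_y2.y2", "K_y3.y3",
                     "K_y1.y2", "K_y1.y3", "K_y2.y3"))
  expect_equal(fit$k, 9L)
  expect_equal(fit$n_free, 9L)  # p(p+3)/2
  expect_equal(unname(fit$theta[1:3]), unname(colMeans(d$data)))
})

test_that("fitting is invariant to observation order", {
  set.seed(45)
  d <- generate_ggm_h0(4, 80)
  fit <- fit_ggm(d$data)
  perm <- sample(80)
  fit2 <- fit_ggm(d$data[perm, ])
  expect_equal(fit2$theta, fit$theta)
  expect_equal(fit2$information, fit$information)
  expect_equal(fit2$scores, fit$scores[perm, ])

  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rnorm(60)
  fl <- fit_linear(X, y)
  pl <- sample(60)
  fl2 <- fit_linear(X[pl, ], y[pl])
  expect_equal(fl2$theta, fl$theta)
  expect_equal(fl2$scores, fl$scores[pl, ])
})

test_that("GGM diagonal-score identity holds exactly at the MLE", {
  set.seed(46)
  d <- generate_ggm_h0(5, 120)
  fit <- fit_ggm(d$data)
  Yc <- sweep(d$data, 2, fit$mu)
  # mean of squared centered data equals the fitted covariance diagonal
  expect_equal(unname(colMeans(Yc^2)), unname(diag(fit$Sigma)), tolerance = 1e-12)
})

test_that("degenerate and ill-posed inputs are hard errors", {
  set.seed(47)
  X <- matrix(rnorm(20 * 2), 20, 2)
  expect_error(fit_linear(X, X %*% c(1, 2)), "zero residual variance")
  X3 <- cbind(X, X[, 1] + X[, 2])
  colnames(X3) <- c("a", "b", "c")
  expect_error(fit_linear(X3, rnorm(20)), "rank deficient")
  expect_error(fit_linear(matrix(rnorm(6), 3, 2), rnorm(3), intercept = TRUE),
               "n > q")
  expect_error(fit_ggm(matrix(rnorm(6), 2, 3)), "n > p")
  Y <- cbind(rnorm(30), rnorm(30))
  Y <- cbind(Y, Y[, 1])  # exactly collinear -> singular covariance
  expect_error(fit_ggm(Y), "singular")
})

test_that("OPG information: trivial cases and convergence to the Fisher information", {
  expect_equal(opg_information(matrix(0, 10, 2)), matrix(0, 2, 2))
  expect_equal(opg_information(matrix(c(1, -1), 2, 1)), matrix(1, 1, 1))
  expect_warning(opg_information(matrix(rnorm(6), 2, 3)), "n < k")

  # analytic Fisher information of the MVN in the (mu, K) parametrization
  fisher_mvn <- function(Sigma) {
    p <- nrow(Sigma)
    K <- solve(Sigma)
    ut <- which(upper.tri(K), arr.ind = TRUE)
    ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
    dK <- c(lapply(seq_len(p), function(j) {
      M <- matrix(0, p, p); M[j, j] <- 1; M
    }), lapply(seq_len(nrow(ut)), function(e) {
      M <- matrix(0, p, p)
      M[ut[e, 1], ut[e, 2]] <- M[ut[e, 2], ut[e, 1]] <- 1
      M
    }))
    nk <- length(dK)
    Ik <- matrix(0, nk, nk)
    for (a in seq_len(nk)) for (b in seq_len(nk))
      Ik[a, b] <- 0.5 * sum(diag(Sigma %*% dK[[a]] %*% Sigma %*% dK[[b]]))
    k <- p + nk
    I <- matrix(0, k, k)
    I[seq_len(p), seq_len(p)] <- K
    I[p + seq_len(nk), p + seq_len(nk)] <- Ik
    I
  }
  set.seed(48)
  g <- sctperm:::make_sparse_precision(5, 0.2)
  Sigma <- solve(g$precision)
  I_true <- fisher_mvn(Sigma)
  rel_err <- vapply(c(200, 2000, 20000), function(n) {
    Y <- MASS::mvrnorm(n, rep(0, 5), Sigma)
    fit <- fit_ggm(Y)
    norm(fit$information - I_true, "F") / norm(I_true, "F")
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
})
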