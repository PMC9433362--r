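#' Fit a linear regression model and extract per-observation scores
#'
#' Fits \eqn{y = X\beta + \epsilon} by maximum likelihood and returns the
#' ingredients of a score-based structural change test: the MLE, the
#' n x k matrix of per-observation scores of the Gaussian log-likelihood,
#' and the outer-product-of-gradients (OPG) estimate of the information.
#'
#' The tested parameter set is the mean-function coefficients. The error
#' variance is profiled out with its ML estimate \eqn{\hat\sigma^2 = RSS/n}
#' and is not part of the tested set. The score of coefficient \eqn{j} at
#' observation \eqn{i} is \eqn{x_{ij}(y_i - x_i'\hat\beta)/\hat\sigma^2};
#' at the MLE every score column sums to zero, which is the identity the
#' fluctuation process is pinned by.
#'
#' @param design numeric matrix (n x q) of regressors. An intercept column
#'   is added unless `intercept = FALSE` and the matrix already contains one.
#' @param response numeric vector of length n.
#' @param intercept logical; prepend a column of ones (default `TRUE`).
#' @param test_intercept logical; keep the intercept in the tested parameter
#'   set (default `TRUE`). When `FALSE` its score column is dropped after
#'   fitting, so only the covariate coefficients are scanned for instability.
#' @return an object of class `sct_fit` with elements `model_kind`
#'   (`"linear"`), `theta` (named MLE vector), `scores` (n x k matrix),
#'   `information` (k x k OPG estimate), `n`, `k`, and `n_free` (number of
#'   free parameters of the full model, including the error variance).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 3), 100, 3)
#' y <- rnorm(100)
#' fit <- fit_linear(X, y)
#' colSums(fit$scores)  # all (near) zero at the MLE
fit_linear <- function(design, response, intercept = TRUE,
                       test_intercept = TRUE) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(X) != n) stop("design and response dimensions disagree")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in design or response")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  has_const <- any(apply(X, 2, function(col) all(col == col[1] & col[1] != 0)))
  if (intercept && !has_const)
    X <- cbind("(Intercept)" = 1, X)
  q <- ncol(X)
  if (n <= q) stop("need more observations than regressors (n > q)")
  qrX <- qr(X)
  if (qrX$rank < q) {
    bad <- colnames(X)[setdiff(seq_len(q), qrX$pivot[seq_len(qrX$rank)])]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  resid <- as.numeric(y - X %*% beta)
  sigma2 <- sum(resid^2) / n
  if (sigma2 <= .Machine$double.eps * max(1, mean(y^2)))
    stop("degenerate zero residual variance: scores are undefined")
  scores <- X * (resid / sigma2)
  colnames(scores) <- names(beta) <- colnames(X)
  if (!test_intercept && "(Intercept)" %in% colnames(scores)) {
    keep <- colnames(scores) != "(Intercept)"
    scores <- scores[, keep, drop = FALSE]
    theta <- beta[keep]
  } else {
    theta <- beta
  }
  new_sct_fit(model_kind = "linear", theta = theta, scores = scores,
              n_free = q + 1L, extra = list(sigma2 = sigma2, beta = beta))
}

#' Fit a saturated Gaussian graphical model and extract scores
#'
#' Fits the saturated multivariate normal model \eqn{N(\mu, K^{-1})} by
#' maximum likelihood (\eqn{\hat\mu} = column means, \eqn{\hat\Sigma} = ML
#' covariance with the 1/n denominator, \eqn{\hat K = \hat\Sigma^{-1}}) and
#' returns per-observation scores for all k = p(p+3)/2 free parameters:
#' the p means ("thresholds"), the p diagonal precision entries, and the
#' p(p-1)/2 off-diagonal precision entries ("interactions"), in that order
#' (off-diagonals in row-major upper-triangle order).
#'
#' Each symmetric off-diagonal pair is a single free parameter, so its
#' score counts both occurrences:
#' \deqn{s_{\mu_j} = [K(y-\mu)]_j, \quad
#'       s_{K_{jj}} = \tfrac12 (K^{-1})_{jj} - \tfrac12 (y_j-\mu_j)^2, \quad
#'       s_{K_{jl}} = (K^{-1})_{jl} - (y_j-\mu_j)(y_l-\mu_l).}
#' The 1/n covariance makes every score column sum to exactly zero at the
#' MLE.
#'
#' @param data numeric matrix (n x p), one row per observation.
#' @return an `sct_fit` object (see [fit_linear()]) with
#'   `model_kind = "ggm"`; `n_free` equals k = p(p+3)/2.
#' @export
fit_ggm <- function(data) {
  Y <- as.matrix(data)
  if (!all(is.finite(Y))) stop("non-finite values in data")
  n <- nrow(Y); p <- ncol(Y)
  if (n <= p) stop("need more observations than variables (n > p)")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(p))
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  Sigma <- crossprod(Yc) / n
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("sample covariance is (near-)singular; cannot invert for the precision matrix")
  K <- chol2inv(chol(Sigma))
  vars <- colnames(Y)
  # scores: means, then diagonal precisions, then upper-triangle off-diagonals
  s_mu <- Yc %*% K
  colnames(s_mu) <- paste0("mu_", vars)
  s_diag <- matrix(rep(diag(Sigma), each = n), n, p) / 2 - Yc^2 / 2
  colnames(s_diag) <- paste0("K_", vars, ".", vars)
  ut <- which(upper.tri(K), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  s_off <- matrix(0, n, nrow(ut))
  off_names <- character(nrow(ut))
  for (e in seq_len(nrow(ut))) {
    j <- ut[e, 1]; l <- ut[e, 2]
    s_off[, e] <- Sigma[j, l] - Yc[, j] * Yc[, l]
    off_names[e] <- paste0("K_", vars[j], ".", vars[l])
  }
  colnames(s_off) <- off_names
  scores <- cbind(s_mu, s_diag, s_off)
  theta_off <- numeric(nrow(ut))
  for (e in seq_len(nrow(ut))) theta_off[e] <- K[ut[e, 1], ut[e, 2]]
  theta <- c(mu, diag(K), theta_off)
  names(theta) <- colnames(scores)
  new_sct_fit(model_kind = "ggm", theta = theta, scores = scores,
              n_free = as.integer(p * (p + 3) / 2),
              extra = list(mu = mu, Sigma = Sigma, K = K, p = p))
}

#' Outer-product-of-gradients information estimate
#'
#' \eqn{\hat I = n^{-1} \sum_i s_i s_i'}, the empirical covariance of the
#' per-observation scores about zero. This is the "asymptotic covariance
#' matrix of the scores" used to decorrelate the fluctuation process.
#'
#' @param scores numeric n x k score matrix.
#' @return symmetric positive semi-definite k x k matrix.
#' @export
opg_information <- function(scores) {
  S <- as.matrix(scores)
  if (!all(is.finite(S))) stop("non-finite scores")
  n <- nrow(S); k <- ncol(S)
  if (n < k)
    warning("fewer observations than parameters (n < k): OPG information is singular by construction")
  info <- crossprod(S) / n
  info <- (info + t(info)) / 2
  info
}

new_sct_fit <- function(model_kind, theta, scores, n_free, extra = list()) {
  info <- opg_information(scores)
  fit <- c(list(model_kind = model_kind, theta = theta,
                scores = scores, information = info,
                n = nrow(scores), k = ncol(scores),
                n_free = as.integer(n_free)),
           extra)
  class(fit) <- "sct_fit"
  fit
}

#' @export
print.sct_fit <- function(x, ...) {
  cat(sprintf("Score-based SCT model fit (%s)\n", x$model_kind))
  cat(sprintf("  n = %d observations, k = %d tested parameters (n_free = %d)\n",
              x$n, x$k, x$n_free))
  cat("  theta-hat:\n")
  print(head(round(x$theta, 4), 12))
  if (length(x$theta) > 12) cat("  ...\n")
  invisible(x)
}
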