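#' Build a sparse random precision matrix with unit partial variances
#'
#' Edges drawn i.i.d. Bernoulli(`edge_prob`) over unordered pairs; each
#' edge's partial correlation drawn uniformly from +/-[0.1, 0.4]. The
#' precision matrix starts with unit diagonal and off-diagonal entries
#' -rho, is made strictly diagonally dominant (any deficient diagonal is
#' raised to the absolute off-diagonal row sum plus 0.05), and is then
#' rescaled to unit partial variances. Diagonal dominance plus congruence
#' scaling guarantees positive definiteness on every draw.
#'
#' @param p number of nodes.
#' @param edge_prob edge probability (default 0.2).
#' @param partial_range magnitude range for edge partial correlations.
#' @return list with `precision`, `partial_cor` (signed, zero off the
#'   graph), `edges` (2-column matrix of node pairs).
#' @keywords internal
make_sparse_precision <- function(p, edge_prob = 0.2,
                                  partial_range = c(0.1, 0.4)) {
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  on <- runif(nrow(pairs)) < edge_prob
  rho <- numeric(nrow(pairs))
  n_on <- sum(on)
  if (n_on > 0)
    rho[on] <- sample(c(-1, 1), n_on, replace = TRUE) *
      runif(n_on, partial_range[1], partial_range[2])
  R <- diag(p)
  for (e in seq_len(nrow(pairs))) {
    R[pairs[e, 1], pairs[e, 2]] <- rho[e]
    R[pairs[e, 2], pairs[e, 1]] <- rho[e]
  }
  precision_from_partial(R)
}

# Partial-correlation matrix (unit diagonal) -> SPD precision with unit
# partial variances. K_jl = -rho_jl; the diagonal-dominance repair (raise
# deficient diagonals to the absolute off-diagonal row sum plus 0.05) is
# applied only when the assembled matrix is not safely positive definite,
# so nominal partial correlations are preserved whenever possible.
precision_from_partial <- function(R) {
  p <- nrow(R)
  K <- -R
  diag(K) <- 1
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0.05) {
    offsum <- rowSums(abs(K)) - abs(diag(K))
    bump <- which(offsum >= diag(K))
    if (length(bump))
      diag(K)[bump] <- offsum[bump] + 0.05
    d <- 1 / sqrt(diag(K))
    K <- K * (d %o% d)  # congruence: stays SPD, unit diagonal
  }
  edges <- which(upper.tri(R) & R != 0, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  rho_out <- R
  diag(rho_out) <- 0
  list(precision = K, partial_cor = rho_out, edges = edges)
}

#' Generate null-hypothesis data for the Gaussian graphical model study
#'
#' Multivariate normal data N(0, Sigma) with a sparse conditional
#' dependence structure (edge probability 0.2 by default) and an
#' auxiliary variable v drawn i.i.d. uniform(0, 1), independent of the
#' data — i.e. parameter invariance holds.
#'
#' @param p number of nodes.
#' @param n sample size.
#' @param edge_prob probability that a node pair interacts (default 0.2).
#' @return list with `data` (n x p), `v` (length n), `spec` (list with
#'   `mu`, `precision`, `partial_cor`, `edges`).
#' @export
generate_ggm_h0 <- function(p, n, edge_prob = 0.2) {
  stopifnot(p >= 2, n >= 1)
  g <- make_sparse_precision(p, edge_prob)
  Sigma <- chol2inv(chol(g$precision))
  data <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  if (n == 1) data <- matrix(data, 1, p)
  colnames(data) <- paste0("y", seq_len(p))
  list(data = data,
       v = runif(n),
       spec = list(mu = rep(0, p), precision = g$precision,
                   partial_cor = g$partial_cor, edges = g$edges))
}

#' Generate null-hypothesis data for the linear regression study
#'
#' Covariates i.i.d. standard normal, all regression coefficients zero,
#' unit error variance, and v i.i.d. uniform(0, 1) independent of
#' everything.
#'
#' @param q number of covariates.
#' @param n sample size.
#' @return list with `design` (n x q, no intercept column), `response`,
#'   `v`.
#' @export
generate_linear_h0 <- function(q, n) {
  stopifnot(q >= 1, n >= 1)
  X <- matrix(rnorm(n * q), n, q)
  colnames(X) <- paste0("x", seq_len(q))
  list(design = X, response = rnorm(n), v = runif(n))
}

#' Generate two-subgroup alternative data for the GGM study
#'
#' A base sparse network is drawn as under the null; observations whose v
#' falls below the `changepoint` quantile come from the base model, the
#' rest from a modified model in which `n_changed_edges` randomly chosen
#' existing edges have their partial correlation shifted by +`delta_theta`
#' (clipped to 0.95 in absolute value; the diagonal-dominance repair keeps
#' the precision SPD). If the base graph has too few edges, edges are
#' force-added with weight drawn as usual.
#'
#' @param p number of nodes.
#' @param n total sample size.
#' @param edge_prob edge probability of the base graph (default 0.2).
#' @param delta_theta size of the partial-correlation shift (>= 0).
#' @param n_changed_edges number of shifted edges (default 1).
#' @param changepoint fraction of v below which the base model applies
#'   (default 0.5, i.e. a split at the median).
#' @return list with `data`, `v`, `spec_lower`, `spec_upper`,
#'   `changed_edges` (2-column matrix).
#' @export
generate_ggm_alternative <- function(p, n, edge_prob = 0.2,
                                     delta_theta = 0.3,
                                     n_changed_edges = 1L,
                                     changepoint = 0.5) {
  stopifnot(p >= 2, n >= 2, delta_theta >= 0, n_changed_edges >= 1)
  g <- make_sparse_precision(p, edge_prob)
  R <- g$partial_cor
  diag(R) <- 1
  # ensure enough edges to change
  have <- g$edges
  if (nrow(have) < n_changed_edges) {
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    free <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in%
                      paste(have[, 1], have[, 2])), , drop = FALSE]
    add <- free[sample.int(nrow(free), n_changed_edges - nrow(have)), ,
                drop = FALSE]
    for (e in seq_len(nrow(add))) {
      w <- sample(c(-1, 1), 1) * runif(1, 0.1, 0.4)
      R[add[e, 1], add[e, 2]] <- R[add[e, 2], add[e, 1]] <- w
    }
    have <- rbind(have, add)
  }
  pick <- have[sample.int(nrow(have), n_changed_edges), , drop = FALSE]
  R2 <- R
  for (e in seq_len(nrow(pick))) {
    j <- pick[e, 1]; l <- pick[e, 2]
    shifted <- max(-0.95, min(0.95, R[j, l] + delta_theta))
    R2[j, l] <- R2[l, j] <- shifted
  }
  base <- precision_from_partial(R)
  alt <- precision_from_partial(R2)
  v <- runif(n)
  lower <- v < quantile(v, changepoint)
  data <- matrix(NA_real_, n, p)
  Sig1 <- chol2inv(chol(base$precision))
  Sig2 <- chol2inv(chol(alt$precision))
  n1 <- sum(lower)
  if (n1 > 0)
    data[lower, ] <- MASS::mvrnorm(n1, rep(0, p), Sig1)
  if (n - n1 > 0)
    data[!lower, ] <- MASS::mvrnorm(n - n1, rep(0, p), Sig2)
  colnames(data) <- paste0("y", seq_len(p))
  list(data = data, v = v,
       spec_lower = base, spec_upper = alt, changed_edges = pick)
}
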