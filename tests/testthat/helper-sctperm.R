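# Build an sct_efp object from an explicit (n+1) x k process matrix,
# for feeding hand-constructed processes to the statistics.
make_efp <- function(B) {
  B <- as.matrix(B)
  n <- nrow(B) - 1L
  structure(list(B = B, t_grid = seq(0, 1, length.out = n + 1L),
                 n = n, k = ncol(B)),
            class = "sct_efp")
}

# Central finite differences of f at x (vector-valued f not needed here).
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Multivariate normal log-density of one observation, parametrized by
# (mu, diag K, upper-triangle K row-major), with each off-diagonal pair
# tied to a single free parameter.
mvn_logdens_param <- function(theta, y, p) {
  mu <- theta[seq_len(p)]
  K <- diag(theta[p + seq_len(p)], p)
  ut <- which(upper.tri(K), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  off <- theta[2 * p + seq_len(nrow(ut))]
  for (e in seq_len(nrow(ut))) {
    K[ut[e, 1], ut[e, 2]] <- off[e]
    K[ut[e, 2], ut[e, 1]] <- off[e]
  }
  d <- y - mu
  0.5 * determinant(K, logarithm = TRUE)$modulus - (p / 2) * log(2 * pi) -
    0.5 * as.numeric(t(d) %*% K %*% d)
}

# Brute-force statistic implementations: explicit double loops, kept
# deliberately independent of the package's vectorized code paths.
brute_dm <- function(B) {
  n <- nrow(B) - 1L
  out <- 0
  for (i in seq_len(n - 1)) for (j in seq_len(ncol(B)))
    out <- max(out, abs(B[i + 1, j]))
  out
}
brute_cvm <- function(B) {
  n <- nrow(B) - 1L
  out <- 0
  for (i in seq_len(n)) for (j in seq_len(ncol(B)))
    out <- out + B[i + 1, j]^2
  out / n
}
brute_maxlm <- function(B, i_lo, i_hi) {
  n <- nrow(B) - 1L
  out <- 0
  for (i in i_lo:i_hi) {
    t <- i / n
    s <- 0
    for (j in seq_len(ncol(B))) s <- s + B[i + 1, j]^2
    out <- max(out, s / (t * (1 - t)))
  }
  out
}
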