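#' Order score rows along the auxiliary variable
#'
#' Stable ascending sort of the score rows by the auxiliary variable `v`;
#' ties keep their original relative order so results are reproducible.
#' Works for continuous and binary-coded orderings alike.
#'
#' @param scores numeric n x k score matrix.
#' @param v numeric (or binary-coded numeric/logical/factor) vector, length n.
#' @return list with `scores` (row-reordered matrix), `order` (the
#'   permutation applied), `v_sorted`, and `v_kind`
#'   (`"continuous"` or `"binary"`).
#' @export
order_scores <- function(scores, v) {
  S <- as.matrix(scores)
  if (is.factor(v) || is.logical(v)) v <- as.numeric(v)
  v <- as.numeric(v)
  if (length(v) != nrow(S)) stop("length(v) must equal nrow(scores)")
  if (anyNA(v)) stop("NA in auxiliary variable")
  if (length(unique(v)) == 1L) stop("auxiliary variable is constant")
  ord <- order(v)  # radix sort for doubles: stable
  list(scores = S[ord, , drop = FALSE],
       order = ord,
       v_sorted = v[ord],
       v_kind = if (length(unique(v)) == 2L) "binary" else "continuous")
}

#' Cumulate ordered scores into the raw fluctuation process
#'
#' \eqn{\Psi(i/n) = n^{-1/2} \sum_{m \le i} s_m}, returned on the full grid
#' t = 0, 1/n, ..., 1 as an (n+1) x k matrix whose first row is zero and
#' whose last row is (numerically) zero at the MLE.
#'
#' @param ordered_scores numeric n x k matrix, already ordered along v.
#' @return numeric (n+1) x k matrix.
#' @export
cumulate <- function(ordered_scores) {
  S <- as.matrix(ordered_scores)
  if (!all(is.finite(S))) stop("non-finite scores")
  n <- nrow(S)
  psi <- rbind(0, apply(S, 2, cumsum) / sqrt(n))
  if (ncol(S) == 1L) psi <- matrix(psi, ncol = 1L)
  rownames(psi) <- NULL
  colnames(psi) <- colnames(S)
  psi
}

#' Inverse symmetric square root of an information matrix
#'
#' Eigendecomposition-based symmetric root; errors (rather than silently
#' regularizing) when the matrix is numerically singular.
#'
#' @param info symmetric PSD k x k matrix.
#' @param tol relative eigenvalue tolerance below which the matrix is
#'   declared singular.
#' @return symmetric k x k matrix \eqn{\hat I^{-1/2}}.
#' @export
inv_sqrt_information <- function(info, tol = 1e-10) {
  info <- as.matrix(info)
  eg <- eigen((info + t(info)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) <= tol * max(lam))
    stop(sprintf(
      "information matrix is numerically singular (smallest eigenvalue %.3e, largest %.3e)",
      min(lam), max(lam)))
  eg$vectors %*% (t(eg$vectors) / sqrt(lam))
}

#' Decorrelate the cumulative-score process
#'
#' Premultiplies each row of \eqn{\Psi} by \eqn{\hat I^{-1/2}} so the k
#' component processes are asymptotically independent standard Brownian
#' bridges under parameter invariance.
#'
#' @param psi numeric (n+1) x k cumulative-score matrix from [cumulate()].
#' @param info k x k information estimate from [opg_information()].
#' @return object of class `sct_efp`: list with `B` ((n+1) x k matrix),
#'   `t_grid`, `n`, `k`.
#' @export
decorrelate <- function(psi, info) {
  psi <- as.matrix(psi)
  n <- nrow(psi) - 1L
  k <- ncol(psi)
  W <- inv_sqrt_information(info)
  B <- psi %*% W
  colnames(B) <- colnames(psi)
  structure(list(B = B, t_grid = seq(0, 1, length.out = n + 1L),
                 n = n, k = k),
            class = "sct_efp")
}

#' Empirical fluctuation process of a fitted model
#'
#' Convenience wrapper: orders the fitted scores along `v`, cumulates, and
#' decorrelates with the fit's OPG information.
#'
#' @param fit an `sct_fit` object.
#' @param v auxiliary ordering variable, length n.
#' @return an `sct_efp` object (see [decorrelate()]).
#' @export
#' @examples
#' set.seed(7)
#' d <- generate_ggm_h0(p = 4, n = 150)
#' efp <- fluctuation_process(fit_ggm(d$data), d$v)
#' max(abs(efp$B[nrow(efp$B), ]))  # pinned to ~0 at t = 1
fluctuation_process <- function(fit, v) {
  stopifnot(inherits(fit, "sct_fit"))
  os <- order_scores(fit$scores, v)
  efp <- decorrelate(cumulate(os$scores), fit$information)
  efp$v_sorted <- os$v_sorted
  efp$v_kind <- os$v_kind
  efp
}

#' @export
print.sct_efp <- function(x, ...) {
  cat(sprintf("Empirical fluctuation process: n = %d, k = %d\n", x$n, x$k))
  cat(sprintf("  ||B(1)||_inf = %.2e (pinned at the MLE)\n",
              max(abs(x$B[nrow(x$B), ]))))
  invisible(x)
}

#' Tidy (long) export of a fluctuation process
#'
#' @param x an `sct_efp` object.
#' @param ... unused.
#' @return data.frame with columns `t`, `parameter`, `value`,
#'   (n+1) rows per parameter.
#' @export
as.data.frame.sct_efp <- function(x, ...) {
  k <- x$k
  nm <- colnames(x$B)
  if (is.null(nm)) nm <- paste0("theta", seq_len(k))
  data.frame(t = rep(x$t_grid, k),
             parameter = rep(nm, each = length(x$t_grid)),
             value = as.vector(x$B),
             stringsAsFactors = FALSE)
}

#' Write a fluctuation process as tidy CSV
#'
#' @param x an `sct_efp` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_efp_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
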