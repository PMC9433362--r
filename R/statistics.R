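#' Trimming specification for the maxLM scan
#'
#' The maxLM statistic weights the process by \eqn{(t(1-t))^{-1}}, which
#' blows up near the endpoints, so its scan excludes the tails. The window
#' is expressed either as observation counts (`mode = "count"`, scan
#' i in [lower, n - upper]) or as fractions (`mode = "fraction"`, scan
#' i in [ceil(lower * n), floor((1 - upper) * n)]).
#'
#' @param mode `"fraction"` or `"count"`.
#' @param lower,upper nonnegative trim amounts (fractions or counts).
#' @return object of class `trim_spec`.
#' @export
trim_spec <- function(mode = c("fraction", "count"), lower, upper = lower) {
  mode <- match.arg(mode)
  if (lower < 0 || upper < 0) stop("trim amounts must be nonnegative")
  structure(list(mode = mode, lower = lower, upper = upper),
            class = "trim_spec")
}

#' Default trimming rule per model
#'
#' GGM: scan i in [n_p, n - n_p] where n_p = p(p+3)/2 is the number of
#' free parameters. Linear model: cut the bottom and upper 10%. When the
#' count-mode window is empty (n_p > n/2, as for p = 15 with n = 200),
#' falls back to symmetric 10% fraction trimming with a warning, since the
#' stated rule cannot be applied at that n.
#'
#' @param model_kind `"linear"` or `"ggm"`.
#' @param n sample size.
#' @param n_p number of free model parameters (required for `"ggm"`).
#' @return a `trim_spec`.
#' @export
default_trim <- function(model_kind = c("linear", "ggm"), n, n_p = NULL) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "ggm") {
    if (is.null(n_p)) stop("n_p is required for the GGM trimming rule")
    if (n_p > n - n_p) {
      warning(sprintf(
        "GGM trim window [%d, %d] is empty (n_p > n/2); falling back to 10%% fraction trimming",
        n_p, n - n_p))
      return(trim_spec("fraction", 0.1))
    }
    return(trim_spec("count", n_p, n_p))
  }
  trim_spec("fraction", 0.1)
}

#' Resolve a trim specification to an index window
#'
#' @param trim a `trim_spec` or `NULL` (no trimming: scan i in [1, n-1]).
#' @param n sample size (grid size of the process).
#' @return integer vector `c(i_lo, i_hi)` with 1 <= i_lo <= i_hi <= n-1.
#' @export
trim_window <- function(trim, n) {
  n <- as.integer(n)
  if (is.null(trim)) return(c(1L, n - 1L))
  stopifnot(inherits(trim, "trim_spec"))
  if (trim$mode == "fraction") {
    i_lo <- max(1L, as.integer(ceiling(trim$lower * n)))
    i_hi <- min(n - 1L, as.integer(floor((1 - trim$upper) * n)))
  } else {
    i_lo <- max(1L, as.integer(trim$lower))
    i_hi <- min(n - 1L, as.integer(n - trim$upper))
  }
  if (i_lo > i_hi)
    stop(sprintf(
      "empty maxLM trim window [%d, %d] at n = %d: use a larger sample size or a looser trim",
      i_lo, i_hi, n))
  c(i_lo, i_hi)
}

new_statistic <- function(name, value, n, k, trim = NULL) {
  structure(list(name = name, value = value, n = n, k = k, trim = trim),
            class = "sct_statistic")
}

#' @export
print.sct_statistic <- function(x, ...) {
  cat(sprintf("%s statistic = %.6g  (n = %d, k = %d)\n",
              x$name, x$value, x$n, x$k))
  invisible(x)
}

#' Double-maximum (DM) statistic
#'
#' \eqn{\max_{i,j} |B_{ij}|} over interior grid points i = 1..n-1: flags
#' any single process straying too far from zero at any point.
#'
#' @param proc an `sct_efp` object.
#' @return an `sct_statistic`.
#' @export
dm_statistic <- function(proc) {
  stopifnot(inherits(proc, "sct_efp"))
  n <- proc$n
  interior <- proc$B[seq(2L, n), , drop = FALSE]
  new_statistic("DM", max(abs(interior)), n, proc$k)
}

#' Cramer-von Mises (CvM) statistic
#'
#' \eqn{n^{-1} \sum_{i=1}^{n} \sum_j B_{ij}^2}: an average squared
#' deviation, sensitive to fluctuations spread over many observations and
#' parameters. The pinned final point contributes (numerically) nothing.
#'
#' @param proc an `sct_efp` object.
#' @return an `sct_statistic`.
#' @export
cvm_statistic <- function(proc) {
  stopifnot(inherits(proc, "sct_efp"))
  n <- proc$n
  rows <- proc$B[seq(2L, n + 1L), , drop = FALSE]
  new_statistic("CvM", sum(rows^2) / n, n, proc$k)
}

#' Maximum Lagrange Multiplier (maxLM) statistic
#'
#' \eqn{\max_{i \in [i_{lo}, i_{hi}]} (\tfrac{i}{n}(1-\tfrac{i}{n}))^{-1}
#' \sum_j B_{ij}^2}: the LM test for a single break at i, maximized over
#' candidate break points inside the trimmed window. Suited when all k
#' processes change at the same observation.
#'
#' @param proc an `sct_efp` object.
#' @param trim a `trim_spec`, or `NULL` for no trimming.
#' @return an `sct_statistic` (with the trim attached).
#' @export
maxlm_statistic <- function(proc, trim = NULL) {
  stopifnot(inherits(proc, "sct_efp"))
  n <- proc$n
  w <- trim_window(trim, n)
  idx <- seq(w[1], w[2])
  tt <- idx / n
  rows <- proc$B[idx + 1L, , drop = FALSE]
  lm_i <- rowSums(rows^2) / (tt * (1 - tt))
  new_statistic("maxLM", max(lm_i), n, proc$k, trim = trim)
}

#' Compute a named statistic on a fluctuation process
#'
#' @param proc an `sct_efp` object.
#' @param statistic `"maxlm"`, `"dm"`, or `"cvm"`.
#' @param trim a `trim_spec` (used by maxLM only).
#' @return an `sct_statistic`.
#' @export
compute_statistic <- function(proc, statistic = c("maxlm", "dm", "cvm"),
                              trim = NULL) {
  statistic <- match.arg(statistic)
  switch(statistic,
         maxlm = maxlm_statistic(proc, trim),
         dm = dm_statistic(proc),
         cvm = cvm_statistic(proc))
}

stat_code <- function(statistic) {
  switch(match.arg(statistic, c("maxlm", "dm", "cvm")),
         dm = 1L, cvm = 2L, maxlm = 3L)
}
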