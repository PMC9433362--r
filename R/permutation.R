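#' Monte Carlo permutation test for parameter invariance
#'
#' Rebuilds the fluctuation process under random rearrangements of the
#' auxiliary variable and compares the observed statistic against the
#' resampled ones. Under the invariance null the ordering of observations
#' along v is exchangeable, so the permutation distribution is a valid
#' null reference at any sample size — unlike the Brownian-bridge
#' asymptotics, which degrade in small samples and large models.
#'
#' The full-data MLE, scores and information do not depend on row order,
#' so nothing is refitted: the decorrelated score rows are permuted
#' uniformly (equivalent to permuting v), cumulated, and re-aggregated.
#' The decorrelation matrix \eqn{\hat I^{-1/2}} is computed once. The
#' p value uses the standard +1 correction,
#' p = (1 + #\{permuted >= observed\}) / (n_perm + 1), which keeps the
#' test valid at level alpha and the p value strictly positive.
#'
#' @param model an `sct_fit` object (fitted on the full data).
#' @param v auxiliary ordering variable, length n.
#' @param statistic `"maxlm"` (default), `"dm"`, or `"cvm"`.
#' @param trim a `trim_spec`; default [default_trim()] for the model.
#' @param n_perm number of random rearrangements (default 5000).
#' @param seed optional integer seed (seeded locally when supplied).
#' @param keep_permuted keep the full vector of permuted statistics in
#'   the result (default `TRUE`).
#' @return object of class `sct_perm_result`: `observed`
#'   (`sct_statistic`), `permuted`, `exceed_count`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
#' @examples
#' set.seed(11)
#' d <- generate_ggm_h0(p = 4, n = 150)
#' fit <- fit_ggm(d$data)
#' permutation_test(fit, d$v, n_perm = 199, seed = 1)
permutation_test <- function(model, v,
                             statistic = c("maxlm", "dm", "cvm"),
                             trim = NULL, n_perm = 5000L, seed = NULL,
                             keep_permuted = TRUE) {
  stopifnot(inherits(model, "sct_fit"))
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 100)
    warning("n_perm < 100: p-value resolution is coarse")
  if (is.null(trim) && statistic == "maxlm")
    trim <- default_trim(model$model_kind, model$n, model$n_free)

  os <- order_scores(model$scores, v)
  W <- inv_sqrt_information(model$information)
  U <- os$scores %*% W  # v-ordered, decorrelated score rows
  proc <- structure(list(B = rbind(0, apply(U, 2, cumsum) / sqrt(model$n)),
                         t_grid = seq(0, 1, length.out = model$n + 1L),
                         n = model$n, k = model$k),
                    class = "sct_efp")
  observed <- compute_statistic(proc, statistic, trim)

  w <- if (statistic == "maxlm") trim_window(trim, model$n)
       else c(1L, model$n - 1L)
  draw <- function() perm_stat_sample_cpp(U, as.integer(n_perm),
                                          stat_code(statistic), w[1], w[2])
  permuted <- if (is.null(seed)) draw() else local_seed(seed, draw())

  exceed <- sum(permuted >= observed$value)
  structure(list(observed = observed,
                 permuted = if (keep_permuted) permuted else NULL,
                 exceed_count = exceed,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = as.integer(n_perm),
                 seed = seed),
            class = "sct_perm_result")
}

#' @export
print.sct_perm_result <- function(x, ...) {
  cat(sprintf("Monte Carlo permutation test (%s statistic)\n",
              x$observed$name))
  cat(sprintf("  observed = %.6g, n_perm = %d, exceedances = %d\n",
              x$observed$value, x$n_perm, x$exceed_count))
  cat(sprintf("  p value = %.4g\n", x$p_value))
  invisible(x)
}
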