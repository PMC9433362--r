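#' Structural change test of parameter invariance
#'
#' The full three-step score-based SCT: fit the model on all data,
#' derive the decorrelated empirical fluctuation process along the
#' auxiliary variable, aggregate it into a scalar statistic, and compute
#' the p value against the simulated Brownian-bridge null, the Monte
#' Carlo permutation null, or both.
#'
#' @param data numeric matrix or data frame. For `model = "linear"`,
#'   `response` names the response column and the remaining columns
#'   (minus `order_by`) form the design; for `model = "ggm"` all columns
#'   except `order_by` are modelled jointly.
#' @param order_by the auxiliary variable: either a column name in
#'   `data` (excluded from the model) or a numeric vector of length n.
#' @param model `"ggm"` or `"linear"`.
#' @param response response column name (linear model only).
#' @param statistic `"maxlm"` (default), `"dm"`, or `"cvm"`.
#' @param method `"both"` (default), `"asymptotic"`, or `"permutation"`.
#' @param trim a `trim_spec`; defaults to [default_trim()] for the model
#'   (maxLM only).
#' @param n_perm permutations for the permutation null (default 5000).
#' @param n_sim Brownian-bridge draws for the asymptotic null (default
#'   20000).
#' @param seed integer seed for both Monte Carlo nulls (required when
#'   they are used; no silent clock seeding).
#' @return object of class `sct_test`: the fit, the fluctuation process,
#'   the observed statistic, and `p_asymptotic` / `p_permutation` as
#'   requested.
#' @export
#' @examples
#' set.seed(3)
#' d <- generate_ggm_h0(p = 4, n = 200)
#' sct_test(d$data, order_by = d$v, model = "ggm",
#'          n_perm = 499, n_sim = 2000, seed = 42)
sct_test <- function(data, order_by, model = c("ggm", "linear"),
                     response = NULL,
                     statistic = c("maxlm", "dm", "cvm"),
                     method = c("both", "asymptotic", "permutation"),
                     trim = NULL, n_perm = 5000L, n_sim = 20000L,
                     seed = NULL) {
  model <- match.arg(model)
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (is.null(seed))
    stop("an explicit integer `seed` is required for the Monte Carlo nulls")

  if (is.character(order_by) && length(order_by) == 1L) {
    if (!order_by %in% colnames(data))
      stop("order_by column '", order_by, "' not found in data")
    if (!is.null(response) && identical(order_by, response))
      stop("order_by and response must be distinct columns")
    v <- as.numeric(data[[order_by]])
    data <- data[, setdiff(colnames(data), order_by), drop = FALSE]
  } else {
    v <- as.numeric(order_by)
  }

  if (model == "linear") {
    if (is.null(response)) stop("`response` is required for the linear model")
    if (!response %in% colnames(data))
      stop("response column '", response, "' not found in data")
    y <- as.numeric(data[[response]])
    X <- as.matrix(data[, setdiff(colnames(data), response), drop = FALSE])
    fit <- fit_linear(X, y)
  } else {
    if (!is.null(response))
      stop("`response` must be absent for the GGM (all columns are modelled)")
    fit <- fit_ggm(as.matrix(data))
  }

  if (is.null(trim) && statistic == "maxlm")
    trim <- default_trim(fit$model_kind, fit$n, fit$n_free)
  proc <- fluctuation_process(fit, v)
  observed <- compute_statistic(proc, statistic, trim)

  p_asym <- p_perm <- NULL
  if (method %in% c("both", "asymptotic")) {
    ref <- build_reference(statistic, k = fit$k, grid_n = fit$n,
                           trim = trim, n_sim = n_sim, seed = seed)
    p_asym <- asymptotic_pvalue(observed, ref)
  }
  if (method %in% c("both", "permutation")) {
    pr <- permutation_test(fit, v, statistic, trim = trim,
                           n_perm = n_perm, seed = seed + 1L,
                           keep_permuted = FALSE)
    p_perm <- pr$p_value
  }
  structure(list(fit = fit, process = proc, observed = observed,
                 statistic = statistic, method = method, trim = trim,
                 p_asymptotic = p_asym, p_permutation = p_perm,
                 n_perm = if (is.null(p_perm)) NULL else as.integer(n_perm),
                 n_sim = if (is.null(p_asym)) NULL else as.integer(n_sim),
                 seed = seed),
            class = "sct_test")
}

#' @export
print.sct_test <- function(x, ...) {
  cat(sprintf("Structural change test (%s model, %s statistic)\n",
              x$fit$model_kind, x$observed$name))
  cat(sprintf("  n = %d, k = %d tested parameters\n", x$fit$n, x$fit$k))
  if (!is.null(x$trim)) {
    w <- trim_window(x$trim, x$fit$n)
    cat(sprintf("  maxLM scan window: observations %d..%d\n", w[1], w[2]))
  }
  cat(sprintf("  observed statistic = %.6g\n", x$observed$value))
  if (!is.null(x$p_asymptotic))
    cat(sprintf("  p (asymptotic, %d bridge draws) = %.4g\n",
                x$n_sim, x$p_asymptotic))
  if (!is.null(x$p_permutation))
    cat(sprintf("  p (permutation, %d rearrangements) = %.4g\n",
                x$n_perm, x$p_permutation))
  invisible(x)
}
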