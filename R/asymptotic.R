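#' Simulate one k-dimensional Brownian bridge on a discrete grid
#'
#' Each column is a cumulative sum of i.i.d. N(0, 1/grid_n) increments,
#' pinned by subtracting t * W(1). Returned on the full grid including
#' both (exactly zero) endpoints. Used for small-scale checks; the mass
#' production of null references runs in compiled code
#' ([build_reference()]).
#'
#' @param grid_n number of increments (grid resolution).
#' @param k number of independent components.
#' @return numeric (grid_n + 1) x k matrix.
#' @export
simulate_bridge <- function(grid_n, k = 1L) {
  if (grid_n < 2) stop("grid_n must be at least 2")
  incr <- matrix(rnorm(grid_n * k, sd = 1 / sqrt(grid_n)), grid_n, k)
  W <- apply(incr, 2, cumsum)
  if (k == 1L) W <- matrix(W, ncol = 1L)
  tt <- seq_len(grid_n) / grid_n
  B <- W - tt %o% W[grid_n, ]
  B[grid_n, ] <- 0  # pin exactly
  rbind(0, B)
}

#' Monte Carlo reference distribution of a statistic under the bridge null
#'
#' Draws `n_sim` independent k-dimensional Brownian bridges on a grid of
#' size `grid_n`, applies the statistic (with the same trimming as the
#' observed data), and stores the sorted values. Asymptotic p values are
#' exceedance proportions against this reference.
#'
#' @param statistic `"maxlm"`, `"dm"`, or `"cvm"`.
#' @param k number of tested parameters.
#' @param grid_n grid size; use the observed sample size n so the trim
#'   window maps one-to-one onto the bridge grid.
#' @param trim a `trim_spec` or `NULL` (maxLM only).
#' @param n_sim number of Monte Carlo draws (default 20000).
#' @param seed optional integer; when supplied the RNG is seeded locally
#'   so the reference is reproducible without disturbing the caller's
#'   RNG state.
#' @return object of class `sct_null_reference`.
#' @export
build_reference <- function(statistic = c("maxlm", "dm", "cvm"), k, grid_n,
                            trim = NULL, n_sim = 20000L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_sim < 1000)
    warning("n_sim < 1000: p values from this reference are coarse")
  w <- if (statistic == "maxlm") trim_window(trim, grid_n) else c(1L, grid_n - 1L)
  draw <- function() bridge_stat_reference_cpp(as.integer(n_sim),
                                               as.integer(grid_n),
                                               as.integer(k),
                                               stat_code(statistic),
                                               w[1], w[2])
  values <- if (is.null(seed)) draw() else local_seed(seed, draw())
  structure(list(statistic_name = toupper(statistic),
                 statistic = statistic,
                 values = sort(values),
                 k = as.integer(k), grid_n = as.integer(grid_n),
                 trim = trim, n_sim = as.integer(n_sim), seed = seed),
            class = "sct_null_reference")
}

local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' @export
print.sct_null_reference <- function(x, ...) {
  cat(sprintf("Simulated %s null reference: k = %d, grid_n = %d, n_sim = %d\n",
              x$statistic_name, x$k, x$grid_n, x$n_sim))
  cat(sprintf("  quantiles 90/95/99%%: %.4g / %.4g / %.4g\n",
              quantile(x$values, 0.90), quantile(x$values, 0.95),
              quantile(x$values, 0.99)))
  invisible(x)
}

#' CDF of the supremum of the absolute Brownian bridge
#'
#' The Kolmogorov distribution
#' \deqn{P(\sup_t |B^0(t)| \le x) = 1 + 2\sum_{j\ge1} (-1)^j e^{-2 j^2 x^2},}
#' truncated once terms fall below 1e-12. This is the closed-form large-n
#' law of the DM statistic with k = 1, used as an independent check of the
#' simulated reference.
#'
#' @param x positive real (values <= 0 return 0).
#' @return probability.
#' @export
kolmogorov_sup_cdf <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    total <- 1
    j <- 1
    repeat {
      term <- 2 * (-1)^j * exp(-2 * j^2 * xi^2)
      total <- total + term
      if (abs(term) < 1e-12) break
      j <- j + 1
    }
    max(0, min(1, total))
  }, numeric(1))
}

#' Asymptotic p value from a simulated null reference
#'
#' Plain exceedance proportion: p = #\{reference >= observed\} / n_sim.
#'
#' @param observed an `sct_statistic`.
#' @param ref an `sct_null_reference` with matching statistic name and k.
#' @return probability.
#' @export
asymptotic_pvalue <- function(observed, ref) {
  stopifnot(inherits(observed, "sct_statistic"),
            inherits(ref, "sct_null_reference"))
  if (toupper(observed$name) != ref$statistic_name)
    stop("statistic name mismatch between observed value and reference")
  if (observed$k != ref$k)
    stop("parameter dimension mismatch between observed value and reference")
  mean(ref$values >= observed$value)
}

#' Save / load a null reference as JSON
#'
#' Cache keyed by (statistic, k, grid_n, trim, n_sim, seed): reuse a
#' reference across replications with the same design.
#'
#' @param ref an `sct_null_reference`.
#' @param path file path.
#' @return `path` (save) or the restored `sct_null_reference` (load).
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "sct_null_reference"))
  obj <- unclass(ref)
  obj$trim <- if (is.null(ref$trim)) NULL else unclass(ref$trim)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$values <- as.numeric(obj$values)
  if (!is.null(obj$trim))
    obj$trim <- structure(obj$trim, class = "trim_spec")
  structure(obj, class = "sct_null_reference")
}
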