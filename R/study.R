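#' Type-I-error (null calibration) study
#'
#' Replicates the null design `n_reps` times; for each replicate, fits
#' the model, and computes the p value of the chosen statistic by the
#' asymptotic (simulated Brownian-bridge) method, the Monte Carlo
#' permutation method, or both. The asymptotic reference is built once
#' per design (same n, k and trim for every replicate) and reused.
#'
#' @param model_kind `"ggm"` or `"linear"`.
#' @param k_or_p nodes (ggm) or covariates (linear; intercept added and
#'   tested, so k = q + 1).
#' @param n sample size per replicate.
#' @param n_reps number of replicates (default 500).
#' @param edge_prob ggm edge probability (default 0.2).
#' @param methods subset of `c("asymptotic", "permutation")`.
#' @param statistic `"maxlm"`, `"dm"`, or `"cvm"`.
#' @param n_perm permutations per replicate (default 1000).
#' @param n_sim Brownian-bridge draws for the asymptotic reference.
#' @param alpha nominal level for the rejection-rate summary.
#' @param seed integer seed for the whole study (default 1).
#' @param progress print a note every 100 replicates.
#' @return object of class `sct_study`: `p_values` (n_reps x methods
#'   matrix), `rejection_rate`, `ks_stat`, `ks_pvalue` (KS test against
#'   uniform), `design`.
#' @export
run_type1_study <- function(model_kind = c("ggm", "linear"), k_or_p, n,
                            n_reps = 500L, edge_prob = 0.2,
                            methods = c("asymptotic", "permutation"),
                            statistic = "maxlm", n_perm = 1000L,
                            n_sim = 20000L, alpha = 0.05, seed = 1L,
                            progress = FALSE) {
  model_kind <- match.arg(model_kind)
  methods <- match.arg(methods, c("asymptotic", "permutation"),
                       several.ok = TRUE)
  gen <- function() {
    if (model_kind == "ggm") {
      d <- generate_ggm_h0(k_or_p, n, edge_prob)
      list(fit = fit_ggm(d$data), v = d$v)
    } else {
      d <- generate_linear_h0(k_or_p, n)
      list(fit = fit_linear(d$design, d$response), v = d$v)
    }
  }
  run_study_engine(gen, n_reps, methods, statistic, n_perm, n_sim, alpha,
                   seed, progress,
                   design = list(hypothesis = "H0", model_kind = model_kind,
                                 k_or_p = k_or_p, n = n,
                                 edge_prob = edge_prob, n_reps = n_reps,
                                 statistic = statistic, n_perm = n_perm,
                                 n_sim = n_sim, alpha = alpha, seed = seed))
}

#' Power study under a two-subgroup GGM alternative
#'
#' As [run_type1_study()], but each replicate draws data whose
#' precision-matrix structure shifts by `delta_theta` (on the
#' partial-correlation scale) on `n_changed_edges` edges for the
#' observations above the v changepoint.
#'
#' @inheritParams run_type1_study
#' @inheritParams generate_ggm_alternative
#' @return an `sct_study` object; `rejection_rate` is the power at
#'   `alpha`.
#' @export
run_power_study <- function(k_or_p, n, delta_theta, n_reps = 500L,
                            edge_prob = 0.2, n_changed_edges = 1L,
                            changepoint = 0.5,
                            methods = c("asymptotic", "permutation"),
                            statistic = "maxlm", n_perm = 1000L,
                            n_sim = 20000L, alpha = 0.05, seed = 1L,
                            progress = FALSE) {
  methods <- match.arg(methods, c("asymptotic", "permutation"),
                       several.ok = TRUE)
  gen <- function() {
    d <- generate_ggm_alternative(k_or_p, n, edge_prob, delta_theta,
                                  n_changed_edges, changepoint)
    list(fit = fit_ggm(d$data), v = d$v)
  }
  run_study_engine(gen, n_reps, methods, statistic, n_perm, n_sim, alpha,
                   seed, progress,
                   design = list(hypothesis = "H1", model_kind = "ggm",
                                 k_or_p = k_or_p, n = n,
                                 delta_theta = delta_theta,
                                 n_changed_edges = n_changed_edges,
                                 changepoint = changepoint,
                                 edge_prob = edge_prob, n_reps = n_reps,
                                 statistic = statistic, n_perm = n_perm,
                                 n_sim = n_sim, alpha = alpha, seed = seed))
}

run_study_engine <- function(gen, n_reps, methods, statistic, n_perm,
                             n_sim, alpha, seed, progress, design) {
  set.seed(seed)
  pv <- matrix(NA_real_, n_reps, length(methods),
               dimnames = list(NULL, methods))
  ref <- NULL
  trim <- NULL
  for (r in seq_len(n_reps)) {
    d <- gen()
    fit <- d$fit
    if (is.null(trim) && statistic == "maxlm")
      trim <- suppressWarnings(default_trim(fit$model_kind, fit$n,
                                            fit$n_free))
    if ("asymptotic" %in% methods) {
      if (is.null(ref))
        ref <- build_reference(statistic, k = fit$k, grid_n = fit$n,
                               trim = trim, n_sim = n_sim)
      proc <- fluctuation_process(fit, d$v)
      obs <- compute_statistic(proc, statistic, trim)
      pv[r, "asymptotic"] <- asymptotic_pvalue(obs, ref)
    }
    if ("permutation" %in% methods) {
      res <- permutation_test(fit, d$v, statistic, trim = trim,
                              n_perm = n_perm, keep_permuted = FALSE)
      pv[r, "permutation"] <- res$p_value
    }
    if (progress && r %% 100 == 0)
      message(sprintf("  replicate %d / %d", r, n_reps))
  }
  rr <- colMeans(pv <= alpha)
  ks <- apply(pv, 2, function(p)
    suppressWarnings(ks.test(p, "punif"))[c("statistic", "p.value")])
  structure(list(design = design,
                 p_values = pv,
                 rejection_rate = rr,
                 ks_stat = vapply(ks, function(x) unname(x$statistic),
                                  numeric(1)),
                 ks_pvalue = vapply(ks, function(x) x$p.value, numeric(1)),
                 alpha = alpha),
            class = "sct_study")
}

#' @export
print.sct_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("SCT simulation study (%s, %s, k_or_p = %d, n = %d, %d reps)\n",
              d$hypothesis, d$model_kind, d$k_or_p, d$n, d$n_reps))
  if (!is.null(d$delta_theta))
    cat(sprintf("  delta_theta = %.2f on %d edge(s)\n",
                d$delta_theta, d$n_changed_edges))
  for (m in names(x$rejection_rate))
    cat(sprintf("  %-12s rejection at alpha = %.2f: %.3f  (KS vs uniform: D = %.3f, p = %.3g)\n",
                m, x$alpha, x$rejection_rate[m], x$ks_stat[m],
                x$ks_pvalue[m]))
  invisible(x)
}

#' Tidy per-replication results of a study
#'
#' @param x an `sct_study`.
#' @param ... unused.
#' @return data.frame with columns `rep`, `method`, `p_value`.
#' @export
as.data.frame.sct_study <- function(x, ...) {
  m <- colnames(x$p_values)
  data.frame(rep = rep(seq_len(nrow(x$p_values)), length(m)),
             method = rep(m, each = nrow(x$p_values)),
             p_value = as.vector(x$p_values),
             stringsAsFactors = FALSE)
}
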