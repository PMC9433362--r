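#' Read a numeric data table for testing
#'
#' CSV with a header row and numeric columns only. Missing values are a
#' hard error: the SCT has no principled way to impute, and silently
#' dropping rows would break the v-ordering.
#'
#' @param path CSV file path.
#' @return data.frame of numeric columns.
#' @export
read_sct_csv <- function(path) {
  df <- read.csv(path, header = TRUE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty data table: ", path)
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric columns: ", paste(non_num, collapse = ", "))
  if (anyNA(df))
    stop("missing values in data table (no imputation is performed)")
  df
}

#' Serialize a model fit to JSON
#'
#' Writes the MLE, parameter names, dimensions and model kind (not the
#' score matrix; see [write_scores_csv()] for that).
#'
#' @param fit an `sct_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sct_fit"))
  jsonlite::write_json(
    list(model_kind = fit$model_kind,
         parameter_names = names(fit$theta),
         theta = unname(fit$theta),
         n = fit$n, k = fit$k, n_free = fit$n_free),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a score matrix as CSV
#'
#' @param fit an `sct_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(fit, path) {
  stopifnot(inherits(fit, "sct_fit"))
  write.csv(as.data.frame(fit$scores), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a test result to JSON
#'
#' @param x an `sct_test` or `sct_perm_result`.
#' @param path output path.
#' @param keep_permuted include the permuted-statistic vector for
#'   `sct_perm_result` objects (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, keep_permuted = FALSE) {
  if (inherits(x, "sct_test")) {
    obj <- list(schema = "sctperm/test-report/v1",
                model_kind = x$fit$model_kind,
                n = x$fit$n, k = x$fit$k,
                statistic = x$observed$name,
                value = x$observed$value,
                trim = if (is.null(x$trim)) NULL else unclass(x$trim),
                p_asymptotic = x$p_asymptotic,
                p_permutation = x$p_permutation,
                n_perm = x$n_perm, n_sim = x$n_sim,
                seed = x$seed,
                package_version = as.character(utils::packageVersion("sctperm")))
  } else if (inherits(x, "sct_perm_result")) {
    obj <- list(schema = "sctperm/permutation-result/v1",
                statistic = x$observed$name,
                observed = x$observed$value,
                exceed_count = x$exceed_count,
                p_value = x$p_value,
                n_perm = x$n_perm, seed = x$seed)
    if (keep_permuted && !is.null(x$permuted))
      obj$permuted <- x$permuted
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a statistic value to JSON
#'
#' @param stat an `sct_statistic`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_statistic_json <- function(stat, path) {
  stopifnot(inherits(stat, "sct_statistic"))
  jsonlite::write_json(
    list(name = stat$name, value = stat$value, n = stat$n, k = stat$k,
         trim = if (is.null(stat$trim)) NULL else unclass(stat$trim)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
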