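## Matrix assembly and batch-grouped cross-validation segments.

#' Assemble a spectra matrix for multivariate modelling
#'
#' Converts a long spectra table (all spectra on one shared grid) into an
#' observations x wavenumbers matrix restricted to the modelling window
#' (250-1500 cm^-1 by default), keeping the per-spectrum metadata alongside.
#'
#' @param data A spectra table sharing one wavenumber grid.
#' @param window Length-2 wavenumber interval retained as X variables.
#' @param group Optional metadata column used as the batch/group label
#'   (default `"sample_id"` when present).
#' @return An object of class `spectra_matrix`: list with `x` (numeric
#'   matrix, rows named by spectrum), `wavenumbers`, `meta` (tibble, one row
#'   per spectrum) and `group` (label column name or `NA`).
#' @export
spectra_matrix <- function(data, window = c(250, 1500), group = NULL) {
  validate_spectra(data)
  if (!spectra_share_grid(data)) {
    abort("all spectra must share one wavenumber grid; resample first.")
  }
  window <- sort(window)
  chunks <- split_spectra(data)
  if (length(chunks) < 2) abort("at least 2 spectra are required.")
  wn <- chunks[[1]]$wavenumber
  keep <- wn >= window[1] & wn <= window[2]
  if (sum(keep) < 2) abort("modelling window captures fewer than 2 wavenumbers.")
  x <- t(vapply(chunks, function(ch) ch$intensity[keep], numeric(sum(keep))))
  meta <- dplyr::bind_rows(purrr::map(chunks, function(ch)
    ch[1, intersect(names(ch), c(SPECTRUM_ID_COLS, "processing")), drop = FALSE]))
  if (is.null(group)) group <- if ("sample_id" %in% names(meta)) "sample_id" else NA_character_
  if (!is.na(group) && !group %in% names(meta)) {
    abort(sprintf("group column `%s` not found in the spectrum metadata.", group))
  }
  rownames(x) <- if (!is.na(group)) make.unique(as.character(meta[[group]])) else NULL
  colnames(x) <- wn[keep]
  if (anyNA(x)) abort("missing values in the spectra matrix.")
  structure(list(x = x, wavenumbers = wn[keep], meta = meta, group = group),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d spectra x %d wavenumbers (%g-%g cm^-1)\n",
              nrow(x$x), ncol(x$x), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

as_matrix_input <- function(x) {
  if (inherits(x, "spectra_matrix")) x$x else as.matrix(x)
}

#' Batch-grouped cross-validation segments
#'
#' Partitions row indices into cross-validation segments such that all rows
#' sharing a group label (e.g. all spectra of one batch, from both probes)
#' always fall in the same segment.  With `n_segments = NULL` each group
#' gets its own segment; with fewer segments than groups, whole groups are
#' assigned round-robin in order of first appearance.
#'
#' @param groups Per-row group labels.
#' @param n_segments Number of segments, or `NULL` for one per group.
#' @return A list of integer index vectors (a partition of
#'   `seq_along(groups)`).
#' @export
#' @examples
#' grouped_segments(c("A", "A", "B"))  # list(1:2, 3)
grouped_segments <- function(groups, n_segments = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) abort("at least 2 distinct groups are required.")
  if (is.null(n_segments)) n_segments <- length(lv)
  n_segments <- as.integer(n_segments)
  if (n_segments < 2) abort("at least 2 segments are required.")
  if (n_segments > length(lv)) {
    abort(sprintf("cannot form %d segments from %d groups without splitting a group.",
                  n_segments, length(lv)))
  }
  assignment <- rep_len(seq_len(n_segments), length(lv))  # round-robin by group order
  seg_of_row <- assignment[match(groups, lv)]
  unname(split(seq_along(groups), seg_of_row))
}

#' Regression performance metrics
#'
#' Root mean square error, mean signed bias, explained variance
#' (`100 * (1 - Var(residual) / Var(reference))`, sample variances) and
#' Pearson correlation between predictions and reference values.  Note that
#' the explained variance uses the residual *variance*, so a pure constant
#' offset still explains 100% of the variance while showing up in the bias.
#'
#' @param truth Reference values.
#' @param estimate Predicted values, same length.
#' @return A one-row tibble: `rmse`, `bias`, `explained_variance_pct`,
#'   `pearson_r`, `n`.
#' @export
#' @examples
#' regression_metrics(c(0, 1, 2), c(0.5, 1, 1.5))
regression_metrics <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("truth and estimate lengths differ.")
  if (length(truth) < 2) abort("at least 2 observations are required.")
  resid <- estimate - truth
  vy <- var(truth)
  if (vy == 0) abort("reference values have zero variance; explained variance undefined.")
  tibble(
    rmse = sqrt(mean(resid^2)),
    bias = mean(resid),
    explained_variance_pct = 100 * (1 - var(resid) / vy),
    pearson_r = if (var(estimate) > 0) cor(estimate, truth) else NA_real_,
    n = length(truth))
}

#' Choose the number of latent factors
#'
#' Default rule (`"first_min"`): the smallest factor count beyond which the
#' validation RMSE stops improving by more than `rel_tol` (2%) relative.
#' Alternatives: `"global_min"` (factor count with the smallest RMSE) and
#' `"fixed"` (always `k`).
#'
#' @param rmsecv Validation RMSE per factor count (1, 2, ...).
#' @param rule Selection rule.
#' @param k Factor count for the `"fixed"` rule.
#' @param rel_tol Relative improvement threshold for `"first_min"`.
#' @return Selected factor count (integer).
#' @export
#' @examples
#' select_factors(c(2.0, 1.0, 0.99, 1.2))  # 2
select_factors <- function(rmsecv, rule = c("first_min", "global_min", "fixed"),
                           k = NULL, rel_tol = 0.02) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(k)) abort("the fixed rule needs `k`.")
    return(as.integer(k))
  }
  if (length(rmsecv) < 1 || any(!is.finite(rmsecv))) abort("invalid RMSE sequence.")
  if (rule == "global_min") return(which.min(rmsecv))
  for (i in seq_len(length(rmsecv) - 1)) {
    improvement <- (rmsecv[i] - rmsecv[i + 1]) / rmsecv[i]
    if (improvement <= rel_tol) return(i)
  }
  length(rmsecv)
}
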