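## NIPALS principal component analysis with grouped cross-validation.

#' NIPALS principal component analysis
#'
#' Mean-centered PCA computed component-by-component with the NIPALS
#' algorithm and deflation.  Convergence is declared when the relative
#' change of the score vector drops below `tol`.  Loadings are unit-norm
#' with a fixed sign convention (the largest-magnitude element of each
#' loading is positive) so that fitted models are reproducible.  Explained
#' calibration variance per component is
#' `100 * sum(t_k^2) / (total centered sum of squares)`.
#'
#' @param x A numeric matrix (observations x variables) or a
#'   [spectra_matrix()].
#' @param n_components Number of components to extract.
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `nipals_pca`: list with `means`, `loadings`
#'   (variables x components), `scores` (observations x components),
#'   `explained_variance` (% per component), `cumulative_variance`,
#'   `total_ss`, `meta` (when built from a `spectra_matrix`).
#' @export
nipals_pca <- function(x, n_components = 2, tol = 1e-9, max_iter = 1000) {
  meta <- if (inherits(x, "spectra_matrix")) x$meta else NULL
  wavenumbers <- if (inherits(x, "spectra_matrix")) x$wavenumbers else NULL
  xm <- as_matrix_input(x)
  n <- nrow(xm); p <- ncol(xm)
  if (n < 2 || p < 2) abort("need at least 2 rows and 2 columns.")
  if (n_components > min(n - 1, p)) {
    abort(sprintf("n_components = %d exceeds min(rows - 1, cols) = %d.",
                  n_components, min(n - 1, p)))
  }
  means <- colMeans(xm)
  e <- sweep(xm, 2, means)
  total_ss <- sum(e^2)
  if (total_ss == 0) abort("matrix has no variance after centering.")
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  comp_ss <- numeric(n_components)
  for (k in seq_len(n_components)) {
    t_vec <- e[, which.max(colSums(e^2))]
    if (sum(t_vec^2) == 0) {
      abort(sprintf("residual matrix exhausted before component %d.", k))
    }
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(e, t_vec)[, 1] / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- e %*% p_vec
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new[, 1]
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      abort(sprintf("NIPALS did not converge for component %d within %d iterations.",
                    k, max_iter))
    }
    # sign convention: largest-magnitude loading element positive
    flip <- sign(p_vec[which.max(abs(p_vec))])
    p_vec <- p_vec * flip; t_vec <- t_vec * flip
    scores[, k] <- t_vec
    loadings[, k] <- p_vec
    comp_ss[k] <- sum(t_vec^2)
    e <- e - tcrossprod(t_vec, p_vec)
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  if (!is.null(colnames(xm))) rownames(loadings) <- colnames(xm)
  structure(list(
    means = means, loadings = loadings, scores = scores,
    explained_variance = 100 * comp_ss / total_ss,
    cumulative_variance = cumsum(100 * comp_ss / total_ss),
    total_ss = total_ss, meta = meta, wavenumbers = wavenumbers
  ), class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("<nipals_pca> %d observations, %d components\n", nrow(x$scores), k))
  cat("  explained variance (%):", paste(sprintf("%.2f", x$explained_variance),
                                         collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.nipals_pca <- function(x, matrix = c("scores", "loadings", "variance"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    out <- as_tibble(as.data.frame(x$scores))
    if (!is.null(x$meta)) out <- dplyr::bind_cols(x$meta, out)
    out
  } else if (matrix == "loadings") {
    out <- as_tibble(as.data.frame(x$loadings))
    out$variable <- if (!is.null(x$wavenumbers)) x$wavenumbers
      else seq_len(nrow(x$loadings))
    dplyr::relocate(out, "variable")
  } else {
    tibble(component = seq_along(x$explained_variance),
           explained_variance_pct = x$explained_variance,
           cumulative_pct = x$cumulative_variance)
  }
}

#' @export
glance.nipals_pca <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         cumulative_variance_pct = x$cumulative_variance[ncol(x$scores)],
         n_obs = nrow(x$scores), n_vars = nrow(x$loadings))
}

#' Project new observations onto a fitted PCA
#'
#' @param object A `nipals_pca`.
#' @param newdata Matrix with the same variables as the training data.
#' @param ... Unused.
#' @return Score matrix for the new observations.
#' @export
predict.nipals_pca <- function(object, newdata, ...) {
  nd <- as_matrix_input(newdata)
  if (ncol(nd) != length(object$means)) abort("variable count mismatch.")
  sweep(nd, 2, object$means) %*% object$loadings
}

#' Cross-validated explained variance of a PCA
#'
#' For each held-out segment a PCA is fitted on the remaining rows; the
#' held-out rows are projected onto the training loadings and their
#' reconstruction residual sum of squares accumulated (PRESS).  The
#' reported validation variance for `k` components is
#' `100 * (1 - PRESS_k / SS0)`, with `SS0` the total sum of squares of the
#' held-out rows about the training means, cumulated over segments.
#'
#' @inheritParams nipals_pca
#' @param segments A list of row-index vectors (see [grouped_segments()]).
#' @return A tibble with `n_components` and cumulative
#'   `validation_variance_pct`.
#' @export
pca_cv_variance <- function(x, segments, n_components = 2, tol = 1e-9,
                            max_iter = 1000) {
  xm <- as_matrix_input(x)
  if (length(segments) < 2) abort("at least 2 segments are required.")
  idx <- as.integer(sort(unlist(segments)))
  if (!identical(idx, seq_len(nrow(xm)))) {
    abort("segments must partition the rows exactly.")
  }
  press <- numeric(n_components)
  ss0 <- 0
  for (seg in segments) {
    train <- xm[-seg, , drop = FALSE]
    if (nrow(train) < 2) abort("a training fold has fewer than 2 rows.")
    fit <- nipals_pca(train, n_components = min(n_components, nrow(train) - 1, ncol(train)),
                      tol = tol, max_iter = max_iter)
    held <- sweep(xm[seg, , drop = FALSE], 2, fit$means)
    ss0 <- ss0 + sum(held^2)
    resid <- held
    for (k in seq_len(n_components)) {
      if (k <= ncol(fit$loadings)) {
        pk <- fit$loadings[, k]
        tk <- resid %*% pk
        resid <- resid - tcrossprod(tk, pk)
      }
      press[k] <- press[k] + sum(resid^2)
    }
  }
  tibble(n_components = seq_len(n_components),
         validation_variance_pct = 100 * (1 - press / ss0))
}

#' Correlation loadings
#'
#' Pearson correlation between every (centered) variable and every score
#' vector of a fitted PCA or PLS1 model.  Zero-variance variables get a
#' correlation of 0 and are flagged.  The radii of the 50% and 100%
#' explained-variance circles used in correlation-loading plots
#' (`sqrt(0.5)` and 1) are attached as attributes.
#'
#' @param model A `nipals_pca` or `pls1_model`.
#' @param x The training matrix (or [spectra_matrix()]) the model was
#'   fitted on.
#' @return A tibble with `variable`, one column per factor, and
#'   `zero_variance` flag; attributes `r50` and `r100`.
#' @export
correlation_loadings <- function(model, x) {
  xm <- as_matrix_input(x)
  scores <- if (inherits(model, "nipals_pca")) model$scores
    else if (inherits(model, "pls1_model")) model$scores
    else abort("model must be a nipals_pca or pls1_model.")
  if (nrow(xm) != nrow(scores)) abort("row count of x does not match the model scores.")
  centered <- sweep(xm, 2, colMeans(xm))
  sds <- apply(centered, 2, sd)
  flag <- sds == 0
  cors <- matrix(0, ncol(xm), ncol(scores))
  ok <- !flag
  cors[ok, ] <- cor(centered[, ok, drop = FALSE], scores)
  colnames(cors) <- colnames(scores)
  wavenumbers <- if (inherits(x, "spectra_matrix")) x$wavenumbers
    else if (!is.null(colnames(xm))) suppressWarnings(as.numeric(colnames(xm)))
    else seq_len(ncol(xm))
  out <- dplyr::bind_cols(tibble(variable = wavenumbers),
                          as_tibble(as.data.frame(cors)),
                          tibble(zero_variance = flag))
  attr(out, "r50") <- sqrt(0.5)
  attr(out, "r100") <- 1
  out
}
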