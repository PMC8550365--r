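## PLS1 regression (NIPALS sequence; for a univariate response the kernel
## and NIPALS algorithms yield identical models).

#' Fit a PLS1 regression model
#'
#' Mean-centered univariate partial least squares: for each factor the
#' weight `w = X'y / |X'y|`, score `t = X w`, loadings `p = X't / t't`,
#' `q = y't / t't` are computed and `X` (and `y`) deflated.  Regression
#' coefficient vectors are retained for every factor count, so predictions
#' and calibration statistics are available for models of 1..`max_factors`
#' factors.
#'
#' @param x A numeric matrix (observations x variables) or
#'   [spectra_matrix()].
#' @param y Numeric response (%CI per row).
#' @param max_factors Largest factor count to fit (at most
#'   `min(rows - 1, cols)`).
#' @param segments Optional list of row-index segments; when supplied,
#'   segment-wise cross-validated RMSE (RMSECV) and validation explained
#'   variance are computed per factor count.
#' @return An object of class `pls1_model`: list with `x_means`, `y_mean`,
#'   `weights`, `x_loadings`, `y_loadings`, `scores`, `coefficients`
#'   (variables x factor-counts), `fitted` (observations x factor-counts),
#'   `stats` (per-factor tibble: RMSEC, explained calibration variance,
#'   bias, and RMSECV / validation variance when segments were given),
#'   `meta`, `wavenumbers`.
#' @export
pls1_fit <- function(x, y, max_factors = 3, segments = NULL) {
  meta <- if (inherits(x, "spectra_matrix")) x$meta else NULL
  wavenumbers <- if (inherits(x, "spectra_matrix")) x$wavenumbers else NULL
  xm <- as_matrix_input(x)
  y <- as.numeric(y)
  if (nrow(xm) != length(y)) abort("x rows and y length differ.")
  if (var(y) == 0) abort("response has zero variance.")
  if (max_factors > min(nrow(xm) - 1, ncol(xm))) {
    abort(sprintf("max_factors = %d exceeds min(rows - 1, cols) = %d.",
                  max_factors, min(nrow(xm) - 1, ncol(xm))))
  }
  core <- pls1_core(xm, y, max_factors)

  stats <- tibble(
    factors = seq_len(max_factors),
    rmsec = vapply(seq_len(max_factors), function(k)
      sqrt(mean((core$fitted[, k] - y)^2)), numeric(1)),
    explained_calibration_pct = vapply(seq_len(max_factors), function(k)
      100 * (1 - var(y - core$fitted[, k]) / var(y)), numeric(1)),
    bias = vapply(seq_len(max_factors), function(k)
      mean(core$fitted[, k] - y), numeric(1)))

  if (!is.null(segments)) {
    cvpred <- matrix(NA_real_, nrow(xm), max_factors)
    for (seg in segments) {
      train_x <- xm[-seg, , drop = FALSE]; train_y <- y[-seg]
      kf <- min(max_factors, nrow(train_x) - 1, ncol(train_x))
      cv <- pls1_core(train_x, train_y, kf)
      held <- sweep(xm[seg, , drop = FALSE], 2, cv$x_means)
      for (k in seq_len(max_factors)) {
        kk <- min(k, kf)
        cvpred[seg, k] <- cv$y_mean + held %*% cv$coefficients[, kk]
      }
    }
    stats$rmsecv <- vapply(seq_len(max_factors), function(k)
      sqrt(mean((cvpred[, k] - y)^2)), numeric(1))
    stats$explained_validation_pct <- vapply(seq_len(max_factors), function(k)
      100 * (1 - var(y - cvpred[, k]) / var(y)), numeric(1))
  }

  structure(c(core, list(y = y, stats = stats, meta = meta,
                         wavenumbers = wavenumbers)),
            class = "pls1_model")
}

## The bare NIPALS-PLS1 sequence; returns means, loadings and per-factor
## coefficient vectors.
pls1_core <- function(xm, y, max_factors) {
  x_means <- colMeans(xm); y_mean <- mean(y)
  e <- sweep(xm, 2, x_means); f <- y - y_mean
  n <- nrow(e); p <- ncol(e)
  w_mat <- matrix(0, p, max_factors)
  p_mat <- matrix(0, p, max_factors)
  t_mat <- matrix(0, n, max_factors)
  q_vec <- numeric(max_factors)
  for (k in seq_len(max_factors)) {
    w <- crossprod(e, f)[, 1]
    wn2 <- sqrt(sum(w^2))
    if (wn2 < 1e-300) abort(sprintf("response fully deflated before factor %d.", k))
    w <- w / wn2
    t_vec <- e %*% w
    tt <- sum(t_vec^2)
    p_vec <- crossprod(e, t_vec)[, 1] / tt
    q <- sum(f * t_vec) / tt
    e <- e - tcrossprod(t_vec[, 1], p_vec)
    f <- f - q * t_vec[, 1]
    w_mat[, k] <- w; p_mat[, k] <- p_vec; t_mat[, k] <- t_vec; q_vec[k] <- q
  }
  coefs <- matrix(0, p, max_factors)
  for (k in seq_len(max_factors)) {
    wk <- w_mat[, seq_len(k), drop = FALSE]
    pk <- p_mat[, seq_len(k), drop = FALSE]
    coefs[, k] <- wk %*% solve(crossprod(pk, wk), q_vec[seq_len(k)])
  }
  centered <- sweep(xm, 2, x_means)
  fitted <- centered %*% coefs + y_mean
  colnames(coefs) <- colnames(fitted) <- paste0("k", seq_len(max_factors))
  colnames(t_mat) <- paste0("Factor", seq_len(max_factors))
  list(x_means = x_means, y_mean = y_mean, weights = w_mat,
       x_loadings = p_mat, y_loadings = q_vec, scores = t_mat,
       coefficients = coefs, fitted = fitted)
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model> %d observations, up to %d factors\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$stats)
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' `y_hat = y_mean + (X_new - X_means) b_k`.  When the model was trained on
#' a [spectra_matrix()], the new data's wavenumber grid must match the
#' training wavenumbers exactly; there is no silent resampling.
#'
#' @param object A `pls1_model`.
#' @param newdata Matrix or `spectra_matrix` with the training variables;
#'   omit to return the calibration fit.
#' @param n_factors Factor count to use (default: largest fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, newdata = NULL, n_factors = NULL, ...) {
  k_max <- ncol(object$coefficients)
  if (is.null(n_factors)) n_factors <- k_max
  if (n_factors > k_max) abort(sprintf("model holds only %d factors.", k_max))
  if (is.null(newdata)) {
    if (n_factors == 0) return(rep(object$y_mean, nrow(object$fitted)))
    return(object$fitted[, n_factors])
  }
  if (inherits(newdata, "spectra_matrix") && !is.null(object$wavenumbers)) {
    if (!isTRUE(all.equal(newdata$wavenumbers, object$wavenumbers))) {
      abort("wavenumber grid of newdata does not match the training grid; no silent resampling.")
    }
  }
  nd <- as_matrix_input(newdata)
  if (ncol(nd) != length(object$x_means)) abort("variable count mismatch.")
  if (n_factors == 0) return(rep(object$y_mean, nrow(nd)))
  centered <- sweep(nd, 2, object$x_means)
  as.numeric(object$y_mean + centered %*% object$coefficients[, n_factors])
}

#' @export
tidy.pls1_model <- function(x, matrix = c("stats", "coefficients", "scores",
                                          "weights", "loadings"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    stats = x$stats,
    coefficients = {
      out <- as_tibble(as.data.frame(x$coefficients))
      out$variable <- if (!is.null(x$wavenumbers)) x$wavenumbers
        else seq_len(nrow(x$coefficients))
      dplyr::relocate(out, "variable")
    },
    scores = {
      out <- as_tibble(as.data.frame(x$scores))
      if (!is.null(x$meta)) out <- dplyr::bind_cols(x$meta, out)
      out
    },
    weights = ,
    loadings = {
      m <- if (matrix == "weights") x$weights else x$x_loadings
      colnames(m) <- paste0("Factor", seq_len(ncol(m)))
      out <- as_tibble(as.data.frame(m))
      out$variable <- if (!is.null(x$wavenumbers)) x$wavenumbers
        else seq_len(nrow(m))
      dplyr::relocate(out, "variable")
    })
}

#' @export
glance.pls1_model <- function(x, ...) {
  k <- ncol(x$coefficients)
  out <- tibble(n_obs = nrow(x$scores), max_factors = k,
                rmsec = x$stats$rmsec[k],
                explained_calibration_pct = x$stats$explained_calibration_pct[k])
  if ("rmsecv" %in% names(x$stats)) out$rmsecv <- x$stats$rmsecv[k]
  out
}

## ---------------------------------------------------------------------------
## Model serialization

#' Write / read a PLS1 model
#'
#' Models are stored as JSON with a schema version, the training
#' wavenumbers, centering constants, per-factor weights/loadings and
#' per-factor statistics.
#'
#' @param model A `pls1_model`.
#' @param path File path.
#' @return `path` (write) or a `pls1_model` (read).
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls1_model"))
  obj <- list(
    schema = "ramanci/pls1/1",
    wavenumbers = model$wavenumbers,
    x_means = unname(model$x_means), y_mean = model$y_mean,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, coefficients = model$coefficients,
    stats = model$stats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ramanci/pls1/1")) {
    abort(sprintf("%s is not a ramanci PLS model file.", path))
  }
  coefs <- as.matrix(obj$coefficients)
  structure(list(
    x_means = obj$x_means, y_mean = obj$y_mean,
    weights = as.matrix(obj$weights), x_loadings = as.matrix(obj$x_loadings),
    y_loadings = obj$y_loadings, coefficients = coefs,
    scores = matrix(numeric(0), 0, ncol(coefs)),
    fitted = matrix(numeric(0), 0, ncol(coefs)),
    y = numeric(0), stats = as_tibble(obj$stats),
    meta = NULL, wavenumbers = obj$wavenumbers
  ), class = "pls1_model")
}
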