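#' Default spread grid for bandwidth selection
#'
#' 30 log-spaced candidates in \[0.02, 2\] (dimensionless, in the
#' min-max-normalized input space). The lower end approaches
#' nearest-neighbour interpolation on the packaged trial's design; the
#' upper end is global smoothing.
#'
#' @return Numeric vector of candidate spreads.
#' @export
default_sigma_grid <- function() {
  exp(seq(log(0.02), log(2), length.out = 30L))
}

# min-max scaler fitted on training inputs; degenerate (constant) features
# map to 0 with a warning at fit time
fit_scaler <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  degenerate <- hi <= lo
  if (any(degenerate)) {
    warning("degenerate feature(s) with zero range mapped to constant 0: ",
            paste(colnames(x)[degenerate], collapse = ", "))
  }
  list(lo = lo, hi = hi, range = ifelse(degenerate, 1, hi - lo))
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$lo, "-"), 2L, scaler$range, "/")
}

#' Fit a generalized regression neural network
#'
#' A GRNN is a one-pass Gaussian-kernel regression estimator: the
#' prediction at a query point is the kernel-weighted average of the
#' stored training targets,
#' \deqn{\hat y(x) = \sum_i y_i e^{-\|x - x_i\|^2 / (2\sigma^2)} /
#'       \sum_i e^{-\|x - x_i\|^2 / (2\sigma^2)},}
#' with distances taken in the min-max-normalized input space so that no
#' input (hypochlorite 0-15 %, peroxide 0-30 %, minutes 0-20) dominates by
#' scale. The single spread parameter \eqn{\sigma} controls the
#' interpolation/smoothing trade-off; when absent it is chosen by
#' leave-one-out RMSE over `sigma_grid` (see [select_sigma()]).
#'
#' @param x Training inputs: data frame or matrix with columns `naocl`,
#'   `h2o2`, `time` (any numeric feature matrix is accepted).
#' @param y Training targets, contamination percentages in \[0, 100\].
#' @param sigma Optional fixed spread (> 0).
#' @param sigma_grid Candidate spreads used when `sigma` is `NULL`.
#' @return An object of class `grnn`.
#' @examples
#' obs <- expand_replicates(disinfection_trial())
#' model <- fit_grnn(obs[, c("naocl", "h2o2", "time")], obs$contamination)
#' predict(model, data.frame(naocl = 5, h2o2 = 0, time = 15))
#' @export
fit_grnn <- function(x, y, sigma = NULL, sigma_grid = default_sigma_grid()) {
  x <- as_treatment_matrix_or_features(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y must have matching lengths")
  if (length(y) < 1L) stop("need at least one training observation")
  if (any(!is.finite(y))) stop("targets must be finite")
  if (any(y < 0 | y > 100)) stop("targets must be contamination percentages in [0, 100]")
  scaler <- fit_scaler(x)
  if (is.null(sigma)) {
    if (length(y) < 2L) {
      stop("sigma must be given explicitly for a single training point")
    }
    sigma <- select_sigma(x, y, sigma_grid)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  structure(
    list(x = apply_scaler(scaler, x), y = y, sigma = sigma, scaler = scaler,
         features = colnames(x)),
    class = "grnn")
}

# accept either the canonical 3-column treatment layout or a generic
# numeric feature matrix (used by tests and the synthetic grid checks)
as_treatment_matrix_or_features <- function(x) {
  if (is.data.frame(x) && all(.treatment_cols %in% names(x))) {
    return(as_treatment_matrix(x, require_nonneg = FALSE))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("inputs must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

# squared Euclidean distances between rows of two scaled matrices,
# clamped at 0 against floating-point cancellation
sqdist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# kernel-weighted average with the max exponent subtracted per query row;
# the largest weight is then exactly 1, so the denominator never
# underflows and the sigma -> 0 limit degrades gracefully to the nearest
# training target
kernel_average <- function(sq, y, sigma, drop_diag = FALSE) {
  e <- -sq / (2 * sigma^2)
  if (drop_diag) diag(e) <- -Inf
  m <- apply(e, 1L, max)
  w <- exp(e - m)
  as.vector(w %*% y) / rowSums(w)
}

#' Predict contamination with a fitted GRNN
#'
#' @param object A `grnn` model.
#' @param newdata Query treatments: data frame or matrix with the model's
#'   input columns, or a single length-3 vector.
#' @param ... Unused.
#' @return Numeric vector of predicted contamination percentages; every
#'   prediction is a convex combination of training targets, hence bounded
#'   by their range.
#' @export
predict.grnn <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != length(object$scaler$lo)) {
      stop("newdata must supply one row per query with ",
           length(object$scaler$lo), " features")
    }
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, object$features))
  }
  q <- as_treatment_matrix_or_features(newdata)
  if (ncol(q) != length(object$scaler$lo)) {
    stop("newdata has ", ncol(q), " features; model expects ",
         length(object$scaler$lo))
  }
  qs <- apply_scaler(object$scaler, q)
  kernel_average(sqdist(qs, object$x), object$y, object$sigma)
}

#' Leave-one-out RMSE of a GRNN at given spreads
#'
#' For each training point, the prediction from all remaining points is
#' computed by deleting the diagonal of the kernel matrix; the min-max
#' scaler is fitted once on the full training set. Vectorized over
#' `sigma`.
#'
#' @param x Training inputs.
#' @param y Training targets.
#' @param sigma Numeric vector of spreads (> 0).
#' @return Numeric vector of LOO-RMSE values, one per spread.
#' @export
loo_rmse <- function(x, y, sigma) {
  x <- as_treatment_matrix_or_features(x)
  y <- as.numeric(y)
  if (nrow(x) < 2L) stop("leave-one-out needs at least 2 observations")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("spreads must be positive")
  }
  xs <- apply_scaler(fit_scaler(x), x)
  sq <- sqdist(xs, xs)
  vapply(sigma, function(s) {
    p <- kernel_average(sq, y, s, drop_diag = TRUE)
    sqrt(mean((p - y)^2))
  }, 1.0)
}

#' Select the GRNN spread by leave-one-out cross-validation
#'
#' Returns the grid candidate minimizing [loo_rmse()]; ties are broken
#' toward the larger spread (the smoother model).
#'
#' @inheritParams loo_rmse
#' @param sigma_grid Positive candidate spreads.
#' @return The selected spread.
#' @export
select_sigma <- function(x, y, sigma_grid = default_sigma_grid()) {
  if (length(sigma_grid) == 0L) stop("sigma_grid is empty")
  if (any(!is.finite(sigma_grid)) || any(sigma_grid <= 0)) {
    stop("sigma_grid must contain positive values only")
  }
  err <- loo_rmse(x, y, sigma_grid)
  best <- which(err <= min(err))
  max(sigma_grid[best])
}

#' @export
print.grnn <- function(x, ...) {
  cat("Generalized regression neural network\n")
  cat(sprintf("  training points: %d  features: %s\n", length(x$y),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  spread (sigma): %.4g (normalized input space)\n", x$sigma))
  cat(sprintf("  target range: [%g, %g] %%\n", min(x$y), max(x$y)))
  invisible(x)
}

#' Save / load a GRNN model as plain-text JSON
#'
#' Serializes the scaler bounds, spread and training points; loading
#' reproduces a model whose predictions equal the original's.
#'
#' @param model A `grnn` object.
#' @param path File path for the JSON document.
#' @return `grnn_save()` returns `path` invisibly; `grnn_load()` returns a
#'   `grnn` object.
#' @export
grnn_save <- function(model, path) {
  stopifnot(inherits(model, "grnn"))
  doc <- list(
    type = "grnn",
    sigma = model$sigma,
    features = model$features,
    scaler = list(lo = unname(model$scaler$lo), hi = unname(model$scaler$hi),
                  range = unname(model$scaler$range)),
    x = unname(as.matrix(model$x)),
    y = model$y)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grnn_save
#' @export
grnn_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || doc$type != "grnn") {
    stop("not a serialized GRNN model: ", path)
  }
  x <- as.matrix(doc$x)
  colnames(x) <- doc$features
  scaler <- list(lo = stats::setNames(doc$scaler$lo, doc$features),
                 hi = stats::setNames(doc$scaler$hi, doc$features),
                 range = stats::setNames(doc$scaler$range, doc$features))
  structure(
    list(x = x, y = doc$y, sigma = doc$sigma, scaler = scaler,
         features = doc$features),
    class = "grnn")
}
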