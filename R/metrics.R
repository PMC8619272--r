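#' Model performance criteria
#'
#' The three criteria used to judge the contamination model: coefficient
#' of determination `r_squared()` (1 - SSE/SST about the observed mean;
#' can be negative for models worse than the mean), root mean square error
#' `rmse()`, and mean bias error `mbe()` defined as
#' `mean(predicted - observed)`, so a negative value means the model
#' under-predicts contamination on average.
#'
#' @param observed Numeric vector of observed contamination percentages.
#' @param predicted Numeric vector of predictions, same length.
#' @return A single number.
#' @examples
#' r_squared(c(0, 50, 100), c(10, 50, 90)) # 0.96
#' rmse(c(0, 0), c(10, -10))               # 10
#' mbe(c(10, 20), c(0, 10))                # -10
#' @export
r_squared <- function(observed, predicted) {
  check_metric_args(observed, predicted, min_n = 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("R-squared is undefined: observed values have zero variance")
  }
  1 - sum((observed - predicted)^2) / sst
}

#' @rdname r_squared
#' @export
rmse <- function(observed, predicted) {
  check_metric_args(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname r_squared
#' @export
mbe <- function(observed, predicted) {
  check_metric_args(observed, predicted)
  mean(predicted - observed)
}

check_metric_args <- function(observed, predicted, min_n = 1L) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " observation(s)")
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observed and predicted must be finite")
  }
  invisible(NULL)
}

#' Evaluate predictions on a labelled set
#'
#' Bundles the three criteria into a one-row report, the unit the
#' pipeline's train/test tables are built from.
#'
#' @inheritParams r_squared
#' @param label Set label, e.g. `"train"` or `"test"`.
#' @return A one-row data frame with columns `set`, `n`, `r2`, `rmse`,
#'   `mbe`.
#' @export
evaluate_predictions <- function(observed, predicted, label = "train") {
  data.frame(set = label, n = length(observed),
             r2 = r_squared(observed, predicted),
             rmse = rmse(observed, predicted),
             mbe = mbe(observed, predicted))
}
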