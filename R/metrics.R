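# Goodness-of-fit metrics for observed (O) vs model-predicted (M) values.
#
# R^2 uses the standard coefficient of determination with a squared-
# deviation denominator — the only form under which values are bounded by 1
# and comparable across responses. MBE is the signed mean bias (M - O), so
# over- and under-prediction carry opposite signs; the absolute variant is
# available as mae().

check_om <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("'observed' and 'predicted' must be equal-length, non-empty vectors",
         call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("metrics require finite values", call. = FALSE)
  }
  invisible(NULL)
}

#' Regression fit metrics
#'
#' @param observed Numeric vector of observed values.
#' @param predicted Numeric vector of model predictions, same length.
#' @return A single numeric value.
#' @details
#' * `r_squared()`: `1 - sum((M-O)^2) / sum((O-mean(O))^2)`; `NA` with a
#'   warning when the observations have zero variance.
#' * `rmse()`: root mean squared error.
#' * `mbe()`: signed mean bias error, `mean(M - O)` (positive means
#'   over-prediction).
#' * `mae()`: mean absolute error.
#' * `mse()`: mean squared error per sample.
#' @examples
#' o <- c(0, 1, 2); m <- c(0, 1, 3)
#' r_squared(o, m)  # 0.5
#' rmse(o, m)       # sqrt(1/3)
#' mbe(o, m)        # 1/3
#' @export
r_squared <- function(observed, predicted) {
  check_om(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("observations have zero variance; R^2 is undefined")
    return(NA_real_)
  }
  1 - sum((predicted - observed)^2) / ss_tot
}

#' @rdname r_squared
#' @export
rmse <- function(observed, predicted) {
  check_om(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname r_squared
#' @export
mbe <- function(observed, predicted) {
  check_om(observed, predicted)
  mean(predicted - observed)
}

#' @rdname r_squared
#' @export
mae <- function(observed, predicted) {
  check_om(observed, predicted)
  mean(abs(predicted - observed))
}

#' @rdname r_squared
#' @export
mse <- function(observed, predicted) {
  check_om(observed, predicted)
  mean((predicted - observed)^2)
}

fit_metrics <- function(observed, predicted) {
  c(r_squared = r_squared(observed, predicted),
    rmse = rmse(observed, predicted),
    mbe = mbe(observed, predicted),
    mse = mse(observed, predicted))
}
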