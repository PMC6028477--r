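# S3 methods for fitted "rootnet" objects.

#' @export
print.rootnet <- function(x, ...) {
  cat("Feed-forward surrogate network (tansig hidden / linear output)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  if (!is.null(x$constant)) {
    cat("Degenerate fit: constant predictor =", format(x$constant), "\n")
    return(invisible(x))
  }
  cat(sprintf("Topology: %d-%d-1 | epochs: %d | stop: %s | train MSE (norm): %.5f\n",
              length(x$var_names), x$control$hidden, x$epochs,
              x$stop_reason, x$mse_train))
  invisible(x)
}

#' @export
coef.rootnet <- function(object, ...) {
  if (!is.null(object$constant)) return(c(constant = object$constant))
  w <- object$weights
  h <- length(w$b1); p <- length(object$var_names)
  nm <- c(outer(seq_len(h), object$var_names,
                function(i, v) sprintf("W1[%d,%s]", i, v)),
          sprintf("b1[%d]", seq_len(h)),
          sprintf("w2[%d]", seq_len(h)), "b2")
  stats::setNames(flatten_weights(w), nm)
}

#' Predict from a fitted surrogate network
#'
#' @param object A `"rootnet"` fit.
#' @param newdata Data frame with the predictor columns; defaults to the
#'   training data.
#' @param type `"response"` (original scale, default) or `"normalized"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rootnet <- function(object, newdata = NULL,
                            type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$model
  if (!is.null(object$constant)) {
    n <- nrow(newdata)
    return(rep(if (type == "response") object$constant else 0, n))
  }
  stopifnot_cols(newdata, object$var_names, "newdata")
  X <- as.matrix(newdata[object$var_names])
  if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
  rng <- object$norm
  Xn <- sweep(sweep(X, 2L, rng$min[object$var_names], "-"), 2L,
              (rng$max - rng$min)[object$var_names], "/") * 2 - 1
  yn <- nn_forward(object$weights, Xn)
  if (type == "normalized") return(yn)
  denorm_vec(yn, rng$min[[object$response_name]],
             rng$max[[object$response_name]])
}

#' @export
residuals.rootnet <- function(object, ...) object$residuals

#' @export
fitted.rootnet <- function(object, ...) object$fitted.values

#' Summarize a fitted surrogate network
#'
#' Reports training-set fit metrics (R^2, RMSE, MBE, MSE) on the original
#' scale, plus training diagnostics. Metrics for a held-out partition can
#' be obtained with [export_scatter()] or by combining [predict.rootnet()]
#' with [r_squared()] and friends.
#'
#' @param object A `"rootnet"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.rootnet"`.
#' @export
summary.rootnet <- function(object, ...) {
  obs <- object$fitted.values + object$residuals
  out <- list(call = object$call, metrics = fit_metrics(obs, object$fitted.values),
              epochs = object$epochs, stop_reason = object$stop_reason,
              mse_train_norm = object$mse_train %||% NA_real_,
              n = length(obs), hidden = object$control$hidden,
              p = length(object$var_names))
  class(out) <- "summary.rootnet"
  out
}

#' @export
print.summary.rootnet <- function(x, digits = 4, ...) {
  cat("Feed-forward surrogate network ", x$p, "-", x$hidden, "-1\n", sep = "")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Training rows: %d | epochs: %d | stop: %s\n",
              x$n, x$epochs, x$stop_reason))
  cat("Training metrics (original scale):\n")
  print(round(x$metrics, digits))
  invisible(x)
}

#' Observed-vs-predicted scatter plot
#'
#' Plots observed against predicted values with the fitted simple
#' regression line and the 1:1 line, the standard diagnostic for surrogate
#' fit quality.
#'
#' @param x A `"rootnet"` fit.
#' @param newdata Optional data frame (e.g. the test partition) containing
#'   predictors and the response column; defaults to the training data.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `(observed, predicted)` data frame from
#'   [export_scatter()].
#' @export
plot.rootnet <- function(x, newdata = NULL, ...) {
  sc <- export_scatter(x, newdata)
  graphics::plot(sc$observed, sc$predicted,
                 xlab = paste("Observed", x$response_name),
                 ylab = paste("Predicted", x$response_name), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(attr(sc, "intercept"), attr(sc, "slope"))
  invisible(sc)
}

#' Simulate replicate-like observations from a fitted network
#'
#' Draws Gaussian noise with the fit's residual standard deviation around
#' the model predictions, clamped to be non-negative (and to at most 1 when
#' the response is a proportion on \[0, 1\], as judged from the
#' normalization range).
#'
#' @param object A `"rootnet"` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed.
#' @param newdata Optional data frame of predictor values; defaults to the
#'   training data.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per
#'   column.
#' @export
simulate.rootnet <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  mu <- predict(object, newdata)
  sdv <- stats::sd(object$residuals)
  hi <- Inf
  if (!is.null(object$norm)) {
    r <- object$norm
    if (r$min[[object$response_name]] >= 0 &&
        r$max[[object$response_name]] <= 1) hi <- 1
  }
  draw <- function() clamp(stats::rnorm(length(mu), mu, sdv), 0, hi)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
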