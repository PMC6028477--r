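# Variable sensitivity analysis.
#
# The importance of an input is measured by what happens to the model when
# that input is unavailable: the variable sensitivity error (VSE) is the
# error of a network retrained with the input's column removed (reduced
# topology, same data partition and stopping rules), and the variable
# sensitivity ratio (VSR) is VSE divided by the full model's error. VSR
# near 1 means the input carried no unique information; large VSR means the
# model degrades badly without it. Errors are RMSE in normalized space so
# ratios are comparable across responses; being a ratio, the ranking is
# unchanged under any monotone error metric.

#' Variable sensitivity ratio
#'
#' @param vse_value Error of the model with the variable unavailable.
#' @param full_error Error of the full model (> 0).
#' @return `vse_value / full_error`.
#' @examples
#' vsr(0.2, 0.1)  # 2
#' @export
vsr <- function(vse_value, full_error) {
  if (!is.numeric(full_error) || any(full_error <= 0)) {
    stop("'full_error' must be > 0", call. = FALSE)
  }
  vse_value / full_error
}

#' Rank variables by sensitivity ratio
#'
#' Assigns rank 1 to the largest VSR. Ties are broken by the variables'
#' given order (for the ion models, the canonical order NO3-, NH4+, K+,
#' Ca2+, Cl-) and flagged via the `"ties"` attribute.
#'
#' @param vsr_values Named (or ordered) numeric vector of VSR values.
#' @return Integer vector of ranks (1 = most important), named like the
#'   input, with attribute `ties` (logical).
#' @examples
#' rank_ions(c(no3 = 1, nh4 = 4.4, k = 7.6, ca = 1.5, cl = 1.2))
#' @export
rank_ions <- function(vsr_values) {
  if (any(!is.finite(vsr_values))) {
    stop("VSR values must be finite", call. = FALSE)
  }
  ord <- order(-vsr_values, seq_along(vsr_values))
  ranks <- integer(length(vsr_values))
  ranks[ord] <- seq_along(vsr_values)
  names(ranks) <- names(vsr_values)
  attr(ranks, "ties") <- anyDuplicated(vsr_values) > 0L
  ranks
}

#' Sensitivity analysis of a fitted surrogate network
#'
#' @param object A fitted model.
#' @param ... Passed to methods.
#' @export
sensitivity <- function(object, ...) UseMethod("sensitivity")

#' @describeIn sensitivity For each predictor of a `"rootnet"` fit, either
#'   retrains a reduced-input network on the fit's own training rows
#'   (`mode = "retrain"`, the definition used for the published rankings)
#'   or holds the column at its training mean (`mode = "hold_at_mean"`, a
#'   cheaper imputation-style variant kept for comparison), then evaluates
#'   RMSE in normalized space on `data` — typically the full replicate
#'   dataset, train and test together.
#'
#' @param data Evaluation rows: a data frame containing all predictor
#'   columns and the response column. Defaults to the fit's training data.
#' @param mode `"retrain"` (default) or `"hold_at_mean"`.
#' @param seed Seed for the reduced-network initializations (default: the
#'   fit's own seed).
#' @return A data.frame of class `"rootnet_sensitivity"` with columns
#'   `variable`, `vse`, `vsr`, `rank`, and attributes `full_error`,
#'   `metric`, `mode`, `n_eval`, `response`, `ties`.
#' @export
sensitivity.rootnet <- function(object, data = NULL,
                                mode = c("retrain", "hold_at_mean"),
                                seed = NULL, ...) {
  mode <- match.arg(mode)
  if (!is.null(object$constant)) {
    stop("sensitivity analysis is undefined for a constant predictor",
         call. = FALSE)
  }
  seed <- seed %||% object$seed
  if (is.null(data)) data <- object$model
  vars <- object$var_names
  resp <- object$response_name
  stopifnot_cols(data, c(vars, resp), "data")

  rng <- object$norm
  yn_eval <- norm_vec(data[[resp]], rng$min[[resp]], rng$max[[resp]])
  full_error <- rmse(yn_eval, predict(object, data, type = "normalized"))
  if (full_error <= 0) {
    stop("full model has zero evaluation error; VSR is undefined",
         call. = FALSE)
  }

  train_df <- as.data.frame(object$model)
  names(train_df)[1L] <- resp   # model.frame puts the response first

  vse_vals <- vapply(vars, function(v) {
    keep <- setdiff(vars, v)
    if (mode == "retrain") {
      fml <- stats::reformulate(keep, response = resp)
      red <- rootnet(fml, train_df, ranges = object$norm,
                     control = object$control, seed = seed)
      rmse(yn_eval, predict(red, data, type = "normalized"))
    } else {
      held <- data
      held[[v]] <- mean(train_df[[v]])
      rmse(yn_eval, predict(object, held, type = "normalized"))
    }
  }, numeric(1))

  vsr_vals <- vsr(vse_vals, full_error)
  ranks <- rank_ions(vsr_vals)
  out <- data.frame(variable = vars, vse = unname(vse_vals),
                    vsr = unname(vsr_vals), rank = as.integer(ranks),
                    row.names = NULL)
  structure(out, full_error = full_error, metric = "rmse_normalized",
            mode = mode, n_eval = nrow(data), response = resp,
            ties = attr(ranks, "ties"),
            class = c("rootnet_sensitivity", "data.frame"))
}

#' @export
print.rootnet_sensitivity <- function(x, digits = 3, ...) {
  cat(sprintf("Sensitivity analysis (%s, %s) on %d rows; full-model error %.4g\n",
              attr(x, "mode"), attr(x, "metric"), attr(x, "n_eval"),
              attr(x, "full_error")))
  if (isTRUE(attr(x, "ties"))) cat("note: tied VSR values, fixed-order tie-break\n")
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}
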