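# End-to-end reproduction pipeline: stoichiometry check -> replicate
# expansion -> normalization and split -> per-response network fit ->
# sensitivity ranking -> GA optimization, with deterministic per-stage
# seeds derived from one base seed.

#' Observed-vs-predicted scatter data with fitted regression line
#'
#' Builds the data behind the standard observed-vs-predicted diagnostic
#' plot: one row per data line plus the least-squares simple regression of
#' predicted on observed.
#'
#' @param object A `"rootnet"` fit.
#' @param newdata Data frame containing the predictors and the response
#'   column (e.g. a test partition); defaults to the training data.
#' @return Data frame with columns `observed` and `predicted` and
#'   attributes `slope`, `intercept`, `r_squared` (of the regression line).
#' @export
export_scatter <- function(object, newdata = NULL) {
  if (is.null(newdata)) {
    newdata <- as.data.frame(object$model)
    names(newdata)[1L] <- object$response_name
  }
  if (nrow(newdata) == 0L) stop("empty partition", call. = FALSE)
  stopifnot_cols(newdata, object$response_name, "newdata")
  observed <- newdata[[object$response_name]]
  predicted <- predict(object, newdata)
  fitline <- stats::lm(predicted ~ observed)
  cf <- stats::coef(fitline)
  r2 <- if (stats::sd(observed) > 0 && stats::sd(predicted) > 0) {
    stats::cor(observed, predicted)^2
  } else 0
  structure(data.frame(observed = observed, predicted = predicted),
            intercept = unname(cf[1L]), slope = unname(cf[2L]),
            r_squared = r2)
}

stage_seed <- function(seed, response_idx, stage) {
  # distinct, reproducible sub-seeds; stays far below .Machine$integer.max
  as.integer(seed) * 101L + response_idx * 10L + stage
}

partition_metrics <- function(fit, rows) {
  obs <- rows$value
  pred <- predict(fit, rows)
  rng <- fit$norm
  obs_n <- norm_vec(obs, rng$min[["value"]], rng$max[["value"]])
  pred_n <- predict(fit, rows, type = "normalized")
  list(original = fit_metrics(obs, pred),
       normalized = fit_metrics(obs_n, pred_n))
}

#' Run the full modelling pipeline
#'
#' Executes, for each requested response: replicate expansion from the
#' treatment means/SEs, min-max normalization (ranges from the full
#' replicate set), the random train/test split, network training,
#' train/test fit metrics (original and normalized scale), retrain-based
#' sensitivity analysis on all rows, and GA optimization over the data box.
#' Before modelling, the salt-formulation table is cross-checked against
#' the treatment ion table.
#'
#' @param seed Base seed; every stage derives its own seed from it, so a
#'   run is fully reproducible.
#' @param responses Character vector of responses to process (default all
#'   five).
#' @param treatments Treatment table in the layout of [gn15_treatments()].
#' @param formulations Salt table in the layout of [gn15_media()], or
#'   `NULL` to skip the stoichiometry verification.
#' @param n_train,n_test Split sizes (defaults 130/86).
#' @param control A [rootnet_control()].
#' @param ga A [ga_control()].
#' @param run_sensitivity,run_ga Logical switches for the heavier stages.
#' @param out_dir If non-`NULL`, write per-response artifacts (fit report
#'   and weights JSON, sensitivity and optimum CSV/JSON, scatter CSVs) and
#'   a manifest JSON there.
#' @return Object of class `"rootnet_run"`: list with `verification`,
#'   per-response `results` (fit, metrics, sensitivity, optimum, scatter),
#'   `seed`, and the configuration echo.
#' @examples
#' \donttest{
#' run <- reproduce(seed = 1, responses = "Rpct",
#'                  control = rootnet_control(max_epochs = 100),
#'                  ga = ga_control(generations = 50))
#' print(run)
#' }
#' @export
reproduce <- function(seed = 1L,
                      responses = c("RN", "RL", "Rpct", "FW", "DW"),
                      treatments = gn15_treatments(),
                      formulations = gn15_media(),
                      n_train = 130L, n_test = 86L,
                      control = rootnet_control(), ga = ga_control(),
                      run_sensitivity = TRUE, run_ga = TRUE,
                      out_dir = NULL) {
  responses <- vapply(responses, match_response, character(1), USE.NAMES = FALSE)
  verification <- NULL
  if (!is.null(formulations)) {
    verification <- verify_against_reference(
      formulations, treatments[c("code", ion_names())], tol = 0.02)
    if (attr(verification, "n_flagged") > 0L) {
      warning(sprintf("stoichiometry check flagged %d entries",
                      attr(verification, "n_flagged")))
    }
  }
  fml <- stats::reformulate(ion_names(), response = "value")
  results <- list()
  for (ri in seq_along(responses)) {
    resp <- responses[ri]
    reps <- expand_replicates(treatments, resp,
                              seed = stage_seed(seed, ri, 1L))
    spec <- normalization_spec(reps, c(ion_names(), "value"))
    parts <- split_train_test(reps, n_train = n_train, n_test = n_test,
                              seed = stage_seed(seed, ri, 2L))
    fit <- rootnet(fml, parts$train, ranges = spec, control = control,
                   seed = stage_seed(seed, ri, 3L))
    metrics <- list(train = partition_metrics(fit, parts$train),
                    test = partition_metrics(fit, parts$test))
    sens <- if (run_sensitivity) {
      sensitivity(fit, data = reps, seed = stage_seed(seed, ri, 4L))
    }
    opt <- if (run_ga) {
      # search in salt space when the formulations are known: candidates then
      # stay on the data manifold induced by the salt-to-ion stoichiometry
      if (!is.null(formulations)) {
        optimize_medium(fit, formulations = formulations, control = ga,
                        seed = stage_seed(seed, ri, 5L))
      } else {
        ga_optimize(fit, control = ga, seed = stage_seed(seed, ri, 5L))
      }
    }
    results[[resp]] <- list(
      response = resp, fit = fit, metrics = metrics,
      epochs = fit$epochs, stop_reason = fit$stop_reason,
      sensitivity = sens, optimum = opt,
      scatter = list(train = export_scatter(fit, parts$train),
                     test = export_scatter(fit, parts$test)),
      n_train = nrow(parts$train), n_test = nrow(parts$test))
  }
  run <- structure(list(verification = verification, results = results,
                        seed = seed, responses = responses,
                        control = control, ga = ga),
                   class = "rootnet_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.rootnet_run <- function(x, ...) {
  cat("Rooting-response surrogate pipeline (seed", x$seed, ")\n")
  if (!is.null(x$verification)) {
    cat(sprintf("Stoichiometry check: %d/%d entries flagged (tol 0.02 mM)\n",
                attr(x$verification, "n_flagged"), nrow(x$verification)))
  }
  for (res in x$results) {
    line <- sprintf("  %-4s test R2 %.3f | train R2 %.3f | epochs %d (%s)",
                    res$response, res$metrics$test$original[["r_squared"]],
                    res$metrics$train$original[["r_squared"]],
                    res$epochs, res$stop_reason)
    if (!is.null(res$optimum)) {
      line <- paste0(line, sprintf(" | GA optimum %.3g", res$optimum$value))
    }
    cat(line, "\n")
  }
  invisible(x)
}

weights_to_json_list <- function(fit) {
  w <- fit$weights
  list(topology = c(length(fit$var_names), fit$control$hidden, 1L),
       inputs = fit$var_names,
       response = fit$response_name,
       W1_row_major = as.numeric(t(w$W1)), b1 = w$b1, w2 = w$w2, b2 = w$b2,
       normalization = list(min = as.list(fit$norm$min),
                            max = as.list(fit$norm$max)))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = run$seed, responses = run$responses, files = list())
  if (!is.null(run$verification)) {
    path <- file.path(out_dir, "stoichiometry_check.csv")
    utils::write.csv(as.data.frame(run$verification), path, row.names = FALSE)
    manifest$files$stoichiometry_check <- basename(path)
  }
  for (res in run$results) {
    tag <- tolower(res$response)
    wpath <- file.path(out_dir, paste0("weights_", tag, ".json"))
    jsonlite::write_json(weights_to_json_list(res$fit), wpath,
                         auto_unbox = TRUE, digits = NA)
    fpath <- file.path(out_dir, paste0("fit_report_", tag, ".json"))
    jsonlite::write_json(list(
      response = res$response, epochs = res$epochs,
      stop_reason = res$stop_reason,
      metrics = res$metrics), fpath, auto_unbox = TRUE, digits = NA)
    manifest$files[[paste0("weights_", tag)]] <- basename(wpath)
    manifest$files[[paste0("fit_report_", tag)]] <- basename(fpath)
    if (!is.null(res$sensitivity)) {
      spath <- file.path(out_dir, paste0("sensitivity_", tag, ".csv"))
      utils::write.csv(as.data.frame(res$sensitivity), spath, row.names = FALSE)
      manifest$files[[paste0("sensitivity_", tag)]] <- basename(spath)
    }
    if (!is.null(res$optimum)) {
      opath <- file.path(out_dir, paste0("optimum_", tag, ".json"))
      jsonlite::write_json(list(
        par = as.list(res$optimum$par), value = res$optimum$value,
        trajectory = res$optimum$trajectory), opath,
        auto_unbox = TRUE, digits = NA)
      manifest$files[[paste0("optimum_", tag)]] <- basename(opath)
    }
    for (part in c("train", "test")) {
      cpath <- file.path(out_dir, sprintf("scatter_%s_%s.csv", tag, part))
      utils::write.csv(res$scatter[[part]], cpath, row.names = FALSE)
      manifest$files[[sprintf("scatter_%s_%s", tag, part)]] <- basename(cpath)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
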