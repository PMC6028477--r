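# Replicate-level synthetic data.
#
# The networks were fitted to replicate-level observations (36 treatments x
# 6 replicates = 216 data lines), but only treatment means +/- SE are
# published. This module reconstructs a dataset with the same statistical
# structure: each treatment contributes n_reps draws from
# Normal(mean, SE * sqrt(n_reps)) — the SE-to-SD conversion for a mean of
# n_reps replicates — clamped to the response's physical domain.

resp_prefix <- function(response) tolower(match_response(response))

#' Expand treatment means and standard errors into replicate rows
#'
#' @param treatments Data frame in the layout of [gn15_treatments()]: ion
#'   columns `no3`, `nh4`, `k`, `ca`, `cl`, plus `<resp>_mean`, `<resp>_se`
#'   and `n_reps` for the requested response.
#' @param response One of `"RN"`, `"RL"`, `"Rpct"` (alias `"R%"`), `"FW"`,
#'   `"DW"`.
#' @param seed Integer seed; the expansion is deterministic given it.
#' @param n_reps Optional override of the number of replicates to emit per
#'   treatment (e.g. for Monte-Carlo checks of the noise model). The SE-to-SD
#'   conversion always uses the design replicate count from
#'   `treatments$n_reps` — the printed SEs summarize that design regardless
#'   of how many draws are emitted.
#' @return Data frame with columns `code`, the five ion columns, `response`
#'   and `value` (original scale, clamped to the response domain);
#'   `sum(n_reps)` rows.
#' @examples
#' reps <- expand_replicates(gn15_treatments(), "Rpct", seed = 1)
#' nrow(reps)  # 216
#' @export
expand_replicates <- function(treatments, response, seed = 1L, n_reps = NULL) {
  response <- match_response(response)
  pre <- resp_prefix(response)
  cols <- c("code", ion_names(), paste0(pre, c("_mean", "_se")))
  stopifnot_cols(treatments, cols, "treatments")
  stopifnot_cols(treatments, "n_reps", "treatments")
  design_n <- as.integer(treatments$n_reps)
  if (is.null(n_reps)) n_reps <- design_n
  n_reps <- as.integer(rep_len(n_reps, nrow(treatments)))
  if (any(n_reps < 1L) || any(design_n < 1L)) {
    stop("n_reps must be >= 1", call. = FALSE)
  }
  mu <- treatments[[paste0(pre, "_mean")]]
  se <- treatments[[paste0(pre, "_se")]]
  if (any(!is.finite(mu)) || any(!is.finite(se)) || any(se < 0) || any(mu < 0)) {
    stop("treatment means must be >= 0 and SEs >= 0 and finite", call. = FALSE)
  }
  dom <- response_domain(response)
  rows <- with_seed(seed, {
    idx <- rep(seq_len(nrow(treatments)), times = n_reps)
    sd_rep <- se * sqrt(design_n)            # SE of mean -> per-replicate SD
    value <- stats::rnorm(length(idx), mean = mu[idx], sd = sd_rep[idx])
    data.frame(code = treatments$code[idx],
               treatments[idx, ion_names(), drop = FALSE],
               response = response,
               value = clamp(value, dom[1], dom[2]),
               row.names = NULL)
  })
  rows
}

#' Min-max normalization to \[-1, 1\]
#'
#' Builds a per-column normalization specification (the column minima and
#' maxima on the original scale) mapping each column linearly onto
#' \[-1, 1\]: `x' = 2 (x - min) / (max - min) - 1`. Ranges are computed on
#' the full dataset before any train/test split, matching how the source
#' study normalized.
#'
#' @param data Data frame holding the columns to normalize.
#' @param cols Character vector of column names (default: the five ions plus
#'   `value`).
#' @return An object of class `"norm_spec"`: a list with named numeric
#'   vectors `min` and `max`.
#' @examples
#' reps <- expand_replicates(gn15_treatments(), "Rpct", seed = 1)
#' sp <- normalization_spec(reps)
#' range(normalize_cols(reps, sp)$value)  # -1 .. 1
#' @export
normalization_spec <- function(data, cols = c(ion_names(), "value")) {
  stopifnot_cols(data, cols, "data")
  mn <- vapply(data[cols], min, numeric(1))
  mx <- vapply(data[cols], max, numeric(1))
  flat <- cols[mx <= mn]
  if (length(flat)) {
    stop(sprintf("column(s) with zero range cannot be normalized: %s",
                 paste(flat, collapse = ", ")), call. = FALSE)
  }
  structure(list(min = mn, max = mx), class = "norm_spec")
}

#' @rdname normalization_spec
#' @param spec A `"norm_spec"` object.
#' @export
normalize_cols <- function(data, spec) {
  stopifnot(inherits(spec, "norm_spec"))
  for (col in intersect(names(spec$min), names(data))) {
    data[[col]] <- 2 * (data[[col]] - spec$min[[col]]) /
      (spec$max[[col]] - spec$min[[col]]) - 1
  }
  data
}

#' @rdname normalization_spec
#' @export
denormalize_cols <- function(data, spec) {
  stopifnot(inherits(spec, "norm_spec"))
  for (col in intersect(names(spec$min), names(data))) {
    data[[col]] <- (data[[col]] + 1) / 2 *
      (spec$max[[col]] - spec$min[[col]]) + spec$min[[col]]
  }
  data
}

# Scalar (vector) forms used internally by the model code.
norm_vec <- function(x, mn, mx) 2 * (x - mn) / (mx - mn) - 1
denorm_vec <- function(x, mn, mx) (x + 1) / 2 * (mx - mn) + mn

#' Random train/test split with media-coverage guard
#'
#' Splits replicate rows into disjoint train and test partitions of the
#' requested sizes. To avoid degenerate splits, both partitions must touch
#' at least `min_media` distinct media (or all of them, when fewer exist);
#' the draw is repeated (deterministically) until the guard holds.
#'
#' @param rows Replicate data frame (from [expand_replicates()]), with a
#'   `code` column.
#' @param n_train,n_test Partition sizes; must sum to `nrow(rows)`.
#'   Defaults 130/86 match the source study's split of 216 lines.
#' @param seed Integer seed; same seed, same split.
#' @param min_media Coverage guard (default 30).
#' @return List with elements `train` and `test`; each keeps an integer
#'   column `.row` giving the row's index in `rows`.
#' @export
split_train_test <- function(rows, n_train = 130L, n_test = 86L, seed = 1L,
                             min_media = 30L) {
  n <- nrow(rows)
  if (n_train + n_test != n) {
    stop(sprintf("n_train + n_test (%d) must equal nrow(rows) (%d)",
                 n_train + n_test, n), call. = FALSE)
  }
  if (n_train < 1L || n_test < 1L) stop("both partitions must be non-empty",
                                        call. = FALSE)
  rows$.row <- seq_len(n)
  need <- if ("code" %in% names(rows)) {
    min(min_media, length(unique(rows$code)))
  } else 0L
  with_seed(seed, {
    for (attempt in 1:100) {
      tr <- sort(sample.int(n, n_train))
      train <- rows[tr, , drop = FALSE]
      test <- rows[-tr, , drop = FALSE]
      if (need == 0L ||
          (length(unique(train$code)) >= need &&
           length(unique(test$code)) >= need)) {
        rownames(train) <- rownames(test) <- NULL
        return(list(train = train, test = test))
      }
    }
    stop(sprintf("could not find a split covering >= %d media in both partitions",
                 need), call. = FALSE)
  })
}

#' Known-truth benchmark response surfaces
#'
#' Constructs a smooth synthetic response surface over the ion box of the
#' packaged experiment, with an analytically known maximizer, and the
#' treatment table sampling it at the 36 observed ion profiles. Used for
#' end-to-end parameter-recovery tests: fit a network to replicates of the
#' surface, run the genetic algorithm, and compare against the known
#' argmax.
#'
#' `kind = "quadratic_bowl"` is a separable concave quadratic
#' `y(x) = ymax - sum_i curv_i u_i^2` with `u_i` the ion scaled to
#' \[-1, 1\] over the box; its argmax is `center`. `kind = "table6_like"`
#' fits a per-ion quadratic least-squares surface to the packaged rooting
#' percentage means and locates its box-constrained maximum numerically.
#'
#' @param kind Surface family.
#' @param params Optional list: `center` (named ion vector, argmax of the
#'   bowl; default box midpoints), `curv` (length-5 curvatures, default
#'   0.15), `ymax` (default 0.95), `se` (per-treatment SE, default 0.02),
#'   `design` (`"media"`, sample at the 36 observed ion profiles, or
#'   `"uniform"`, draw `n_points` profiles uniformly in the box — the
#'   observed profiles are exactly collinear, so use `"uniform"` whenever a
#'   test needs input importance to be identifiable), `n_points` (default
#'   36, uniform design only), `ridge` (penalty of the `table6_like`
#'   quadratic fit, default 1).
#' @param seed Seed for the uniform design draw and `table6_like`'s
#'   numerical argmax restarts.
#' @return Object of class `"benchmark_surface"`: list with `kind`,
#'   `treatments` (layout of [gn15_treatments()] with a `y` response),
#'   `truth` (vectorized function of an ion data frame), `argmax` (named
#'   vector), `maximum`, and `bounds` (2 x 5 matrix).
#' @export
benchmark_surface <- function(kind = c("quadratic_bowl", "table6_like"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  base <- gn15_treatments()
  ions <- base[ion_names()]
  lo <- vapply(ions, min, numeric(1))
  hi <- vapply(ions, max, numeric(1))
  bounds <- rbind(lower = lo, upper = hi)
  design <- match.arg(params$design %||% "media", c("media", "uniform"))
  if (design == "uniform") {
    n_points <- params$n_points %||% 36L
    ions <- with_seed(seed, as.data.frame(
      vapply(seq_along(lo), function(j) stats::runif(n_points, lo[j], hi[j]),
             numeric(n_points))))
    names(ions) <- ion_names()
    base <- data.frame(code = seq_len(n_points),
                       n_reps = rep(base$n_reps[1L], n_points))
  }

  if (kind == "quadratic_bowl") {
    center <- params$center %||% ((lo + hi) / 2)
    center <- center[ion_names()]
    curv <- rep_len(params$curv %||% 0.15, 5L)
    ymax <- params$ymax %||% 0.95
    if (any(center < lo) || any(center > hi)) {
      stop("benchmark argmax lies outside the sampled ion bounds", call. = FALSE)
    }
    truth <- function(x) {
      u <- mapply(function(v, a, b, m) (v - m) / ((b - a) / 2),
                  x[ion_names()], lo, hi, center)
      u <- matrix(u, ncol = 5L)
      ymax - drop(u^2 %*% curv)
    }
    argmax <- center
    maximum <- ymax
  } else {
    obs <- gn15_treatments()   # the fit is always to the observed means
    y <- obs$rpct_mean
    X <- as.matrix(obs[ion_names()])
    # ridge-regularized per-ion quadratic on standardized features: the ion
    # design is near-collinear, so unpenalized least squares produces wild
    # off-manifold coefficients; a small penalty keeps the surface on the
    # response's scale while still fitting the means (R^2 ~ 0.98). As a
    # proportion surface, predictions clamp to [0, 1].
    lam <- params$ridge %||% 1
    Z <- cbind(X, X^2)
    z_mu <- colMeans(Z)
    z_sd <- apply(Z, 2L, stats::sd)
    Zs <- scale(Z, z_mu, z_sd)
    beta <- solve(crossprod(Zs) + lam * diag(ncol(Zs)),
                  crossprod(Zs, y - mean(y)))
    truth <- function(x) {
      M <- as.matrix(x[ion_names()])
      Zx <- scale(cbind(M, M^2), z_mu, z_sd)
      clamp(mean(y) + drop(Zx %*% beta), 0, 1)
    }
    # box-constrained argmax by multistart quasi-Newton
    best <- with_seed(seed, {
      starts <- rbind((lo + hi) / 2,
                      t(replicate(9, stats::runif(5, lo, hi))))
      res <- apply(starts, 1, function(s) {
        o <- stats::optim(s, function(p) {
          d <- as.data.frame(as.list(stats::setNames(p, ion_names())))
          -truth(d)
        }, method = "L-BFGS-B", lower = lo, upper = hi)
        list(par = o$par, value = -o$value)
      })
      res[[which.max(vapply(res, `[[`, numeric(1), "value"))]]
    })
    argmax <- stats::setNames(best$par, ion_names())
    maximum <- best$value
  }

  se <- params$se %||% 0.02
  # published under the rooting-percentage label so expand_replicates() can
  # consume benchmark treatments directly (same [0,1] domain)
  treatments <- data.frame(code = base$code, ions,
                           rpct_mean = clamp(truth(ions), 0, 1), rpct_se = se,
                           n_reps = base$n_reps, row.names = NULL)
  structure(list(kind = kind, treatments = treatments, truth = truth,
                 argmax = argmax, maximum = maximum, bounds = bounds),
            class = "benchmark_surface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
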