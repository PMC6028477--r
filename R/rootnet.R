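# Feed-forward surrogate network: one hidden layer of tansig units, linear
# output, trained by Levenberg-Marquardt on min-max normalized data.
#
# The topology used throughout the rooting study is 5-8-1: the five ion
# concentrations in, eight hidden units, one response out. Parameters are
# few (57) and the training set small (130 rows), so LM with an analytic
# Jacobian is both exact and fast.

#' Hyperbolic tangent sigmoid activation
#'
#' The hidden-layer transfer function, `2 / (1 + exp(-2 n)) - 1`, which is
#' algebraically `tanh(n)`; values lie in (-1, 1) and saturate for large
#' `|n|`.
#'
#' @param n Numeric vector of net inputs.
#' @return Numeric vector of activations.
#' @examples
#' tansig(0)                # 0
#' tansig(0.5)              # 0.4621...
#' all.equal(tansig(1.3), tanh(1.3))
#' @export
tansig <- function(n) 2 / (1 + exp(-2 * n)) - 1

# ---- weight plumbing ---------------------------------------------------

n_params <- function(p, h) h * p + h + h + 1L

init_weights <- function(p, h, seed) {
  # Nguyen-Widrow initialization for the hidden layer: random directions
  # rescaled so the tansig active regions tile the [-1,1]^p input box, with
  # biases spreading the units along it. Small symmetric uniform weights for
  # the linear output layer. Seeded for reproducibility.
  with_seed(seed, {
    beta <- 0.7 * h^(1 / p)
    W1 <- matrix(stats::runif(h * p, -0.5, 0.5), h, p)
    W1 <- W1 * beta / sqrt(rowSums(W1 * W1))
    b1 <- beta * seq(-1, 1, length.out = h) * sign(W1[, 1L])
    list(W1 = W1, b1 = b1,
         w2 = stats::runif(h, -0.5, 0.5) / sqrt(h),
         b2 = stats::runif(1, -0.5, 0.5))
  })
}

flatten_weights <- function(w) c(as.numeric(w$W1), w$b1, w$w2, w$b2)

unflatten_weights <- function(theta, p, h) {
  list(W1 = matrix(theta[seq_len(h * p)], h, p),
       b1 = theta[h * p + seq_len(h)],
       w2 = theta[h * p + h + seq_len(h)],
       b2 = theta[h * p + 2 * h + 1L])
}

# Forward pass for an n x p input matrix (normalized space).
nn_forward <- function(w, X) {
  H <- tanh(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  drop(H %*% w$w2 + w$b2)
}

# Jacobian of predictions w.r.t. the flattened parameter vector.
# Column order matches flatten_weights(): W1 (column-major, hidden index
# fastest), b1, w2, b2.
nn_jacobian <- function(w, X) {
  n <- nrow(X); p <- ncol(X); h <- length(w$b1)
  H <- tanh(sweep(X %*% t(w$W1), 2L, w$b1, "+"))
  D <- (1 - H * H) * matrix(w$w2, n, h, byrow = TRUE)   # dy/db1
  J_W1 <- D[, rep(seq_len(h), times = p), drop = FALSE] *
    X[, rep(seq_len(p), each = h), drop = FALSE]
  list(J = cbind(J_W1, D, H, 1), H = H)
}

# ---- training ----------------------------------------------------------

#' Training configuration for [rootnet()]
#'
#' Defaults mirror the source study's setup: MSE goal 0.01 (per-sample mean
#' squared error in normalized space), at most 800 epochs,
#' Levenberg-Marquardt. A full-batch gradient-descent-with-momentum
#' fallback is provided under `algorithm = "gdm"`.
#'
#' @param hidden Hidden layer size (default 8).
#' @param max_epochs Maximum accepted training steps (default 800).
#' @param mse_goal Stop once training MSE (per sample, normalized space)
#'   falls to or below this value (default 0.01).
#' @param algorithm `"lm"` (Levenberg-Marquardt, default) or `"gdm"`.
#' @param lambda_init,lambda_factor LM damping: initial value and the
#'   multiplicative adaptation factor (x on rejected steps, / on accepted).
#' @param lambda_max Damping ceiling; exceeding it means no further
#'   improving step exists and training stalls.
#' @param learning_rate,momentum Parameters for the `"gdm"` fallback.
#' @return A list of class `"rootnet_control"`.
#' @export
rootnet_control <- function(hidden = 8L, max_epochs = 800L, mse_goal = 0.01,
                            algorithm = c("lm", "gdm"),
                            lambda_init = 1e-3, lambda_factor = 10,
                            lambda_max = 1e12,
                            learning_rate = 0.05, momentum = 0.9) {
  stopifnot(hidden >= 1L, max_epochs >= 1L, mse_goal > 0,
            lambda_init > 0, lambda_factor > 1)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs), mse_goal = mse_goal,
                 algorithm = match.arg(algorithm),
                 lambda_init = lambda_init, lambda_factor = lambda_factor,
                 lambda_max = lambda_max, learning_rate = learning_rate,
                 momentum = momentum),
            class = "rootnet_control")
}

fit_nn_lm <- function(X, y, control, seed) {
  p <- ncol(X); h <- control$hidden
  w <- init_weights(p, h, seed)
  theta <- flatten_weights(w)
  n <- nrow(X)
  lambda <- control$lambda_init
  r <- nn_forward(w, X) - y
  sse <- sum(r * r)
  if (!is.finite(sse)) stop("non-finite training loss at initialization",
                            call. = FALSE)
  trace <- numeric(control$max_epochs)
  best <- list(theta = theta, sse = sse)
  epochs <- 0L
  stop_reason <- "max_epochs"
  if (sse / n <= control$mse_goal) stop_reason <- "mse_goal"
  ident <- diag(n_params(p, h))
  while (stop_reason == "max_epochs" && epochs < control$max_epochs) {
    jac <- nn_jacobian(w, X)
    g <- crossprod(jac$J, r)
    A <- crossprod(jac$J)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(solve(A + lambda * ident, g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta - drop(step)
        w_new <- unflatten_weights(theta_new, p, h)
        r_new <- nn_forward(w_new, X) - y
        sse_new <- sum(r_new * r_new)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new; w <- w_new; r <- r_new; sse <- sse_new
          lambda <- max(lambda / control$lambda_factor, 1e-12)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        lambda <- lambda * control$lambda_factor
        if (lambda > control$lambda_max) break
      }
    }
    if (!accepted) {
      stop_reason <- "stalled"
      break
    }
    epochs <- epochs + 1L
    trace[epochs] <- sse / n
    if (sse < best$sse) best <- list(theta = theta, sse = sse)
    if (sse / n <= control$mse_goal) stop_reason <- "mse_goal"
  }
  list(weights = unflatten_weights(best$theta, p, h),
       mse = best$sse / n, trace = trace[seq_len(epochs)],
       epochs = epochs, stop_reason = stop_reason)
}

fit_nn_gdm <- function(X, y, control, seed) {
  p <- ncol(X); h <- control$hidden
  w <- init_weights(p, h, seed)
  theta <- flatten_weights(w)
  n <- nrow(X)
  v <- numeric(length(theta))
  trace <- numeric(control$max_epochs)
  best <- list(theta = theta, sse = Inf)
  epochs <- 0L
  stop_reason <- "max_epochs"
  for (e in seq_len(control$max_epochs)) {
    w <- unflatten_weights(theta, p, h)
    r <- nn_forward(w, X) - y
    sse <- sum(r * r)
    if (!is.finite(sse)) stop("non-finite training loss", call. = FALSE)
    if (sse < best$sse) best <- list(theta = theta, sse = sse)
    epochs <- e
    trace[e] <- sse / n
    if (sse / n <= control$mse_goal) {
      stop_reason <- "mse_goal"
      break
    }
    g <- drop(crossprod(nn_jacobian(w, X)$J, r)) / n
    v <- control$momentum * v - control$learning_rate * g
    theta <- theta + v
  }
  list(weights = unflatten_weights(best$theta, p, h),
       mse = best$sse / n, trace = trace[seq_len(epochs)],
       epochs = epochs, stop_reason = stop_reason)
}

#' Fit a feed-forward surrogate network to a rooting response
#'
#' Fits a single-hidden-layer network (tansig hidden units, linear output)
#' by Levenberg-Marquardt least squares. Inputs and the response are
#' min-max normalized to \[-1, 1\] internally; predictions are returned on
#' the original scale. Training stops when the per-sample MSE in normalized
#' space reaches `control$mse_goal`, after `control$max_epochs` accepted
#' steps, or when no improving damped step exists (`"stalled"`); the
#' weights with the lowest recorded training MSE are kept.
#'
#' @param formula Model formula, e.g. `value ~ no3 + nh4 + k + ca + cl`.
#'   Predictors must be numeric.
#' @param data Data frame of training rows (original scale).
#' @param ranges Optional `"norm_spec"` giving the normalization ranges; by
#'   default computed from `data`. Supply the spec of the full dataset when
#'   fitting on a training partition, so train and test share one mapping.
#' @param control A [rootnet_control()] list.
#' @param seed Integer seed controlling weight initialization; fits are
#'   deterministic given it.
#' @return An object of class `"rootnet"` with components `weights` (list
#'   `W1`, `b1`, `w2`, `b2`), `norm` (normalization spec), `trace`
#'   (training MSE per accepted epoch, normalized space), `epochs`,
#'   `stop_reason`, `fitted.values`, `residuals` (original scale), `model`
#'   (the model frame), `call`, `seed`, `control`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()` and `simulate()`.
#' @examples
#' reps <- expand_replicates(gn15_treatments(), "Rpct", seed = 1)
#' fit <- rootnet(value ~ no3 + nh4 + k + ca + cl, reps,
#'                control = rootnet_control(max_epochs = 50), seed = 1)
#' summary(fit)
#' @export
rootnet <- function(formula, data, ranges = NULL,
                    control = rootnet_control(), seed = 1L) {
  cl <- match.call()
  stopifnot(inherits(control, "rootnet_control"))
  mf <- stats::model.frame(formula, data)
  y <- unname(stats::model.response(mf))
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  icpt <- attr(X, "assign") == 0L
  X <- X[, !icpt, drop = FALSE]
  if (ncol(X) < 1L) stop("at least one predictor is required", call. = FALSE)
  if (nrow(X) < 2L) stop("at least two training rows are required", call. = FALSE)
  response_name <- deparse(formula[[2L]])

  if (is.null(ranges)) {
    df_rng <- data.frame(X, check.names = FALSE)
    df_rng[[response_name]] <- y
    if (max(y) == min(y)) {
      warning("constant response; returning a constant predictor")
      obj <- structure(list(
        call = cl, terms = trm, constant = mean(y), weights = NULL,
        var_names = colnames(X), response_name = response_name,
        norm = NULL, trace = numeric(0), epochs = 0L,
        stop_reason = "constant_response", control = control, seed = seed,
        fitted.values = rep(mean(y), length(y)),
        residuals = y - mean(y), model = mf), class = "rootnet")
      return(obj)
    }
    ranges <- normalization_spec(df_rng, c(colnames(X), response_name))
  }
  stopifnot(inherits(ranges, "norm_spec"))
  need <- c(colnames(X), response_name)
  missing_rng <- setdiff(need, names(ranges$min))
  if (length(missing_rng)) {
    stop(sprintf("'ranges' lacks column(s): %s",
                 paste(missing_rng, collapse = ", ")), call. = FALSE)
  }

  Xn <- sweep(sweep(X, 2L, ranges$min[colnames(X)], "-"), 2L,
              (ranges$max - ranges$min)[colnames(X)], "/") * 2 - 1
  yn <- norm_vec(y, ranges$min[[response_name]], ranges$max[[response_name]])

  fit <- switch(control$algorithm,
                lm = fit_nn_lm(Xn, yn, control, seed),
                gdm = fit_nn_gdm(Xn, yn, control, seed))

  fitted_n <- nn_forward(fit$weights, Xn)
  fitted_o <- unname(denorm_vec(fitted_n, ranges$min[[response_name]],
                                ranges$max[[response_name]]))
  structure(list(call = cl, terms = trm, weights = fit$weights,
                 var_names = colnames(X), response_name = response_name,
                 norm = ranges, trace = fit$trace, epochs = fit$epochs,
                 stop_reason = fit$stop_reason, mse_train = fit$mse,
                 control = control, seed = seed,
                 fitted.values = fitted_o, residuals = y - fitted_o,
                 model = mf),
            class = "rootnet")
}
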