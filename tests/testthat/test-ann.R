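# Network forward pass, training behavior, and the fitted-model methods.

test_that("tansig matches its closed form and tanh", {
  expect_equal(tansig(0), 0)
  expect_equal(tansig(0.5), 2 / (1 + exp(-1)) - 1)  # 0.462117...
  expect_equal(tansig(0.5), 0.4621172, tolerance = 1e-7)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(tansig(x), tanh(x))
  expect_equal(tansig(-x), -tansig(x))
  expect_lt(1 - tansig(20), 1e-12)
})

test_that("forward pass equals the independent nested-loop oracle", {
  set.seed(2024)
  for (i in 1:200) {
    w <- random_weights()
    x <- rnorm(5)
    ours <- rootnet:::nn_forward(w, matrix(x, 1))
    theirs <- oracle_forward(w$W1, w$b1, w$w2, w$b2, x)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
  # batched evaluation agrees with row-by-row evaluation
  w <- random_weights()
  X <- matrix(rnorm(50), 10, 5)
  batch <- rootnet:::nn_forward(w, X)
  rowwise <- apply(X, 1, function(x) oracle_forward(w$W1, w$b1, w$w2, w$b2, x))
  expect_equal(batch, rowwise, tolerance = 1e-12)
})

test_that("degenerate weight configurations reduce the network correctly", {
  zero <- list(W1 = matrix(0, 8, 5), b1 = rep(0, 8), w2 = rep(0, 8), b2 = 0)
  X <- matrix(rnorm(25), 5, 5)
  expect_equal(rootnet:::nn_forward(zero, X), rep(0, 5))

  # single-unit passthrough: output = tansig(x1)
  pass <- list(W1 = rbind(c(1, 0, 0, 0, 0), matrix(0, 7, 5)),
               b1 = rep(0, 8), w2 = c(1, rep(0, 7)), b2 = 0)
  expect_equal(rootnet:::nn_forward(pass, X), tansig(X[, 1]))
})

test_that("training reaches the MSE goal on a realizable linear target", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "Rpct", seed = 1)
  reps$value <- reps$no3 / max(reps$no3)   # noiseless function of one input
  fit <- rootnet(ion_formula, reps, seed = 2)
  expect_equal(fit$stop_reason, "mse_goal")
  expect_lt(fit$epochs, 800L)
  expect_lte(fit$mse_train, 0.01)
})

test_that("training is deterministic given the seed and models are independent", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "Rpct", seed = 1)
  f1 <- rootnet(ion_formula, reps, seed = 5)
  # fitting an unrelated response in between must not change anything
  other <- expand_replicates(tr, "RL", seed = 9)
  invisible(rootnet(ion_formula, other, seed = 6))
  f2 <- rootnet(ion_formula, reps, seed = 5)
  expect_identical(coef(f1), coef(f2))
  expect_identical(fitted(f1), fitted(f2))
  f3 <- rootnet(ion_formula, reps, seed = 6)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("training loss trace is non-increasing across accepted LM steps", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "RN", seed = 3)
  fit <- rootnet(ion_formula, reps, seed = 4)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("a network can recover the function of a frozen random generator", {
  set.seed(77)
  gen <- random_weights()
  gen$W1 <- gen$W1 * 0.5   # keep the generator surface smooth
  X <- matrix(runif(500 * 5, -1, 1), ncol = 5)
  df <- as.data.frame(X)
  names(df) <- c("no3", "nh4", "k", "ca", "cl")
  df$value <- rootnet:::nn_forward(gen, X)
  # noiseless target: tighten the MSE goal so training runs to convergence
  fit <- rootnet(ion_formula, df, seed = 10,
                 control = rootnet_control(mse_goal = 1e-6))
  grid <- matrix(runif(200 * 5, -1, 1), ncol = 5)
  gdf <- as.data.frame(grid)
  names(gdf) <- c("no3", "nh4", "k", "ca", "cl")
  expect_gt(r_squared(rootnet:::nn_forward(gen, grid), predict(fit, gdf)), 0.99)
})

test_that("constant targets yield a warned constant predictor", {
  df <- data.frame(no3 = runif(30), nh4 = runif(30), k = runif(30),
                   ca = runif(30), cl = runif(30), value = 0.5)
  expect_warning(fit <- rootnet(ion_formula, df), "constant")
  expect_equal(unname(predict(fit, df[1:3, ])), rep(0.5, 3))
})

test_that("gradient-descent fallback trains and is seeded", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "Rpct", seed = 1)
  ctl <- rootnet_control(algorithm = "gdm", max_epochs = 300)
  g1 <- rootnet(ion_formula, reps, control = ctl, seed = 3)
  g2 <- rootnet(ion_formula, reps, control = ctl, seed = 3)
  expect_identical(coef(g1), coef(g2))
  expect_gt(r_squared(reps$value, fitted(g1)), 0.7)
})

test_that("fitted-model methods are coherent", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "FW", seed = 6)
  fit <- rootnet(ion_formula, reps, seed = 7)
  expect_equal(fitted(fit) + residuals(fit), reps$value)
  expect_length(coef(fit), 5 * 8 + 8 + 8 + 1)
  expect_output(print(fit), "5-8-1")
  sm <- summary(fit)
  expect_output(print(sm), "Training metrics")
  expect_equal(unname(sm$metrics["r_squared"]),
               r_squared(reps$value, fitted(fit)))
  # normalized-scale predictions map back through the response range
  pn <- predict(fit, reps, type = "normalized")
  rng <- fit$norm
  expect_equal((pn + 1) / 2 * (rng$max[["value"]] - rng$min[["value"]]) +
                 rng$min[["value"]],
               predict(fit, reps))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(216L, 3L))
  expect_true(all(sims >= 0))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
})
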