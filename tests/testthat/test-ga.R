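# Genetic-algorithm operators and the box-constrained optimizer.

test_that("roulette selection is fitness-proportionate", {
  set.seed(1)
  # dominant fitness takes essentially every draw
  sel <- roulette_select(c(0, 0, 1), 2000)
  expect_gt(mean(sel == 3L), 0.99)
  # equal fitness selects uniformly (binomial CI around 1/3)
  sel <- roulette_select(c(2, 2, 2), 30000)
  freq <- tabulate(sel, 3) / 30000
  expect_true(all(abs(freq - 1 / 3) < 0.01))
  # positive fitness (1, 3): exact probability 3/4
  sel <- roulette_select(c(1, 3), 100000)
  expect_equal(mean(sel == 2L), 0.75, tolerance = 0.01)
  # all-negative fitness is handled by the shift
  sel <- roulette_select(c(-3, -1), 5000)
  expect_gt(mean(sel == 2L), 0.8)
  expect_error(roulette_select(c(NA, NaN), 5), "finite")
})

test_that("crossover copies or blends, preserving identical parents", {
  set.seed(2)
  a <- c(1, 2, 3, 4, 5)
  b <- c(5, 4, 3, 2, 1)
  off <- ga_crossover(a, b, rate = 0)
  expect_identical(off, list(a, b))
  for (i in 1:20) {
    off <- ga_crossover(a, a, rate = 1)
    expect_equal(off[[1]], a)
    expect_equal(off[[2]], a)
  }
  # blended offspring stay on the segment between parents
  for (i in 1:50) {
    off <- ga_crossover(a, b, rate = 1)
    expect_true(all(off[[1]] >= pmin(a, b) - 1e-12 &
                    off[[1]] <= pmax(a, b) + 1e-12))
  }
})

test_that("mutation never leaves the bounds even at the boundary", {
  set.seed(3)
  bounds <- rbind(lower = c(0, 0), upper = c(1, 10))
  at_upper <- c(1, 10)
  for (i in 1:10000) {
    m <- ga_mutate(at_upper, rate = 1, scale = 5, bounds = bounds)
    expect_true(all(m >= bounds[1, ] & m <= bounds[2, ]))
  }
})

test_that("optimizer trajectory is non-decreasing with elitism and candidates stay in bounds", {
  bounds <- rbind(lower = c(0, 0, 0), upper = c(1, 2, 3))
  seen_outside <- FALSE
  f <- function(X) {
    if (any(sweep(X, 2, bounds[1, ]) < -1e-9) ||
        any(sweep(X, 2, bounds[2, ]) > 1e-9)) seen_outside <<- TRUE
    rowSums(X)
  }
  res <- ga_optimize(f, bounds = bounds,
                     control = ga_control(20, 60), seed = 4)
  expect_false(seen_outside)
  expect_true(all(diff(res$trajectory) >= 0))
  expect_true(all(res$par >= bounds[1, ] & res$par <= bounds[2, ]))
})

test_that("a monotone one-dimensional surface drives the optimum to the corner", {
  bounds <- rbind(lower = c(0, 0, 0, 0, 0), upper = c(1, 1, 1, 5, 1))
  res <- ga_optimize(function(X) X[, 4], bounds = bounds,
                     control = ga_control(30, 100), seed = 5)
  expect_gt(res$par[4], 5 * 0.98)
})

test_that("a single-generation run is brute force over the initial population", {
  bounds <- rbind(lower = c(-1, -1), upper = c(1, 1))
  f <- function(X) -rowSums(X^2)
  res <- ga_optimize(f, bounds = bounds,
                     control = ga_control(population_size = 2, generations = 1),
                     seed = 6)
  # reconstruct the seeded initial population independently
  set.seed(6L)
  pop <- matrix(sapply(1:2, function(j) runif(2, bounds[1, j], bounds[2, j])),
                nrow = 2)
  fits <- f(pop)
  expect_equal(res$value, max(fits))
  expect_equal(unname(res$par), pop[which.max(fits), ])
  expect_length(res$trajectory, 1L)
})

test_that("the optimizer recovers the analytic argmax of the quadratic bowl", {
  bs <- benchmark_surface("quadratic_bowl", seed = 7)
  f <- function(X) {
    df <- as.data.frame(X)
    names(df) <- c("no3", "nh4", "k", "ca", "cl")
    bs$truth(df)
  }
  res <- ga_optimize(f, bounds = bs$bounds, seed = 8)
  width <- bs$bounds[2, ] - bs$bounds[1, ]
  expect_true(all(abs(res$par - bs$argmax) / width < 0.05))
  expect_lt(abs(res$value - bs$maximum) / abs(bs$maximum), 0.02)
})

test_that("runs are deterministic given the seed", {
  bounds <- rbind(lower = rep(0, 3), upper = rep(1, 3))
  f <- function(X) X[, 1] * X[, 2] - X[, 3]
  r1 <- ga_optimize(f, bounds = bounds, control = ga_control(10, 30), seed = 9)
  r2 <- ga_optimize(f, bounds = bounds, control = ga_control(10, 30), seed = 9)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("salt-space optimization returns stoichiometry-consistent optima", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "Rpct", seed = 41)
  spec <- normalization_spec(reps)
  parts <- split_train_test(reps, seed = 42)
  fit <- rootnet(ion_formula, parts$train, ranges = spec, seed = 43)
  res <- optimize_medium(fit, control = ga_control(generations = 100), seed = 44)
  med <- gn15_media()
  for (col in names(res$salts)) {
    expect_gte(res$salts[[col]], min(med[[col]]))
    expect_lte(res$salts[[col]], max(med[[col]]))
  }
  # reported ions are exactly the stoichiometric image of the salts
  fdf <- data.frame(code = 1L, as.list(res$salts), check.names = FALSE)
  ions <- ions_from_salts(fdf)
  expect_equal(unname(res$par),
               unname(unlist(ions[c("no3", "nh4", "k", "ca", "cl")])))
  # and the reported value is the model prediction there
  expect_equal(res$value, unname(predict(fit, ions)))
})
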