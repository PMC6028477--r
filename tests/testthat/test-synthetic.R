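# Replicate expansion, normalization, splitting, benchmark surfaces.

test_that("replicate expansion has the right shape and respects domains", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "Rpct", seed = 1)
  expect_equal(nrow(reps), 216L)
  expect_equal(as.integer(table(reps$code)), rep(6L, 36L))
  expect_true(all(reps$value >= 0 & reps$value <= 1))

  rn <- expand_replicates(tr, "RN", seed = 1)
  expect_true(all(rn$value >= 0))

  # same seed, same draw; different seed, different draw
  expect_identical(expand_replicates(tr, "FW", seed = 7),
                   expand_replicates(tr, "FW", seed = 7))
  expect_false(identical(expand_replicates(tr, "FW", seed = 7),
                         expand_replicates(tr, "FW", seed = 8)))

  expect_error(expand_replicates(tr, "XX", seed = 1), "unknown response")
})

test_that("zero-SE treatments replicate their mean exactly", {
  toy <- toy_treatments(se = 0)
  reps <- expand_replicates(toy, "Rpct", seed = 3)
  expect_equal(reps$value, rep(toy$rpct_mean, each = 6L))
})

test_that("noise model recovers the printed mean in expectation", {
  # Monte-Carlo check: many draws from one treatment, SD = SE * sqrt(6)
  tr <- gn15_treatments()[1, ]
  mc <- expand_replicates(tr, "RN", seed = 42, n_reps = 10000L)
  expect_equal(nrow(mc), 10000L)
  expect_equal(mean(mc$value), 8.17, tolerance = 0.05 / 8.17)
  expect_equal(sd(mc$value), 0.31 * sqrt(6), tolerance = 0.03)
})

test_that("rooting-percentage replicates are clamped into [0, 1]", {
  toy <- toy_treatments(se = 0.5)   # huge SE forces clamping
  reps <- expand_replicates(toy, "Rpct", seed = 5, n_reps = 500L)
  expect_true(all(reps$value >= 0 & reps$value <= 1))
  expect_true(any(reps$value == 0) || any(reps$value == 1))
})

test_that("normalization maps the data range onto [-1, 1] and inverts exactly", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "RL", seed = 2)
  sp <- normalization_spec(reps)
  nn <- normalize_cols(reps, sp)
  for (col in c("no3", "nh4", "k", "ca", "cl", "value")) {
    expect_equal(range(nn[[col]]), c(-1, 1))
  }
  # midpoint of a range maps to zero
  mid <- data.frame(value = (sp$min[["value"]] + sp$max[["value"]]) / 2)
  expect_equal(normalize_cols(mid, sp)$value, 0)

  # round trip to machine precision on random vectors
  set.seed(99)
  rand <- data.frame(value = runif(1000, -50, 50))
  back <- denormalize_cols(normalize_cols(rand, sp), sp)
  expect_equal(back$value, rand$value, tolerance = 1e-12)

  flat <- data.frame(a = rep(1, 5))
  expect_error(normalization_spec(flat, "a"), "zero range")
})

test_that("train/test split is exact, disjoint, reproducible and covering", {
  tr <- gn15_treatments()
  reps <- expand_replicates(tr, "DW", seed = 4)
  parts <- split_train_test(reps, seed = 11)
  expect_equal(nrow(parts$train), 130L)
  expect_equal(nrow(parts$test), 86L)
  expect_length(intersect(parts$train$.row, parts$test$.row), 0L)
  expect_equal(sort(c(parts$train$.row, parts$test$.row)), 1:216)
  expect_gte(length(unique(parts$train$code)), 30L)
  expect_gte(length(unique(parts$test$code)), 30L)

  again <- split_train_test(reps, seed = 11)
  expect_identical(parts, again)

  expect_error(split_train_test(reps, n_train = 100, n_test = 100, seed = 1),
               "must equal")
})

test_that("quadratic benchmark surface has its stated argmax and exact means", {
  bs <- benchmark_surface("quadratic_bowl", seed = 1)
  box_mid <- (bs$bounds[1, ] + bs$bounds[2, ]) / 2
  expect_equal(bs$argmax, box_mid)
  expect_equal(unname(bs$truth(as.data.frame(as.list(bs$argmax)))), bs$maximum)

  # zero noise: sampled treatment means equal the surface exactly
  bs0 <- benchmark_surface("quadratic_bowl", params = list(se = 0), seed = 1)
  reps <- expand_replicates(bs0$treatments, "Rpct", seed = 2)
  truth_at <- bs0$truth(reps[c("no3", "nh4", "k", "ca", "cl")])
  expect_equal(reps$value, pmin(pmax(truth_at, 0), 1))

  # argmax outside the sampled bounds is rejected
  bad_center <- bs$bounds[2, ] * 2
  expect_error(benchmark_surface("quadratic_bowl",
                                 params = list(center = bad_center)),
               "outside")
})

test_that("table6-like surface stays on the response scale", {
  bt <- benchmark_surface("table6_like", seed = 3)
  expect_true(bt$maximum >= 0 && bt$maximum <= 1)
  expect_true(all(bt$argmax >= bt$bounds[1, ] & bt$argmax <= bt$bounds[2, ]))
  # evaluating on a grid never leaves [0, 1]
  set.seed(17)
  grid <- as.data.frame(sapply(seq_len(5), function(j)
    runif(200, bt$bounds[1, j], bt$bounds[2, j])))
  names(grid) <- c("no3", "nh4", "k", "ca", "cl")
  vals <- bt$truth(grid)
  expect_true(all(vals >= 0 & vals <= 1))
  # and it fits the observed treatment means well
  obs <- gn15_treatments()
  expect_gt(r_squared(obs$rpct_mean, bt$truth(obs)), 0.9)
})
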