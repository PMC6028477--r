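# Independent oracles and small fixture builders used across tests.

# Brute-force nested-loop evaluation of a 5-8-1 (or any p-h-1) network:
# written without matrix algebra on purpose, so it shares nothing with the
# package's vectorized forward pass.
oracle_forward <- function(W1, b1, w2, b2, x) {
  h <- length(b1)
  out <- b2
  for (i in seq_len(h)) {
    s <- b1[i]
    for (j in seq_along(x)) s <- s + W1[i, j] * x[j]
    act <- 2 / (1 + exp(-2 * s)) - 1
    out <- out + w2[i] * act
  }
  out
}

random_weights <- function(p = 5L, h = 8L) {
  list(W1 = matrix(stats::rnorm(h * p), h, p), b1 = stats::rnorm(h),
       w2 = stats::rnorm(h), b2 = stats::rnorm(1))
}

# A 4-treatment toy table in the layout of gn15_treatments().
toy_treatments <- function(se = 0.02) {
  data.frame(code = 1:4,
             no3 = c(20, 30, 40, 25), nh4 = c(10, 15, 20, 12),
             k = c(9.4, 14, 18.8, 10), ca = c(1.2, 2.3, 3, 1.5),
             cl = c(0, 1.5, 3, 0),
             rpct_mean = c(0.4, 0.7, 0.9, 0.5), rpct_se = se,
             rn_mean = c(5, 9, 14, 6), rn_se = se * 10,
             n_reps = 6L)
}

ion_formula <- value ~ no3 + nh4 + k + ca + cl

# Shared seed scheme for multi-seed experiments on the packaged data.
seed_of <- function(s, stage) 100L * s + stage
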