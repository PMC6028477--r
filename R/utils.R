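# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical ion order used everywhere: fixed so tie-breaks and reports are
# reproducible independent of how a data frame happens to be ordered.
ion_names <- function() c("no3", "nh4", "k", "ca", "cl")

# Canonical response labels; "R%" and "Rpct" both accepted on input.
response_names <- function() c("RN", "RL", "Rpct", "FW", "DW")

match_response <- function(response) {
  if (length(response) != 1L || !is.character(response)) {
    stop("'response' must be a single character label", call. = FALSE)
  }
  r <- sub("^R%$", "Rpct", response)
  if (!r %in% response_names()) {
    stop(sprintf("unknown response label '%s' (use one of %s)", response,
                 paste(c(response_names(), "R%"), collapse = ", ")),
         call. = FALSE)
  }
  r
}

# Physical domain of each response: all are non-negative, rooting percentage
# is a proportion.
response_domain <- function(response) {
  response <- match_response(response)
  if (response == "Rpct") c(0, 1) else c(0, Inf)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
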