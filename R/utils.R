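# Internal helpers shared across modules.

# Deterministic 31-bit seed from a master seed plus arbitrary tags, so every
# restart / permutation draws from its own reproducible stream.
derive_seed <- function(master, ...) {
  tag <- paste(c(format(master), vapply(list(...), format, character(1))),
               collapse = "|")
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Half-up decimal rounding (the convention needed to invert printed
# one-decimal percentages; R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Display a p-value threshold at two significant figures
#'
#' Formats a threshold the way journals print them, e.g. `0.05/74` becomes
#' `"6.8e-04"`.
#'
#' @param x positive numeric value.
#' @return character scalar in `m.me-xx` scientific notation.
#' @export
format_signif_threshold <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1, x > 0)
  e <- floor(log10(x))
  m <- round_half_up(x / 10^e, 1)
  if (m >= 10) {
    m <- m / 10
    e <- e + 1
  }
  sprintf("%.1fe%+03d", m, e)
}

#' Simulated-annealing acceptance probability
#'
#' The Metropolis rule used by the search: a proposal changing the deviance by
#' `delta` at temperature `temp` is accepted with probability
#' `min(1, exp(-delta / temp))`. Exposed so the cooling-limit behaviour
#' (greedy descent as `temp -> 0`, random walk as `temp -> Inf`) can be
#' inspected directly.
#'
#' @param delta deviance change of the proposal (new minus current).
#' @param temp positive temperature.
#' @return acceptance probability in `[0, 1]`.
#' @export
accept_probability <- function(delta, temp) {
  stopifnot(all(temp > 0))
  pmin(1, exp(-delta / temp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
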