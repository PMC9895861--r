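# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention that reproduces every verifiable printed percentage in the
#' reference tables (base R's `round()` uses banker's rounding instead).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.25, 1) # 0.3, not 0.2
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' `100 * count / n`, rounded half-away-from-zero to one decimal place --
#' the arithmetic behind every printed prevalence and exclusion percentage.
#'
#' @param count Nonnegative count.
#' @param n Positive total.
#' @return Percentage in `[0, 100]` with one decimal.
#' @export
#' @examples
#' prevalence_pct(358, 503) # 71.2
prevalence_pct <- function(count, n) {
  stopifnot(n > 0, count >= 0, count <= n)
  round_half_away(100 * count / n, 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_symptomnet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "symptomnet_error")))
}
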