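#' @keywords internal
"_PACKAGE"

## classed conditions so callers can distinguish bad inputs from bugs
stop_invalid <- function(msg, class = "ovatome_invalid_input") {
  stop(errorCondition(msg, class = c(class, "ovatome_error")))
}

stop_format <- function(msg) stop_invalid(msg, class = "ovatome_format_error")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so generators are bit-reproducible without
#' clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

## deterministic substreams: one top-level seed fans out per generator,
## kept strictly inside 32-bit integer range
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + stream * 9973
  as.integer(s %% 2147483647L) + 1L
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables round half up to match
#' how bench numbers are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
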