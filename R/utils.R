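# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tallies in this field
#' conventionally round half up (1/15 prints as 6.7%). Used for all reported
#' percentages.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
# Keeps every generator a pure function of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# stop() with call.=FALSE everywhere for cleaner user-facing errors
abort <- function(...) stop(..., call. = FALSE)
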