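# RNG hygiene: run code under a given seed without disturbing the
# caller's global RNG stream.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Stage seeds are split from the master seed by a fixed affine scheme,
#' `(seed * 48271 + stream) mod (2^31 - 1)`, so any stochastic stage of
#' a study can be re-run in isolation and reproduced bit-for-bit.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  m <- 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(stream)
  as.integer(s %% m + 1)
}

# Report-table number formatting: 3 decimals for effects, scientific
# notation (mantissa to 3 decimals) for values below 0.001 in magnitude.
format_effect <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 0.001) {
      formatC(v, format = "E", digits = 3)
    } else {
      formatC(round(v, 3), format = "f", digits = 3)
    }
  }, character(1))
}

format_pval <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v < 0.001) formatC(v, format = "E", digits = 3)
    else formatC(round(v, 3), format = "f", digits = 3)
  }, character(1))
}
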