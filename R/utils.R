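# Internal helpers.

# Run `expr` under a fixed, platform-independent RNG state, restoring the
# caller's state afterwards. All stochastic package code funnels through
# this so results are reproducible regardless of the session's RNG kind.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  oldKind <- RNGkind()
  on.exit({
    RNGkind(oldKind[1L], oldKind[2L], oldKind[3L])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed that stays inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 7919L) %% 2147483647)
}

# Round half away from zero at `digits` decimals (the rounding convention of
# remote-sensing accuracy tables; base round() is half-to-even).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
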