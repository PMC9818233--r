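# Internal helpers shared across modules.

# Evaluate `expr` under a deterministic RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards. All stochastic code in the
# package funnels through this so identical seeds give bit-identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Round half away from zero (the convention used by the printed report
# tables); base round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Reduce a positive rational target/source to smallest integer p/q.
rational_ratio <- function(target, source, scale = 1e6) {
  p <- round(target * scale)
  q <- round(source * scale)
  g <- gcd_int(p, q)
  c(p = p / g, q = q / g)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
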