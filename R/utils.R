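# small numerical helpers shared across modules

# trapezoidal integral of y sampled at constant rate (Hz)
trapz_rate <- function(y, rate) {
  n <- length(y)
  if (n < 2L) return(0)
  (sum(y) - (y[1L] + y[n]) / 2) / rate
}

# composite Simpson integral at constant rate; falls back to a trapezoid
# for the leftover interval (odd interval count) and for very short series.
# Needed because a plain trapezoid at 120 Hz biases half-sine lobes of
# ~0.05 s duration by > 2 %, beyond the accuracy the impulse contract asks.
simpson_rate <- function(y, rate) {
  n <- length(y)
  if (n < 3L) return(trapz_rate(y, rate))
  m <- if ((n - 1L) %% 2L == 0L) n else n - 1L
  i <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1L] <- 1; w[m] <- 1
  s <- sum(w * y[i]) / (3 * rate)
  if (m < n) s <- s + (y[n - 1L] + y[n]) / (2 * rate)
  s
}

# unwrap a phase-like series in degrees (jumps > 180 deg folded back)
unwrap_deg <- function(x) {
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  c(x[1L], x[1L] + cumsum(d))
}

# deterministic sub-seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p)) %% 2147483647
  as.integer(s)
}

# evaluate a piecewise-constant schedule tibble (t_start, value) at times t
piecewise_at <- function(schedule, t, value_col = "speed") {
  idx <- findInterval(t, schedule$t_start)
  idx[idx < 1L] <- 1L
  schedule[[value_col]][idx]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rnorm_clip <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}
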