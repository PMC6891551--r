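# Shared numerical helpers.

# Quintic smoothstep: C2 monotone ramp on [0, 1] with zero first and second
# derivatives at both ends. Used for all synthetic trajectory segments so
# that knots are the only interior extrema.
smoothstep <- function(u) u * u * u * (10 + u * (-15 + 6 * u))

# Piecewise smoothstep interpolation through (kt, kv) knots; values are held
# constant outside the knot range. Knot times must be strictly increasing.
interp_knots <- function(kt, kv, t) {
  stopifnot(length(kt) == length(kv), all(diff(kt) > 0))
  idx <- findInterval(t, kt)
  v <- numeric(length(t))
  v[idx <= 0] <- kv[1]
  v[idx >= length(kt)] <- kv[length(kt)]
  inside <- idx >= 1 & idx < length(kt)
  i <- idx[inside]
  u <- (t[inside] - kt[i]) / (kt[i + 1] - kt[i])
  v[inside] <- kv[i] + (kv[i + 1] - kv[i]) * smoothstep(u)
  v
}

# Indices of interior local minima. Plateaus count once, at their first
# sample (ties broken toward earlier frames).
local_minima <- function(z) {
  if (length(z) < 3) return(integer(0))
  d <- diff(z)
  s <- sign(d)
  s[s == 0] <- 1
  which(diff(s) > 0) + 1L
}

# Trailing moving average of width w (samples), aligned so element i
# averages x[(i - w + 1):i]. Used for the pre-contact velocity gate.
rollmean_trailing <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0)
  (cs[i + 1] - cs[lo + 1]) / (i - lo)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-subject RNG stream from a base seed; stays below 2^31.
subject_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}
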