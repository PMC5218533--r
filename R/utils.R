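# Internal helpers: scoped RNG and circular sampling.

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive an independent substream seed from a master seed, so adding one
# signal to a simulation never perturbs the draws of another. Linear hash
# kept inside the 32-bit integer range.
substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1299709) %% 2147483647
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution on
# angles (radians). kappa = 0 degenerates to the uniform distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
        break
      }
    }
  }
  out %% (2 * pi)
}

# von Mises sample expressed as cycle fractions in [0, 1)
rvonmises_phase <- function(n, mu_phase, kappa) {
  (rvonmises(n, 2 * pi * mu_phase, kappa) / (2 * pi)) %% 1
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  bad_lo <- if (open_lower) x <= lower else x < lower
  bad_hi <- if (open_upper) x >= upper else x > upper
  if (bad_lo || bad_hi)
    stop(sprintf("`%s` = %g is outside its valid range", name, x))
  invisible(x)
}
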