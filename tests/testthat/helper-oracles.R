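# Independent oracles, deliberately written as literal loops so they share
# no code path with the vectorised implementations they check.

# Event-by-event replay of the debounce state machine. DEBOUNCING
# accumulates chained impulses and discards them on a long gap; reaching
# the required count (at least two impulses make a grouping) promotes to
# COUNTING with retroactive credit; COUNTING adds one step per chained
# impulse and closes on a long gap.
oracle_count_steps <- function(times, dsteps, dt_ms) {
  dt <- dt_ms / 1000 + 1e-9
  need <- max(dsteps, 2)
  steps <- 0L
  discarded <- 0L
  acc <- 0L
  counting <- FALSE
  last <- -Inf
  for (t in times) {
    chained <- (t - last) <= dt
    if (counting) {
      if (chained) {
        steps <- steps + 1L
      } else {
        counting <- FALSE
        acc <- 1L
      }
    } else {
      if (chained) acc <- acc + 1L
      else {
        discarded <- discarded + acc
        acc <- 1L
      }
      if (acc >= need) {
        steps <- steps + acc
        acc <- 0L
        counting <- TRUE
      }
    }
    last <- t
  }
  if (!counting) discarded <- discarded + acc
  list(steps = steps, discarded = discarded)
}

# Direct per-sample moving mean with the plateau rule: output the mean when
# it is whole AND equals every nonzero sample in the (zero-padded) window.
oracle_smooth <- function(labels, window) {
  n <- length(labels)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  padded <- c(rep(0L, left), as.integer(labels), rep(0L, right))
  vapply(seq_len(n), function(i) {
    win <- padded[i:(i + window - 1)]
    m <- mean(win)
    nz <- win[win != 0]
    if (m == round(m) && (length(nz) == 0 || all(nz == m))) as.integer(m) else 0L
  }, integer(1))
}

# Normal-equations least squares, the classical alternative to QR.
oracle_ls_coef <- function(M, y) {
  as.vector(solve(t(M) %*% M, t(M) %*% y))
}

# Direct monomial-sum evaluation of a polynomial model at one point.
oracle_poly_eval <- function(model, x) {
  s <- 0
  for (j in seq_len(nrow(model$exponents)))
    s <- s + model$coefficients[j] * prod(x^model$exponents[j, ])
  s
}

# Settings row without grid validation (for off-grid probes like a 1000 ms
# debounce window).
raw_settings <- function(threshold_mg, debounce_steps, debounce_time_ms) {
  data.frame(threshold_mg = threshold_mg,
             debounce_steps = debounce_steps,
             debounce_time_ms = debounce_time_ms)
}

# Quadratic bowl model with its unique zero at the normalized coordinates
# of one grid setting: error = scale * sum((x - x0)^2) over the three
# setting axes (cadence-independent).
planted_model <- function(th0 = 0.5, ds0 = 0.5, dt0 = 0.5, scale = 0.4) {
  ex <- monomial_exponents(2)
  coefs <- numeric(nrow(ex))
  find <- function(a, b, c, d) {
    which(ex[, 1] == a & ex[, 2] == b & ex[, 3] == c & ex[, 4] == d)
  }
  coefs[find(0, 0, 0, 0)] <- scale * (th0^2 + ds0^2 + dt0^2)
  coefs[find(1, 0, 0, 0)] <- -2 * scale * th0
  coefs[find(0, 1, 0, 0)] <- -2 * scale * ds0
  coefs[find(0, 0, 1, 0)] <- -2 * scale * dt0
  coefs[find(2, 0, 0, 0)] <- scale
  coefs[find(0, 2, 0, 0)] <- scale
  coefs[find(0, 0, 2, 0)] <- scale
  error_model(2, coefs)
}
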