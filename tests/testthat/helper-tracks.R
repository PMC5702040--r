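# Shared fixtures and independent oracles, built in code.

# A straight ship track through the origin, heading north, source at 50 m.
straight_ship <- function(speed = 4.1, t0 = 0, t1 = 600, y0 = 0, depth = 50) {
  tt <- seq(t0, t1, by = 20)
  tibble::tibble(time_s = tt, x_m = 0, y_m = y0 + speed * (tt - t0),
                 depth_m = depth)
}

# A stationary whale "track" (two points suffice for interpolation).
stationary_whale <- function(x, y, depth = 0, t0 = 0, t1 = 600) {
  tibble::tibble(time_s = c(t0, t1), x_m = x, y_m = y, depth_m = depth)
}

# Wrap a pulse tibble as a scheme (for hand-built test schedules).
as_test_scheme <- function(pulses, name = "custom", interval = 20) {
  sonarramp:::new_scheme(tibble::as_tibble(pulses), name, interval)
}

# Baseline turn set drawn with sigma = 30 deg (both directions).
sigma30_baseline_turns <- function(n_per_direction = 175, sd = 30) {
  tibble::tibble(
    direction = rep(c("cw", "ccw"), each = n_per_direction),
    magnitude_deg = abs(stats::rnorm(2 * n_per_direction, 0, sd))
  )
}

# Brute-force pursuit oracle: earliest time (0.1 s steps) at which a ship
# sailing straight at `speed` from `ship` can be at the whale's position.
intercept_oracle <- function(whale0, v, ship, speed = 4.1, t_max = 3600) {
  for (t in seq(0.1, t_max, by = 0.1)) {
    wp <- whale0 + v * t
    if (sqrt(sum((wp - ship)^2)) <= speed * t) return(t)
  }
  NA_real_
}

# Enumeration oracle for Barnard's unconditional test (pooled score
# statistic, uniform nuisance grid), written as plain loops.
barnard_oracle <- function(x1, n1, x2, n2, grid_size = 1001) {
  zstat <- function(a, b) {
    p <- (a + b) / (n1 + n2)
    v <- p * (1 - p) * (1 / n1 + 1 / n2)
    if (v <= 0) return(0)
    (a / n1 - b / n2) / sqrt(v)
  }
  z_obs <- zstat(x1, x2)
  grid <- seq(0, 1, length.out = grid_size + 2)[-c(1, grid_size + 2)]
  best <- 0
  for (p in grid) {
    tot <- 0
    for (a in 0:n1) for (b in 0:n2) {
      if (abs(zstat(a, b)) >= abs(z_obs) - 1e-12) {
        tot <- tot + stats::dbinom(a, n1, p) * stats::dbinom(b, n2, p)
      }
    }
    if (tot > best) best <- tot
  }
  list(Z = z_obs, p = min(1, best))
}
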