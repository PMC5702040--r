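#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Wrap an angle (deg) to [0, 360)
wrap360 <- function(x) x %% 360

# Wrap an angle difference (deg) to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Decibel sum: 10*log10(sum(10^(x/10)))
db_sum <- function(x) 10 * log10(sum(10^(x / 10)))

# Heading (deg clockwise from north) of a displacement (dx east, dy north)
displacement_heading <- function(dx, dy) wrap360(atan2(dx, dy) * 180 / pi)

# Linear interpolation of a track to arbitrary times.
# Errors if any time falls outside the track span.
interp_track <- function(track, times, what = "track") {
  stopifnot(nrow(track) >= 2)
  rng <- range(track$time_s)
  out_of_span <- times < rng[1] - 1e-9 | times > rng[2] + 1e-9
  if (any(out_of_span)) {
    abort(sprintf(
      "%s does not cover requested time(s): %s s (track spans [%g, %g] s)",
      what, paste(signif(times[out_of_span], 6), collapse = ", "), rng[1], rng[2]
    ))
  }
  tibble(
    time_s  = times,
    x_m     = stats::approx(track$time_s, track$x_m, times, rule = 1)$y,
    y_m     = stats::approx(track$time_s, track$y_m, times, rule = 1)$y,
    depth_m = stats::approx(track$time_s, track$depth_m, times, rule = 1)$y
  )
}

assert_track <- function(track, arg = "track") {
  need <- c("time_s", "x_m", "y_m", "depth_m")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    abort(sprintf("`%s` must be a data frame with columns %s",
                  arg, paste(need, collapse = ", ")))
  }
  invisible(track)
}
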