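#' Baseline whale-movement parameters
#'
#' Parameters of the correlated-random-walk generator used to emulate
#' undisturbed whale movement: a 20 s position grid (matching the sonar pulse
#' interval), wrapped-normal turn increments, truncated-normal horizontal
#' speeds, a sinusoidal dive/surfacing cycle with noise, and Poisson feeding
#' lunges restricted to depths below 0.5 m.
#'
#' Defaults describe a slowly meandering feeding humpback: ~1 m/s travel
#' speed, 30 deg step-to-step heading spread, ~7 min dive cycles to ~30 m,
#' and a handful of lunges per hour.
#'
#' @param step_interval_s Track sampling step in seconds (default 20).
#' @param speed_mean_mps,speed_sd_mps Mean and s.d. of the truncated-normal
#'   (lower bound 0.05 m/s) horizontal speed per step.
#' @param turn_sd_deg S.d. of the wrapped-normal heading increment per step
#'   (degrees); 0 gives straight-line motion. The default (10) emulates a
#'   whale in directed travel whose spontaneous turns rarely reach the
#'   90 deg avoidance screen within a 10-min window, matching the field
#'   observation that approach-alone (control) sessions elicit no
#'   avoidance-like turns.
#' @param dive_depth_m Peak dive depth of the sinusoidal dive cycle (m).
#' @param dive_period_s Dive cycle period (s).
#' @param depth_noise_m S.d. of Gaussian depth noise (m).
#' @param lunge_rate_per_hr Expected feeding lunges per hour.
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(step_interval_s = 20,
                            speed_mean_mps = 1.0, speed_sd_mps = 0.3,
                            turn_sd_deg = 10,
                            dive_depth_m = 30, dive_period_s = 420,
                            depth_noise_m = 1.5,
                            lunge_rate_per_hr = 8) {
  p <- list(step_interval_s = step_interval_s,
            speed_mean_mps = speed_mean_mps, speed_sd_mps = speed_sd_mps,
            turn_sd_deg = turn_sd_deg,
            dive_depth_m = dive_depth_m, dive_period_s = dive_period_s,
            depth_noise_m = depth_noise_m,
            lunge_rate_per_hr = lunge_rate_per_hr)
  bad <- c("step_interval_s", "speed_mean_mps", "dive_period_s")
  for (nm in bad) if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
    abort(sprintf("baseline parameter `%s` must be positive", nm))
  }
  for (nm in c("speed_sd_mps", "turn_sd_deg", "dive_depth_m", "depth_noise_m",
               "lunge_rate_per_hr")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      abort(sprintf("baseline parameter `%s` must be non-negative", nm))
    }
  }
  structure(p, class = "baseline_params")
}

#' Generate a baseline (undisturbed) whale track
#'
#' Simulates a correlated random walk on a regular time grid: per-step
#' headings accumulate wrapped-normal increments, per-step speeds are
#' truncated normal, depth follows a sinusoidal dive cycle plus noise
#' (clipped at the surface), and feeding lunges occur as a Poisson process
#' thinned to moments when the whale is deeper than 0.5 m. Lunge event times
#' are attached as attribute `lunge_times_s`.
#'
#' @param params A [baseline_params()] list.
#' @param duration_s Track duration in seconds (at least two steps).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param start_time_s Time of the first point (default 0; negative values
#'   are convenient for pre-session baseline).
#' @param start_xy Numeric length-2 start position (m east, m north).
#' @param start_heading_deg Initial heading; drawn uniformly if `NULL`.
#' @return A track tibble with columns `time_s`, `x_m`, `y_m`, `depth_m`,
#'   `heading_deg` and attribute `lunge_times_s`.
#' @export
generate_baseline_track <- function(params = baseline_params(),
                                    duration_s,
                                    seed = NULL,
                                    start_time_s = 0,
                                    start_xy = c(0, 0),
                                    start_heading_deg = NULL) {
  if (!inherits(params, "baseline_params")) {
    abort("`params` must be created by baseline_params()")
  }
  dt <- params$step_interval_s
  if (duration_s < 2 * dt) abort("`duration_s` must be at least two steps long")
  if (!is.null(seed)) set.seed(seed)

  times <- seq(start_time_s, start_time_s + duration_s, by = dt)
  n <- length(times)
  h0 <- start_heading_deg %||% stats::runif(1, 0, 360)
  # heading for step i is used for the displacement from point i to i+1
  increments <- stats::rnorm(n - 1, 0, params$turn_sd_deg)
  headings <- wrap360(h0 + cumsum(c(0, increments[-(n - 1)])))
  speeds <- rtruncnorm(n - 1, params$speed_mean_mps, params$speed_sd_mps,
                       lower = 0.05)
  dx <- speeds * dt * sin(headings * pi / 180)
  dy <- speeds * dt * cos(headings * pi / 180)
  x <- start_xy[1] + cumsum(c(0, dx))
  y <- start_xy[2] + cumsum(c(0, dy))
  phase <- 2 * pi * (times - start_time_s) / params$dive_period_s
  depth <- pmax(0, params$dive_depth_m * pmax(0, sin(phase)) +
                  stats::rnorm(n, 0, params$depth_noise_m))

  n_lunges <- stats::rpois(1, params$lunge_rate_per_hr * duration_s / 3600)
  lunge_times <- sort(stats::runif(n_lunges, start_time_s, start_time_s + duration_s))
  lunge_depths <- stats::approx(times, depth, lunge_times, rule = 2)$y
  lunge_times <- lunge_times[lunge_depths > 0.5]

  track <- tibble(
    time_s = times, x_m = x, y_m = y, depth_m = depth,
    heading_deg = c(headings, headings[n - 1])
  )
  attr(track, "lunge_times_s") <- lunge_times
  track
}

#' Inject an avoidance response into a whale track
#'
#' From `onset_s` the whale's heading is rotated by `turn_deg` (signed,
#' positive clockwise) and its motion modified until `until_s`:
#'
#' * `rule = "hold"` (default): the rotated heading is held constant, i.e.
#'   directed flight, with horizontal speed `speed_mps` (original per-step
#'   speeds are kept when `speed_mps` is `NULL`);
#' * `rule = "rotate"`: all subsequent step headings are rotated by
#'   `turn_deg` but the baseline wiggle is preserved (with `turn_deg = 0`
#'   and `speed_mps = NULL` this is the identity);
#' * `rule = "ship_relative"`: the held heading is drawn so the whale moves
#'   at a relative heading in `[0, 100)` deg to `ship_course_deg` (the
#'   movement-away criterion of the avoidance detector), on side `side`;
#'   `turn_deg` is then implied, not prescribed.
#'
#' Depth is left unchanged; positions after the onset are rebuilt from the
#' modified headings and speeds.
#'
#' @param track A track tibble on a regular grid (from
#'   [generate_baseline_track()]).
#' @param onset_s Response onset time; must lie within the track span.
#' @param turn_deg Signed turn angle in degrees (clockwise positive).
#' @param speed_mps Post-onset horizontal speed (m/s), or `NULL` to keep the
#'   original per-step speeds. Avoidance speeds observed in ramp-up
#'   responses average about 1.3 m/s.
#' @param rule Post-turn heading rule; see Details.
#' @param ship_course_deg Ship course, required for `rule = "ship_relative"`.
#' @param side +1 or -1: side of the ship course for `"ship_relative"`.
#' @param until_s End of the modified window (default: end of track).
#' @return The modified track tibble (attribute `lunge_times_s` preserved),
#'   with attributes `avoidance_onset_s` and `avoidance_turn_deg`.
#' @export
inject_avoidance <- function(track, onset_s, turn_deg, speed_mps = NULL,
                             rule = c("hold", "rotate", "ship_relative"),
                             ship_course_deg = NULL, side = 1,
                             until_s = NULL) {
  rule <- match.arg(rule)
  assert_track(track)
  times <- track$time_s
  if (onset_s < times[1] || onset_s > times[length(times)]) {
    abort(sprintf("onset_s = %g lies outside the track span [%g, %g]",
                  onset_s, times[1], times[length(times)]))
  }
  until_s <- until_s %||% times[length(times)]
  n <- nrow(track)
  dt <- diff(times[1:2])
  # step i: displacement from point i to i+1, heading track$heading_deg[i]
  step_h <- track$heading_deg[-n]
  step_sp <- sqrt(diff(track$x_m)^2 + diff(track$y_m)^2) / dt
  i0 <- which(times >= onset_s)[1]          # first point affected
  if (i0 >= n) i0 <- n - 1
  affected <- seq_len(n - 1) >= i0 & times[-n] < until_s
  h_pre <- if (i0 > 1) step_h[i0 - 1] else step_h[1]

  new_h <- step_h
  if (rule == "hold") {
    new_h[affected] <- wrap360(h_pre + turn_deg)
  } else if (rule == "rotate") {
    new_h[affected] <- wrap360(step_h[affected] + turn_deg)
  } else {
    if (is.null(ship_course_deg)) {
      abort("`ship_course_deg` is required for rule = \"ship_relative\"")
    }
    rel <- stats::runif(1, 0, 100)
    held <- wrap360(ship_course_deg + sign(side) * rel)
    turn_deg <- wrap180(held - h_pre)
    new_h[affected] <- held
  }
  new_sp <- step_sp
  if (!is.null(speed_mps)) new_sp[affected] <- speed_mps

  dx <- new_sp * dt * sin(new_h * pi / 180)
  dy <- new_sp * dt * cos(new_h * pi / 180)
  out <- track
  out$x_m <- track$x_m[1] + cumsum(c(0, dx))
  out$y_m <- track$y_m[1] + cumsum(c(0, dy))
  out$heading_deg <- c(new_h, new_h[n - 1])
  attr(out, "lunge_times_s") <- attr(track, "lunge_times_s")
  attr(out, "avoidance_onset_s") <- times[i0]
  attr(out, "avoidance_turn_deg") <- turn_deg
  out
}

#' Plan a straight intercept approach
#'
#' Solves the constant-velocity pursuit problem: a ship sailing straight at
#' `ship_speed_mps` must meet a whale whose velocity is estimated by least
#' squares over its most recent fixes (up to 3). The session is scheduled to
#' start when the ship is `start_range_m` (default 1250 m, the distance
#' covered in 5 min at 4.1 m/s) from the predicted intercept point, so that
#' the predicted intercept falls at t = 5 min of the session.
#'
#' If no intercept exists (whale as fast as the ship and diverging), the
#' plan falls back to a course toward the whale's current position and is
#' flagged infeasible.
#'
#' @param whale_fixes Tibble of recent whale fixes (`time_s`, `x_m`, `y_m`),
#'   at least one row; the last row is taken as the current position.
#' @param ship_position Numeric length-2 current ship position (m).
#' @param ship_speed_mps Ship speed (default 4.1 m/s).
#' @param start_range_m Range from intercept at session start (default 1250).
#' @return A one-row tibble: `course_deg`, `session_start_s` (absolute time),
#'   `intercept_x_m`, `intercept_y_m`, `time_to_intercept_s` (from the last
#'   fix), and `feasible`.
#' @export
plan_intercept <- function(whale_fixes, ship_position,
                           ship_speed_mps = 4.1, start_range_m = 1250) {
  if (!is.data.frame(whale_fixes) || nrow(whale_fixes) < 1) {
    abort("`whale_fixes` must contain at least one fix")
  }
  fixes <- utils::tail(whale_fixes, 3)
  now <- fixes$time_s[nrow(fixes)]
  p_w <- c(fixes$x_m[nrow(fixes)], fixes$y_m[nrow(fixes)])
  v <- c(0, 0)
  if (nrow(fixes) >= 2) {
    tt <- fixes$time_s - now
    v <- c(unname(stats::coef(stats::lm(fixes$x_m ~ tt))[2]),
           unname(stats::coef(stats::lm(fixes$y_m ~ tt))[2]))
  }
  d <- p_w - ship_position
  a <- sum(v^2) - ship_speed_mps^2
  b <- 2 * sum(d * v)
  cc <- sum(d^2)
  t_int <- NA_real_
  if (abs(a) < 1e-9) {
    if (b < 0) t_int <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      pos <- roots[roots > 1e-9]
      if (length(pos) > 0) t_int <- min(pos)
    }
  }
  feasible <- is.finite(t_int)
  if (feasible) {
    intercept <- p_w + v * t_int
  } else {
    intercept <- p_w       # fall back: head for the current position
    t_int <- sqrt(cc) / ship_speed_mps
  }
  course <- displacement_heading(intercept[1] - ship_position[1],
                                 intercept[2] - ship_position[2])
  tibble(
    course_deg = course,
    session_start_s = now + t_int - start_range_m / ship_speed_mps,
    intercept_x_m = intercept[1], intercept_y_m = intercept[2],
    time_to_intercept_s = t_int,
    feasible = feasible
  )
}

#' Generate a synthetic controlled exposure experiment
#'
#' Builds one whale's full experiment: a 4 h pre-session baseline, then a
#' no-sonar control and two sonar sessions (10 min each, starts separated by
#' 70 min), with ship approach tracks planned by [plan_intercept()] (straight
#' course, 4.1 m/s, session start 1250 m from the predicted intercept) and
#' optional injected avoidance responses.
#'
#' For responding sessions the response onset is drawn uniformly in
#' [180, 300] s after session start, the post-turn heading is held on the
#' side of the ship course that maximises the turn magnitude at a relative
#' heading of 80-99 deg (compliant with the movement-away criterion), and
#' the avoidance speed is 1.3 m/s. Feeding flags control whether a lunge is
#' guaranteed (or removed) in the feeding-assignment window of each session.
#'
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @param design `"rampup_rampup"` (Control, RampUp1, RampUp2) or
#'   `"rampup_fullpower"` (Control, RampUp1, FullPower).
#' @param respond Logical length 2: inject an avoidance response in the two
#'   sonar sessions?
#' @param feeding Logical length 3: force (TRUE) or suppress (FALSE) lunges
#'   in each session's feeding window.
#' @param params [baseline_params()] for the whale's movement.
#' @param whale_id,group_id Identifiers carried into output tables.
#' @param baseline_duration_s Pre-control baseline length (default 4 h).
#' @return A list of class `cee_experiment`: `whale_id`, `group_id`,
#'   `design`, `seed`, `whale_track` (full record, injections applied),
#'   `lunge_times_s`, and `sessions`, a list with per-session
#'   `session_type`, `start_s`, `end_s`, `scheme`, `ship_track`,
#'   `ship_course_deg`, `plan`, `respond`, `onset_s`, `feeding`.
#' @export
make_experiment <- function(seed,
                            design = c("rampup_rampup", "rampup_fullpower"),
                            respond = c(FALSE, FALSE),
                            feeding = c(FALSE, FALSE, FALSE),
                            params = baseline_params(),
                            whale_id = "w01", group_id = "g01",
                            baseline_duration_s = 4 * 3600) {
  design <- match.arg(design)
  stopifnot(length(respond) == 2, length(feeding) == 3)
  set.seed(seed)
  types <- c("Control", "RampUp1",
             if (design == "rampup_rampup") "RampUp2" else "FullPower")
  session_gap_s <- 4200                    # start-to-start; >= 1 h apart
  starts <- (seq_along(types) - 1) * session_gap_s
  dur <- 600
  dt <- params$step_interval_s

  track <- generate_baseline_track(
    params, duration_s = baseline_duration_s + starts[3] + dur + 600,
    start_time_s = -baseline_duration_s
  )
  lunges <- attr(track, "lunge_times_s")

  sessions <- vector("list", length(types))
  for (k in seq_along(types)) {
    st <- starts[k]
    # plan the approach from whale fixes taken shortly before the session
    fix_times <- st - c(60, 40, 20)
    fixes <- interp_track(track, fix_times, "whale track")
    beta <- stats::runif(1, 0, 360)        # bearing from intercept to ship start
    v_est <- c((fixes$x_m[3] - fixes$x_m[1]) / 40,
               (fixes$y_m[3] - fixes$y_m[1]) / 40)
    predicted <- c(fixes$x_m[3], fixes$y_m[3]) + v_est * (20 + 1250 / 4.1)
    ship0 <- predicted + 1250 * c(sin(beta * pi / 180), cos(beta * pi / 180))
    plan <- plan_intercept(fixes, ship0)
    course <- plan$course_deg
    u <- c(sin(course * pi / 180), cos(course * pi / 180))
    ship_times <- seq(st, st + dur, by = dt)
    ship_track <- tibble(
      time_s = ship_times,
      x_m = ship0[1] + 4.1 * (ship_times - st) * u[1],
      y_m = ship0[2] + 4.1 * (ship_times - st) * u[2],
      depth_m = 50
    )
    scheme <- switch(types[k],
      Control = build_control_scheme(),
      RampUp1 = build_ramp_up_scheme(),
      RampUp2 = build_ramp_up_scheme(),
      FullPower = build_full_power_scheme()
    )
    onset_s <- NA_real_
    if (k > 1 && isTRUE(respond[k - 1])) {
      onset_s <- st + floor(stats::runif(1, 180, 300) / dt) * dt
      h_pre <- track$heading_deg[which(track$time_s >= onset_s)[1] - 1]
      rel <- stats::runif(1, 80, 99)
      cand <- wrap360(course + c(-1, 1) * rel)
      turn <- wrap180(cand - h_pre)
      turn <- turn[which.max(abs(turn))]
      track <- inject_avoidance(track, onset_s, turn, speed_mps = 1.3,
                                rule = "hold", until_s = st + dur)
    }
    # feeding control: guarantee or remove a lunge in the assignment window
    win <- c(st - 600, st + dur)
    if (isTRUE(feeding[k])) {
      if (!any(lunges >= win[1] & lunges <= win[2])) {
        lunges <- sort(c(lunges, st - 300))
      }
    } else {
      lunges <- lunges[lunges < win[1] | lunges > win[2]]
    }
    sessions[[k]] <- list(
      session_type = types[k], start_s = st, end_s = st + dur,
      scheme = scheme, ship_track = ship_track,
      ship_course_deg = course, plan = plan,
      respond = if (k > 1) isTRUE(respond[k - 1]) else FALSE,
      onset_s = onset_s, feeding = isTRUE(feeding[k])
    )
  }
  attr(track, "lunge_times_s") <- lunges
  structure(list(
    whale_id = whale_id, group_id = group_id, design = design, seed = seed,
    params = params, whale_track = track, lunge_times_s = lunges,
    sessions = sessions
  ), class = "cee_experiment")
}

#' @export
print.cee_experiment <- function(x, ...) {
  cat(sprintf(
    "<controlled exposure experiment: whale %s, group %s, design %s, seed %d>\n",
    x$whale_id, x$group_id, x$design, x$seed))
  for (s in x$sessions) {
    cat(sprintf("  %-9s [%6d, %6d] s  respond=%s feeding=%s\n",
                s$session_type, s$start_s, s$end_s, s$respond, s$feeding))
  }
  invisible(x)
}

# Truncated-normal sampler (lower bound only), by rejection; the truncation
# mass is small for all uses here.
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) {
    if (mean < lower) abort("degenerate truncated normal below its lower bound")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}
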