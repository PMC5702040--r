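#' Propagation-loss models
#'
#' Propagation loss (PL) is pluggable: any function of class `pl_model`
#' taking a vector of ranges (m) and an optional receiver depth (m) and
#' returning PL in dB may be supplied to [compute_exposure()].
#'
#' `pl_spherical()` builds the shipped default, spherical spreading with
#' optional linear absorption: `PL = 20 log10(r / 1 m) + alpha r / 1000`.
#' `pl_grid()` builds a model from an externally computed PL field given as
#' `range_m`, `depth_m`, `PL_dB` triples on a rectangular grid (e.g. exported
#' from a ray-trace run), interpolated bilinearly and clamped to the grid
#' edges.
#'
#' @param absorption_dB_per_km Linear absorption coefficient (default 0).
#' @return A function of class `pl_model`.
#' @examples
#' pl <- pl_spherical()
#' pl(1000) # 60 dB
#' @export
pl_spherical <- function(absorption_dB_per_km = 0) {
  f <- function(range_m, depth_m = NULL) {
    if (any(range_m <= 0)) abort("propagation loss requires range_m > 0")
    20 * log10(range_m) + absorption_dB_per_km * range_m / 1000
  }
  structure(f, class = c("pl_model", "function"), model = "spherical")
}

#' @rdname pl_spherical
#' @param grid A data frame with columns `range_m`, `depth_m`, `PL_dB`
#'   covering a full rectangular grid.
#' @export
pl_grid <- function(grid) {
  stopifnot(all(c("range_m", "depth_m", "PL_dB") %in% names(grid)))
  rs <- sort(unique(grid$range_m))
  ds <- sort(unique(grid$depth_m))
  m <- matrix(NA_real_, length(rs), length(ds))
  m[cbind(match(grid$range_m, rs), match(grid$depth_m, ds))] <- grid$PL_dB
  if (anyNA(m)) abort("PL grid must cover a full range x depth rectangle")
  f <- function(range_m, depth_m = NULL) {
    if (any(range_m <= 0)) abort("propagation loss requires range_m > 0")
    depth_m <- depth_m %||% rep(ds[1], length(range_m))
    r <- pmin(pmax(range_m, rs[1]), rs[length(rs)])
    d <- pmin(pmax(depth_m, ds[1]), ds[length(ds)])
    ri <- pmax(1, pmin(findInterval(r, rs), length(rs) - 1))
    di <- pmax(1, pmin(findInterval(d, ds), length(ds) - 1))
    fr <- (r - rs[ri]) / (rs[ri + 1] - rs[ri])
    fd <- (d - ds[di]) / (ds[di + 1] - ds[di])
    (1 - fr) * (1 - fd) * m[cbind(ri, di)] +
      fr * (1 - fd) * m[cbind(ri + 1, di)] +
      (1 - fr) * fd * m[cbind(ri, di + 1)] +
      fr * fd * m[cbind(ri + 1, di + 1)]
  }
  structure(f, class = c("pl_model", "function"), model = "grid")
}

#' @rdname pl_spherical
#' @param path CSV file with columns `range_m`, `depth_m`, `PL_dB`.
#' @export
read_pl_grid <- function(path) {
  pl_grid(readr::read_csv(path, show_col_types = FALSE))
}

#' Spherical-spreading propagation loss (plain function)
#'
#' Convenience scalar/vector form of the default PL model:
#' `20 log10(range_m) + absorption_dB_per_km * range_m / 1000`.
#'
#' @param range_m Range(s) in metres, > 0.
#' @param absorption_dB_per_km Linear absorption (default 0).
#' @return Propagation loss in dB.
#' @export
propagation_loss_spherical <- function(range_m, absorption_dB_per_km = 0) {
  pl_spherical(absorption_dB_per_km)(range_m)
}

#' Slant range between source and whale
#'
#' Three-dimensional Euclidean distance between two points given as
#' `(x_m, y_m, depth_m)`. Coincident points are rejected (a zero range is
#' unphysical for a received-level calculation).
#'
#' @param source,whale Numeric length-3 vectors or data frames with columns
#'   `x_m`, `y_m`, `depth_m` (vectorised row-wise).
#' @return Slant range(s) in metres.
#' @export
slant_range <- function(source, whale) {
  pick <- function(p) {
    if (is.data.frame(p)) cbind(p$x_m, p$y_m, p$depth_m)
    else matrix(p, ncol = 3)
  }
  s <- pick(source); w <- pick(whale)
  r <- sqrt(rowSums((s - w)^2))
  if (any(r == 0)) abort("source and whale positions coincide (zero slant range)")
  r
}

#' Per-pulse received levels and session risk indicators
#'
#' For every pulse of a transmission scheme, interpolates the ship (source)
#' and whale tracks to the pulse time, evaluates slant range and propagation
#' loss, and computes the received sound pressure level `SPL = SL - PL` and
#' single-pulse sound exposure level `SEL = SL_E - PL`. Session risk
#' indicators are:
#'
#' * `SPL_max_dB`: maximum SPL over pulses;
#' * `SEL_cum_dB`: `10 log10(sum(10^(SEL/10)))`, the cumulative sound
#'   exposure level;
#' * `R_min_m`: the minimum slant range over the whole session window,
#'   evaluated on the tracks interpolated to 1 s resolution (proximity is
#'   not tied to pulse times).
#'
#' For a control scheme (no pulses) the level indicators are `NA` but
#' `R_min_m` is still computed.
#'
#' @param scheme A transmission-scheme tibble (possibly empty).
#' @param ship_track,whale_track Track tibbles (`time_s`, `x_m`, `y_m`,
#'   `depth_m`). The ship track's `depth_m` is the source tow depth.
#' @param pl_model A `pl_model` function (default [pl_spherical()]).
#' @param session_start_s Absolute time of session start; pulse times in the
#'   scheme are relative to it (default 0).
#' @param session_window Length-2 window (absolute s) over which `R_min_m`
#'   is evaluated; defaults to the overlap of the two tracks.
#' @return A list of class `exposure_result` with elements `pulses` (tibble:
#'   `pulse`, `time_s`, `SL_dB`, `slant_range_m`, `PL_dB`, `SPL_dB`,
#'   `SEL_dB`, `E_uPa2s`) and `indicators` (one-row tibble: `SPL_max_dB`,
#'   `SEL_cum_dB`, `R_min_m`, `n_pulses`).
#' @export
compute_exposure <- function(scheme, ship_track, whale_track,
                             pl_model = pl_spherical(),
                             session_start_s = 0,
                             session_window = NULL) {
  assert_track(ship_track, "ship_track")
  assert_track(whale_track, "whale_track")
  window <- session_window %||% c(
    max(min(ship_track$time_s), min(whale_track$time_s)),
    min(max(ship_track$time_s), max(whale_track$time_s))
  )
  if (window[2] <= window[1]) abort("ship and whale tracks do not overlap in time")

  if (nrow(scheme) > 0) {
    t_abs <- session_start_s + scheme$time_s
    ship <- interp_track(ship_track, t_abs, "ship track")
    whale <- interp_track(whale_track, t_abs, "whale track")
    rng <- slant_range(ship, whale)
    pl <- pl_model(rng, whale$depth_m)
    spl <- scheme$SL_dB - pl
    sel <- energy_source_level(scheme$SL_dB, scheme$effective_duration_s) - pl
    pulses <- tibble(
      pulse = seq_len(nrow(scheme)),
      time_s = t_abs, SL_dB = scheme$SL_dB,
      slant_range_m = rng, PL_dB = pl,
      SPL_dB = spl, SEL_dB = sel, E_uPa2s = 10^(sel / 10)
    )
    spl_max <- max(spl)
    sel_cum <- db_sum(sel)
  } else {
    pulses <- tibble(
      pulse = integer(), time_s = numeric(), SL_dB = numeric(),
      slant_range_m = numeric(), PL_dB = numeric(),
      SPL_dB = numeric(), SEL_dB = numeric(), E_uPa2s = numeric()
    )
    spl_max <- NA_real_
    sel_cum <- NA_real_
  }

  fine <- seq(window[1], window[2], by = 1)
  r_min <- min(slant_range(interp_track(ship_track, fine, "ship track"),
                           interp_track(whale_track, fine, "whale track")))

  structure(list(
    pulses = pulses,
    indicators = tibble(SPL_max_dB = spl_max, SEL_cum_dB = sel_cum,
                        R_min_m = r_min, n_pulses = nrow(pulses))
  ), class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat("<exposure result>\n")
  print(x$indicators)
  invisible(x)
}

#' Modelled full-power outcome of a no-sonar control session
#'
#' Computes the risk indicators a whale would have received had the source
#' transmitted the full-power sequence during its no-sonar control approach:
#' the observed ship and whale tracks are kept (behaviour unchanged) and the
#' full-power scheme is imposed.
#'
#' @param session A session list with elements `ship_track`, `start_s`,
#'   `end_s` (as produced by [make_experiment()]); the whale track is taken
#'   from `whale_track` if the session carries one, else supply it.
#' @param whale_track Whale track tibble covering the session.
#' @param pl_model A `pl_model` function.
#' @return An `exposure_result` (see [compute_exposure()]).
#' @export
simulate_fullpower_outcome <- function(session, whale_track = NULL,
                                       pl_model = pl_spherical()) {
  whale_track <- whale_track %||% session$whale_track
  if (is.null(whale_track)) abort("a whale track is required")
  compute_exposure(build_full_power_scheme(), session$ship_track, whale_track,
                   pl_model = pl_model, session_start_s = session$start_s,
                   session_window = c(session$start_s, session$end_s))
}

#' Bias-correct modelled received levels against measurements
#'
#' Modelled received levels are corrected by the mean difference between
#' measured and modelled values over all paired sessions (or a fixed
#' offset), reflecting higher confidence in the tag measurements. Offsets
#' are maintained separately per indicator by the caller (the field
#' experiment found +5.8 dB for SPL_max and +2.2 dB for SEL_cum).
#'
#' @param modelled Numeric vector of modelled levels (dB).
#' @param measured Numeric vector of measured levels, paired with
#'   `modelled`; or `NULL` when `offset` is given.
#' @param offset A fixed additive offset (dB), used when `measured` is
#'   `NULL`.
#' @return Corrected levels, with attribute `offset_dB`.
#' @export
apply_bias_correction <- function(modelled, measured = NULL, offset = NULL) {
  if (is.null(measured) && is.null(offset)) {
    abort("supply either paired `measured` levels or a fixed `offset`")
  }
  if (!is.null(measured)) {
    if (length(measured) != length(modelled)) {
      abort("`measured` and `modelled` must be paired (equal length)")
    }
    offset <- mean(measured - modelled)
  }
  structure(modelled + offset, offset_dB = offset)
}

#' Ramp-up cumulative-exposure adjustment
#'
#' The ramp-up scheme transmits more total acoustic energy than the
#' full-power scheme (its ramp phase adds pulses); the fielded schedules
#' differed by 0.43 dB in total energy source level. So that ramp-up vs.
#' full-power contrasts in `SEL_cum` reflect behaviour rather than the
#' transmission protocols, 0.43 dB is subtracted from ramp-up session
#' `SEL_cum` values. The operation is idempotent per value (a flag attribute
#' guards against double application) and leaves non-ramp-up sessions
#' unchanged with a warning.
#'
#' @param SEL_cum_dB Cumulative sound exposure level(s), dB re. 1 uPa^2 s.
#' @param session_type Session type string(s): adjustment applies only to
#'   `"RampUp1"`/`"RampUp2"` (any string starting with "RampUp").
#' @param adjustment_dB The protocol energy difference (default 0.43 dB).
#' @return Adjusted value(s) with attribute `rampup_adjusted = TRUE`.
#' @export
adjust_rampup_selcum <- function(SEL_cum_dB, session_type = "RampUp1",
                                 adjustment_dB = 0.43) {
  if (isTRUE(attr(SEL_cum_dB, "rampup_adjusted"))) {
    warn("SEL_cum already ramp-up adjusted; returning unchanged")
    return(SEL_cum_dB)
  }
  is_ramp <- grepl("^RampUp", session_type)
  if (!all(is_ramp)) {
    warn("non-ramp-up session(s) passed to adjust_rampup_selcum(); left unchanged")
  }
  out <- SEL_cum_dB - ifelse(is_ramp, adjustment_dB, 0)
  attr(out, "rampup_adjusted") <- TRUE
  out
}

#' Propagate whale-position uncertainty into received levels
#'
#' Monte Carlo uncertainty propagation: each draw perturbs the whale track
#' with isotropic horizontal Gaussian noise (`horiz_sd_m`) and Gaussian
#' depth noise (`depth_sd_m`, default 1 m, the tag pressure-sensor
#' precision), recomputes the exposure, and records `SPL_max` and
#' `SEL_cum`.
#'
#' @inheritParams compute_exposure
#' @param horiz_sd_m S.d. of the horizontal position error (m), >= 0.
#' @param depth_sd_m S.d. of the depth error (m), >= 0 (default 1).
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Optional integer seed.
#' @return A list with `draws` (tibble: `draw`, `SPL_max_dB`, `SEL_cum_dB`)
#'   and `summary` (tibble: `metric`, `mean`, `sd`).
#' @export
propagate_position_uncertainty <- function(scheme, ship_track, whale_track,
                                           horiz_sd_m, depth_sd_m = 1,
                                           n_draws = 100, seed = NULL,
                                           pl_model = pl_spherical(),
                                           session_start_s = 0) {
  if (horiz_sd_m < 0 || depth_sd_m < 0) abort("position s.d. must be non-negative")
  if (n_draws < 1) abort("n_draws must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(whale_track)
  draws <- purrr::map_dfr(seq_len(n_draws), function(i) {
    pert <- whale_track
    pert$x_m <- pert$x_m + stats::rnorm(n, 0, horiz_sd_m)
    pert$y_m <- pert$y_m + stats::rnorm(n, 0, horiz_sd_m)
    pert$depth_m <- pmax(0, pert$depth_m + stats::rnorm(n, 0, depth_sd_m))
    ind <- compute_exposure(scheme, ship_track, pert, pl_model = pl_model,
                            session_start_s = session_start_s)$indicators
    tibble(draw = i, SPL_max_dB = ind$SPL_max_dB, SEL_cum_dB = ind$SEL_cum_dB)
  })
  summ <- draws |>
    tidyr::pivot_longer(-"draw", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  list(draws = draws, summary = summ)
}

#' @rdname compute_exposure
#' @param object An `exposure_result`.
#' @param ... Unused.
#' @method autoplot exposure_result
#' @export
autoplot.exposure_result <- function(object, ...) {
  if (nrow(object$pulses) == 0) {
    abort("nothing to plot: the scheme transmitted no pulses")
  }
  long <- object$pulses |>
    tidyr::pivot_longer(c("SPL_dB", "SEL_dB"), names_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$level)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$indicators$SPL_max_dB,
                        linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "Received level (dB)", colour = NULL,
                  subtitle = sprintf(
                    "SPL_max %.1f dB, SEL_cum %.1f dB, R_min %.0f m",
                    object$indicators$SPL_max_dB,
                    object$indicators$SEL_cum_dB,
                    object$indicators$R_min_m)) +
    ggplot2::theme_minimal()
}
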