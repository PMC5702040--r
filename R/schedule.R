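#' Sonar transmission schemes
#'
#' A transmission scheme is the ordered pulse schedule of one 10-min
#' experimental session. Three session protocols are supported:
#'
#' * **ramp-up**: source level rises from 152 to 214 dB re. 1 uPa m over the
#'   first 5 min (pulse duration 0.5 s, effective duration 0.47 s), then full
#'   power at 214 dB for the last 5 min (duration 1 s, effective 0.93 s);
#' * **full power**: silent for the first 5 min, then 214 dB pulses for the
#'   last 5 min;
#' * **control**: the ship approaches but nothing is transmitted.
#'
#' Pulses are emitted every 20 s on the grid t = 0, 20, ..., 580 s (half-open
#' 10-min window), giving 15 ramp-phase and 15 full-phase slots.
#'
#' A scheme is a tibble with one row per pulse and columns `time_s`, `SL_dB`
#' (source level re. 1 uPa m), `duration_s` (nominal) and
#' `effective_duration_s` (the energy-equivalent duration T used to convert
#' SL to energy source level), carrying attributes `scheme_name` and
#' `pulse_interval_s`.
#'
#' @param step_rule How ramp-phase source levels interpolate between 152 and
#'   214 dB: `"linear_db"` (default; linear in decibels across the 15 ramp
#'   pulses, final ramp pulse at 214 dB) or `"constant"` (all pulses at the
#'   full-power level, a degenerate schedule useful for sensitivity checks).
#' @param pulse_interval_s Seconds between pulses (default 20).
#' @param session_duration_s Total session length in seconds (default 600).
#' @param sl_start_dB,sl_full_dB Ramp start and full-power source levels
#'   (dB re. 1 uPa m; defaults 152 and 214).
#' @param ramp_effective_duration_s,full_effective_duration_s Effective pulse
#'   durations T in the ramp and full-power phases (defaults 0.47 and 0.93 s).
#' @return A transmission-scheme tibble (see Details).
#' @examples
#' build_ramp_up_scheme()
#' build_full_power_scheme()
#' @export
build_ramp_up_scheme <- function(step_rule = c("linear_db", "constant"),
                                 pulse_interval_s = 20,
                                 session_duration_s = 600,
                                 sl_start_dB = 152, sl_full_dB = 214,
                                 ramp_effective_duration_s = 0.47,
                                 full_effective_duration_s = 0.93) {
  step_rule <- match.arg(step_rule)
  half <- session_duration_s / 2
  t_ramp <- seq(0, half - pulse_interval_s, by = pulse_interval_s)
  t_full <- seq(half, session_duration_s - pulse_interval_s, by = pulse_interval_s)
  sl_ramp <- switch(step_rule,
    linear_db = seq(sl_start_dB, sl_full_dB, length.out = length(t_ramp)),
    constant  = rep(sl_full_dB, length(t_ramp))
  )
  pulses <- tibble(
    time_s = c(t_ramp, t_full),
    SL_dB = c(sl_ramp, rep(sl_full_dB, length(t_full))),
    duration_s = c(rep(0.5, length(t_ramp)), rep(1.0, length(t_full))),
    effective_duration_s = c(rep(ramp_effective_duration_s, length(t_ramp)),
                             rep(full_effective_duration_s, length(t_full)))
  )
  new_scheme(pulses, "ramp_up", pulse_interval_s)
}

#' @rdname build_ramp_up_scheme
#' @export
build_full_power_scheme <- function(pulse_interval_s = 20,
                                    session_duration_s = 600,
                                    sl_full_dB = 214,
                                    full_effective_duration_s = 0.93) {
  half <- session_duration_s / 2
  t_full <- seq(half, session_duration_s - pulse_interval_s, by = pulse_interval_s)
  pulses <- tibble(
    time_s = t_full,
    SL_dB = sl_full_dB,
    duration_s = 1.0,
    effective_duration_s = full_effective_duration_s
  )
  new_scheme(pulses, "full_power", pulse_interval_s)
}

#' @rdname build_ramp_up_scheme
#' @export
build_control_scheme <- function(pulse_interval_s = 20) {
  pulses <- tibble(
    time_s = numeric(), SL_dB = numeric(),
    duration_s = numeric(), effective_duration_s = numeric()
  )
  new_scheme(pulses, "control", pulse_interval_s)
}

new_scheme <- function(pulses, name, pulse_interval_s) {
  validate_scheme_pulses(pulses, name)
  structure(pulses,
            class = c("sonar_scheme", class(pulses)),
            scheme_name = name,
            pulse_interval_s = pulse_interval_s)
}

validate_scheme_pulses <- function(pulses, name) {
  if (nrow(pulses) == 0) return(invisible(pulses))
  with(pulses, {
    stopifnot(all(is.finite(SL_dB)),
              all(effective_duration_s > 0),
              all(effective_duration_s <= duration_s),
              all(time_s >= 0))
  })
  if (is.unsorted(pulses$time_s, strictly = TRUE)) {
    abort(sprintf("pulse times in scheme '%s' must be strictly increasing", name))
  }
  invisible(pulses)
}

#' @export
print.sonar_scheme <- function(x, ...) {
  cat(sprintf("<sonar transmission scheme: %s, %d pulses, %g s interval>\n",
              scheme_name(x), nrow(x), attr(x, "pulse_interval_s")))
  NextMethod()
}

#' @rdname build_ramp_up_scheme
#' @param scheme A transmission-scheme tibble.
#' @export
scheme_name <- function(scheme) attr(scheme, "scheme_name") %||% "custom"

#' Energy source level of a pulse
#'
#' Converts a source level based on mean-square sound pressure (SL, dB re.
#' 1 uPa m) to an energy source level (SL_E, dB re. 1 uPa^2 m^2 s) using the
#' effective pulse duration `T_s`: `SL_E = SL + 10 log10(T / t0)` with
#' reference duration t0 = 1 s.
#'
#' @param SL_dB Source level (dB re. 1 uPa m). Vectorised.
#' @param T_s Effective pulse duration in seconds; must be positive.
#' @return Energy source level (dB re. 1 uPa^2 m^2 s).
#' @examples
#' energy_source_level(214, 0.93)
#' @export
energy_source_level <- function(SL_dB, T_s) {
  if (any(!is.finite(T_s)) || any(T_s <= 0)) {
    abort("effective pulse duration `T_s` must be positive and finite")
  }
  SL_dB + 10 * log10(T_s)
}

#' Total energy source level of a scheme
#'
#' Energy-sums the per-pulse energy source levels of a transmission scheme:
#' `10 log10(sum_i 10^(SL_E,i / 10))`. This is the quantity whose ramp-up
#' vs. full-power difference motivates the fixed cumulative-exposure
#' adjustment applied by [adjust_rampup_selcum()].
#'
#' @param scheme A transmission-scheme tibble with at least one pulse.
#' @return Total SL_E (dB re. 1 uPa^2 m^2 s).
#' @examples
#' total_energy_source_level(build_full_power_scheme())
#' @export
total_energy_source_level <- function(scheme) {
  if (nrow(scheme) == 0) {
    abort("cannot compute total energy source level of a scheme with no pulses")
  }
  db_sum(energy_source_level(scheme$SL_dB, scheme$effective_duration_s))
}

#' Read and write transmission schemes
#'
#' Schemes serialise to YAML or JSON as a named record with the scheme name,
#' pulse interval and a list of pulses `{time_s, SL_dB, duration_s,
#' effective_duration_s}`. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param scheme A transmission-scheme tibble.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()` returns
#'   the scheme tibble.
#' @export
write_scheme <- function(scheme, path) {
  rec <- list(
    scheme_name = scheme_name(scheme),
    pulse_interval_s = attr(scheme, "pulse_interval_s"),
    pulses = purrr::transpose(as.list(as_tibble(scheme)))
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("scheme path must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    abort("scheme path must end in .yaml, .yml or .json")
  }
  pulses <- purrr::map_dfr(rec$pulses, as_tibble)
  if (nrow(pulses) == 0) {
    pulses <- tibble(time_s = numeric(), SL_dB = numeric(),
                     duration_s = numeric(), effective_duration_s = numeric())
  }
  new_scheme(pulses, rec$scheme_name, rec$pulse_interval_s)
}
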