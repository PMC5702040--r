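#' Track and table I/O
#'
#' Tracks are exchanged as headered UTF-8 CSV with a `.` decimal separator
#' and columns `time_s`, `x_m`, `y_m`, `depth_m` (plus any extra columns,
#' which are preserved).
#'
#' @param track A track tibble.
#' @param path File path.
#' @return `write_track_csv()` returns `path` invisibly; `read_track_csv()`
#'   the track tibble.
#' @export
write_track_csv <- function(track, path) {
  assert_track(track)
  readr::write_csv(track, path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  assert_track(readr::read_csv(path, show_col_types = FALSE))
}

pipeline_stamp <- function(seed, config = NULL) {
  list(seed = seed, config_hash = rlang::hash(list(seed = seed, config = config)))
}

#' Generate a synthetic experiment on disk
#'
#' Writes a complete synthetic controlled exposure experiment to `dir`:
#' whale and per-session ship tracks as CSV, transmission schemes as YAML,
#' and a session manifest (`manifest.yaml`) recording session windows, ship
#' courses, lunge times, identifiers, the seed and a config hash. Output is
#' byte-identical for identical seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @inheritParams make_experiment
#' @return The manifest, invisibly.
#' @export
pipeline_generate <- function(dir, seed,
                              design = c("rampup_rampup", "rampup_fullpower"),
                              respond = c(FALSE, FALSE),
                              feeding = c(FALSE, FALSE, FALSE),
                              params = baseline_params(),
                              whale_id = "w01", group_id = "g01") {
  design <- match.arg(design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exp <- make_experiment(seed, design, respond, feeding, params,
                         whale_id, group_id)
  write_track_csv(exp$whale_track, file.path(dir, "whale_track.csv"))
  sess <- purrr::imap(exp$sessions, function(s, k) {
    ship_file <- sprintf("ship_track_%d_%s.csv", k, s$session_type)
    scheme_file <- sprintf("scheme_%d_%s.yaml", k, s$session_type)
    write_track_csv(s$ship_track, file.path(dir, ship_file))
    write_scheme(s$scheme, file.path(dir, scheme_file))
    list(session_type = s$session_type, start_s = s$start_s, end_s = s$end_s,
         ship_track = ship_file, scheme = scheme_file,
         ship_course_deg = s$ship_course_deg,
         respond = s$respond, feeding = s$feeding)
  })
  manifest <- c(
    list(whale_id = whale_id, group_id = group_id, design = design,
         whale_track = "whale_track.csv",
         lunge_times_s = as.numeric(exp$lunge_times_s),
         sessions = sess),
    pipeline_stamp(seed, list(design = design, respond = respond,
                              feeding = feeding))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

read_manifest <- function(dir) yaml::read_yaml(file.path(dir, "manifest.yaml"))

#' Compute risk indicators for every session of a generated experiment
#'
#' Reads an experiment directory written by [pipeline_generate()], runs
#' [compute_exposure()] for every session — imposing the full-power scheme
#' on the no-sonar control to obtain its modelled full-power outcome — and
#' writes `indicators.csv`. A control session contributes two rows: its own
#' (level indicators absent, proximity present) and the modelled full-power
#' outcome obtained by imposing the full-power scheme on the observed
#' control tracks (`session_type = "FullPower"`, `modelled = TRUE`).
#'
#' @param dir Experiment directory.
#' @param pl_model A `pl_model` function (default [pl_spherical()]).
#' @param out File to write (default `indicators.csv` inside `dir`).
#' @return The indicator tibble, one row per whale x session.
#' @export
pipeline_expose <- function(dir, pl_model = pl_spherical(),
                            out = file.path(dir, "indicators.csv")) {
  man <- read_manifest(dir)
  whale <- read_track_csv(file.path(dir, man$whale_track))
  rows <- purrr::map_dfr(man$sessions, function(s) {
    ship_path <- file.path(dir, s$ship_track)
    if (!file.exists(ship_path)) {
      abort(sprintf("missing ship track for session %s: %s",
                    s$session_type, ship_path))
    }
    ship <- read_track_csv(ship_path)
    scheme <- read_scheme(file.path(dir, s$scheme))
    res <- compute_exposure(scheme, ship, whale, pl_model = pl_model,
                            session_start_s = s$start_s,
                            session_window = c(s$start_s, s$end_s))
    out <- dplyr::bind_cols(
      tibble(whale_id = man$whale_id, group_id = man$group_id,
             session_type = s$session_type, modelled = FALSE,
             session_start_s = s$start_s),
      res$indicators
    )
    if (s$session_type == "Control") {
      # modelled full-power outcome: full-power scheme imposed on the
      # observed control tracks, behaviour unchanged
      fp <- simulate_fullpower_outcome(
        list(ship_track = ship, start_s = s$start_s, end_s = s$end_s),
        whale_track = whale, pl_model = pl_model)
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble(whale_id = man$whale_id, group_id = man$group_id,
               session_type = "FullPower", modelled = TRUE,
               session_start_s = s$start_s),
        fp$indicators
      ))
    }
    out
  })
  rows$seed <- man$seed
  rows$config_hash <- man$config_hash
  readr::write_csv(rows, out)
  rows
}

#' Detect avoidance responses for a generated experiment
#'
#' Reconstructs the experiment from `dir` and runs [detect_experiment()],
#' writing the calls table as TSV.
#'
#' @param dir Experiment directory.
#' @param alpha Family-wise significance level (default 0.05).
#' @param out File to write (default `calls.tsv` inside `dir`).
#' @param ... Passed to [detect_experiment()].
#' @return The calls tibble.
#' @export
pipeline_detect <- function(dir, alpha = 0.05,
                            out = file.path(dir, "calls.tsv"), ...) {
  man <- read_manifest(dir)
  whale <- read_track_csv(file.path(dir, man$whale_track))
  sessions <- purrr::map(man$sessions, function(s) {
    list(session_type = s$session_type, start_s = s$start_s, end_s = s$end_s,
         ship_course_deg = s$ship_course_deg)
  })
  exp <- structure(list(
    whale_id = man$whale_id, group_id = man$group_id,
    whale_track = whale, lunge_times_s = unlist(man$lunge_times_s) %||% numeric(),
    sessions = sessions
  ), class = "cee_experiment")
  calls <- detect_experiment(exp, alpha = alpha, ...)
  calls$seed <- man$seed
  readr::write_tsv(calls, out)
  calls
}

#' Risk-indicator statistics for a set of experiments
#'
#' Given pooled indicator and avoidance-call tables (one row per whale x
#' session), fits the session factor model for each risk indicator
#' (Gaussian for the level indicators, gamma for minimum range), computes
#' Wald tests for the ramp-up vs. full-power differences, bootstrap
#' contrasts, Barnard's test of avoidance presence in sonar vs. control
#' sessions, and the hearing-risk classification of the highest SEL_cum.
#'
#' @param indicators Indicator table (columns `whale_id`, `group_id`,
#'   `session_type`, `SPL_max_dB`, `SEL_cum_dB`, `R_min_m`).
#' @param calls Calls table from [pipeline_detect()]/[detect_experiment()],
#'   or `NULL` to skip avoidance-related analyses.
#' @param n_boot Bootstrap draws for contrasts (default 5000).
#' @param seed Integer seed for the bootstrap.
#' @param out Optional path of a JSON report to write.
#' @return A list: `models` (tidy coefficients per indicator), `contrasts`
#'   (RampUp1 - FullPower per indicator), `barnard`, `hearing`, `seed`.
#' @export
pipeline_stats <- function(indicators, calls = NULL, n_boot = 5000,
                           seed = 1, out = NULL) {
  indicators <- as_tibble(indicators)
  # the factor models use sonar sessions (incl. modelled full-power
  # outcomes); control rows carry no level indicators
  model_rows <- indicators |>
    filter(.data$session_type != "Control", !is.na(.data$SPL_max_dB))
  responses <- c(SPL_max_dB = "gaussian", SEL_cum_dB = "gaussian",
                 R_min_m = "gamma")
  models <- list(); contrasts <- list()
  for (resp in names(responses)) {
    f <- stats::as.formula(paste(resp, "~ session_type"))
    fit <- fit_factor_model(model_rows, f, family = responses[[resp]])
    models[[resp]] <- tidy(fit)
    if (all(c("RampUp1", "FullPower") %in% model_rows$session_type)) {
      contrasts[[resp]] <- bootstrap_contrast(
        fit, list(session_type = "RampUp1"), list(session_type = "FullPower"),
        n_boot = n_boot, seed = seed
      ) |> mutate(indicator = resp, .before = 1)
    }
  }
  barnard <- NULL
  if (!is.null(calls)) {
    per_session <- calls |>
      group_by(.data$whale_id, .data$session_type, .data$session_start_s) |>
      summarise(avoided = any(.data$is_avoidance, na.rm = TRUE), .groups = "drop")
    sonar <- per_session |> filter(.data$session_type != "Control")
    control <- per_session |> filter(.data$session_type == "Control")
    if (nrow(sonar) > 0 && nrow(control) > 0) {
      barnard <- barnard_test(sum(sonar$avoided), nrow(sonar),
                              sum(control$avoided), nrow(control))
    }
  }
  hearing <- hearing_risk(max(indicators$SEL_cum_dB, na.rm = TRUE))
  report <- list(
    models = models,
    contrasts = if (length(contrasts)) dplyr::bind_rows(contrasts) else NULL,
    barnard = barnard, hearing = hearing, seed = seed,
    config_hash = rlang::hash(list(seed = seed, n_boot = n_boot))
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}

#' Read a per-session risk-indicator table
#'
#' Loads an indicator table CSV with (at least) columns `whale_id`,
#' `group_id`, `session_type`, `avoided`, `feeding`, `SPL_max_dB`,
#' `SEL_cum_dB`, `R_min_m` — the minimal schema of a field study's
#' per-session supplementary record — for use with [fit_factor_model()]
#' and [pipeline_stats()].
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_indicator_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf(
      paste("indicator table not found: %s.",
            "Supply a CSV with columns whale_id, group_id, session_type,",
            "avoided, feeding, SPL_max_dB, SEL_cum_dB, R_min_m"), path))
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("whale_id", "group_id", "session_type",
            "SPL_max_dB", "SEL_cum_dB", "R_min_m")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("indicator table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tab
}
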