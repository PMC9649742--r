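validate_columns <- function(data, required, what) {
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

#' Read and write bead-track tables
#'
#' CSV schema: `bead_id, frame, time_s, y_px, x_px, y_um, x_um, area_px`.
#' Numbers are written at full precision with "." as the decimal separator
#' regardless of locale.
#'
#' @param tracks A track table (see [track_beads()]).
#' @param path File path.
#' @return `read_tracks_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  validate_columns(tracks, c("bead_id", "frame", "time_s", "y_px", "x_px",
                             "y_um", "x_um", "area_px"), "track table")
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, locale = readr::locale())
  validate_columns(out, c("bead_id", "frame", "time_s", "y_px", "x_px",
                          "y_um", "x_um", "area_px"), path)
  out
}

#' Read and write rupture tables
#'
#' CSV schema: `bead_id, channel_index, width_um, loading_rate_pn_s,
#' rupture_flow_rate_mm3_s, censored` (a `rupture_force_pn` column is kept
#' when present, e.g. in simulator truth tables).
#'
#' @param ruptures A rupture table (see [simulate_rupture_experiment()]).
#' @param path File path.
#' @return `read_ruptures_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_ruptures_csv <- function(ruptures, path) {
  validate_columns(ruptures, c("bead_id", "channel_index",
                               "loading_rate_pn_s",
                               "rupture_flow_rate_mm3_s", "censored"),
                   "rupture table")
  readr::write_csv(ruptures, path)
  invisible(path)
}

#' @rdname write_ruptures_csv
#' @export
read_ruptures_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_columns(out, c("bead_id", "channel_index", "loading_rate_pn_s",
                          "rupture_flow_rate_mm3_s", "censored"), path)
  out
}

#' Read and write survival tables
#'
#' CSV schema: `bead_id, removal_time_s, censored`; the observation horizon
#' and applied force ride along as extra columns so the round trip preserves
#' them.
#'
#' @param record A survival record (see [simulate_survival()]).
#' @param path File path.
#' @return `read_survival_csv()` returns a tibble with the
#'   `observation_time_s` / `applied_force_pn` attributes restored; the
#'   writer returns `path` invisibly.
#' @export
write_survival_csv <- function(record, path) {
  validate_columns(record, c("bead_id", "removal_time_s", "censored"),
                   "survival record")
  out <- tibble::as_tibble(record)
  out$observation_time_s <- attr(record, "observation_time_s") %||% NA_real_
  out$applied_force_pn <- attr(record, "applied_force_pn") %||% NA_real_
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_columns(out, c("bead_id", "removal_time_s", "censored"), path)
  if ("observation_time_s" %in% names(out)) {
    attr(out, "observation_time_s") <- out$observation_time_s[1]
    out$observation_time_s <- NULL
  }
  if ("applied_force_pn" %in% names(out)) {
    attr(out, "applied_force_pn") <- out$applied_force_pn[1]
    out$applied_force_pn <- NULL
  }
  out
}

#' Read a scenario configuration from YAML
#'
#' A scenario file declares, with explicit unit-suffixed keys, everything a
#' pipeline run needs: the chip geometry, the loading protocol, the
#' environment, the calibration slope (or instruction to fit one), the
#' generating energy landscape for simulations, and the seeds. See
#' [run_pipeline()] for the recognized keys.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_scenario(cfg)
}

#' Validate a scenario configuration list
#'
#' @param cfg A configuration list (see [run_pipeline()]).
#' @return `cfg`, invisibly, after validation; errors name the offending key.
#' @export
validate_scenario <- function(cfg) {
  if (!is.list(cfg)) stop("scenario config must be a list / YAML mapping",
                          call. = FALSE)
  need <- function(key, sub = NULL) {
    where <- if (is.null(sub)) cfg else cfg[[sub]]
    if (is.null(where[[key]])) {
      stop(sprintf("scenario config is missing key `%s`",
                   if (is.null(sub)) key else paste(sub, key, sep = ".")),
           call. = FALSE)
    }
    where[[key]]
  }
  need("widths_um", "chip"); need("height_um", "chip")
  need("ramp_mm3_s2", "protocol"); need("duration_s", "protocol")
  need("slope_pn_s_mm", "calibration")
  need("k_off", "landscape"); need("delta_x", "landscape")
  need("seed")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("scenario config key `seed` must be an integer", call. = FALSE)
  }
  invisible(cfg)
}

#' Write a results bundle as JSON
#'
#' Numbers are written unrounded; scalars are unboxed.
#'
#' @param results A (nested) list of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
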