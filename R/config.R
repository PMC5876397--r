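# Experiment configuration: a single JSON file with [geometry], [schedule],
# [dose] and [lod] tables, plus optional [calibration] (linear
# fluorescence-to-concentration slopes) and [schedule_overrides]
# (per-compound schedules). Unknown keys are rejected so silent typos
# cannot change an analysis.

CONFIG_KEYS <- c("geometry", "schedule", "dose", "lod", "calibration",
                 "schedule_overrides")
GEOMETRY_KEYS <- c("membrane_area_cm2", "apical_volume_ml",
                   "basolateral_volume_ml", "pore_size_um")
SCHEDULE_KEYS <- c("times_h", "sample_volume_ml")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Build an experiment configuration
#'
#' @param geometry An [insert_geometry()].
#' @param schedule Default [sampling_schedule()].
#' @param dose Named list/vector: compound -> dosing concentration C0
#'   (mg ml^-1).
#' @param lod Named list/vector: compound -> limit of detection
#'   (mg ml^-1). Compounds absent from the table get no LOD flagging.
#' @param calibration Named list/vector: compound -> linear calibration
#'   slope converting instrument readings (e.g. fluorescence units) to
#'   mg ml^-1. Only needed for readings whose unit is not `mg_per_ml`.
#' @param schedule_overrides Named list: compound -> [sampling_schedule()]
#'   replacing the default schedule.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = insert_geometry(),
                              schedule = sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 0.05),
                              dose = list(), lod = list(),
                              calibration = list(),
                              schedule_overrides = list()) {
  structure(list(geometry = geometry, schedule = schedule,
                 dose = as.list(dose), lod = as.list(lod),
                 calibration = as.list(calibration),
                 schedule_overrides = schedule_overrides),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON
#'
#' See [experiment_config()] for the documented tables. Unknown keys at
#' the top level or inside `geometry`/`schedule` raise an error.
#'
#' @param path Path to a JSON configuration file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, CONFIG_KEYS, "config")
  if (is.null(raw$geometry) || is.null(raw$schedule)) {
    stop("config must contain 'geometry' and 'schedule' tables", call. = FALSE)
  }
  check_keys(raw$geometry, GEOMETRY_KEYS, "config$geometry")
  check_keys(raw$schedule, SCHEDULE_KEYS, "config$schedule")
  geometry <- do.call(insert_geometry, raw$geometry)
  schedule <- sampling_schedule(raw$schedule$times_h, raw$schedule$sample_volume_ml)
  overrides <- list()
  for (cmp in names(raw$schedule_overrides)) {
    ov <- raw$schedule_overrides[[cmp]]
    check_keys(ov, SCHEDULE_KEYS, sprintf("config$schedule_overrides$%s", cmp))
    overrides[[cmp]] <- sampling_schedule(ov$times_h, ov$sample_volume_ml)
  }
  experiment_config(geometry, schedule,
                    dose = raw$dose %||% list(),
                    lod = raw$lod %||% list(),
                    calibration = raw$calibration %||% list(),
                    schedule_overrides = overrides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment configuration to JSON
#'
#' @param config An [experiment_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  out <- list(
    geometry = config$geometry[GEOMETRY_KEYS],
    schedule = list(times_h = config$schedule$times_h,
                    sample_volume_ml = config$schedule$sample_volume_ml),
    dose = config$dose,
    lod = config$lod
  )
  if (length(config$calibration)) out$calibration <- config$calibration
  if (length(config$schedule_overrides)) {
    out$schedule_overrides <- lapply(config$schedule_overrides, function(s) {
      list(times_h = s$times_h, sample_volume_ml = s$sample_volume_ml)
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Configuration implied by a synthetic study design (dogfooding: the
# simulator's fixtures are read back through the same config the analysis
# uses).
config_from_design <- function(design) {
  cmp <- design$compounds
  overrides <- list()
  for (i in seq_len(nrow(cmp))) {
    if (cmp$schedule[i] != "fluorescence") {
      overrides[[cmp$compound[i]]] <- study_schedule(cmp$schedule[i])
    }
  }
  experiment_config(
    geometry = design$geometry,
    schedule = study_schedule("fluorescence"),
    dose = stats::setNames(as.list(cmp$c0_mg_ml), cmp$compound),
    lod = stats::setNames(as.list(cmp$lod_mg_ml), cmp$compound),
    schedule_overrides = overrides
  )
}
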