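# Domain types shared by all stages: insert geometry, sampling schedule,
# dose, translocation series, TEER records and particle specifications.
# Constructors validate by default; validate_series() re-checks a series and
# returns findings instead of raising, so malformed inputs can be reported
# row-by-row from file readers.

CONDITION_LEVELS <- c("control", "bewo", "hpec", "coculture")
REGIME_LEVELS <- c("static", "shaken")

#' Transwell insert geometry
#'
#' Physical frame for all mass-balance computations: membrane area and the
#' two chamber volumes. The default profile is a 12-well polycarbonate
#' insert with 3 um pores, 1.12 cm^2 growth area, 0.5 ml apical and 1.5 ml
#' basolateral volume -- the standard format for placental BeWo/HPEC
#' translocation studies.
#'
#' @param membrane_area_cm2 Membrane growth area (cm^2).
#' @param apical_volume_ml Apical (donor) chamber volume (ml).
#' @param basolateral_volume_ml Basolateral (receiver) chamber volume (ml).
#' @param pore_size_um Membrane pore size (um); informational only.
#' @return An object of class `insert_geometry`.
#' @export
#' @examples
#' insert_geometry() # the default 12-well insert profile
insert_geometry <- function(membrane_area_cm2 = 1.12,
                            apical_volume_ml = 0.5,
                            basolateral_volume_ml = 1.5,
                            pore_size_um = 3.0) {
  fields <- c(membrane_area_cm2 = membrane_area_cm2,
              apical_volume_ml = apical_volume_ml,
              basolateral_volume_ml = basolateral_volume_ml,
              pore_size_um = pore_size_um)
  if (!all(is.finite(fields)) || any(fields <= 0)) {
    stop("all insert_geometry fields must be finite and > 0", call. = FALSE)
  }
  structure(as.list(fields), class = "insert_geometry")
}

#' @export
print.insert_geometry <- function(x, ...) {
  cat(sprintf(
    "<insert_geometry> area %.3g cm^2, apical %.3g ml, basolateral %.3g ml, pores %.3g um\n",
    x$membrane_area_cm2, x$apical_volume_ml, x$basolateral_volume_ml, x$pore_size_um))
  invisible(x)
}

#' Basolateral sampling schedule
#'
#' Timepoints (hours) at which a fixed volume is withdrawn from the
#' basolateral chamber and replaced with fresh medium. Two schedules are
#' typical: fluorescence reads at 0, 0.25, 2, 4, 6, 8, 24 h with 50 ul
#' draws, and HPLC reads at 0, 0.25, 1, 2, 6 h with 200 ul draws.
#'
#' @param times_h Strictly increasing timepoints (h); first must be >= 0.
#' @param sample_volume_ml Volume withdrawn and replaced at each timepoint
#'   (ml). Use [ul_to_ml()] for microlitre protocols.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `sampling_schedule`.
#' @export
#' @examples
#' sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), ul_to_ml(50))
sampling_schedule <- function(times_h, sample_volume_ml, validate = TRUE) {
  times_h <- as.numeric(times_h)
  sample_volume_ml <- as.numeric(sample_volume_ml)
  x <- structure(list(times_h = times_h, sample_volume_ml = sample_volume_ml),
                 class = "sampling_schedule")
  if (validate) {
    msg <- schedule_findings(x)
    if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  x
}

schedule_findings <- function(schedule, geometry = NULL) {
  out <- character()
  t <- schedule$times_h
  if (!length(t) || anyNA(t)) out <- c(out, "schedule times missing or NA")
  else {
    if (t[1] < 0) out <- c(out, "first schedule time is negative")
    if (length(t) > 1 && any(diff(t) <= 0)) out <- c(out, "times not strictly increasing")
  }
  vs <- schedule$sample_volume_ml
  if (!length(vs) || is.na(vs) || vs <= 0) out <- c(out, "sample volume must be > 0")
  else if (!is.null(geometry) && vs >= geometry$basolateral_volume_ml) {
    out <- c(out, "sample volume exceeds chamber")
  }
  out
}

#' Apical dose specification
#'
#' @param initial_concentration_mg_ml Apical dosing concentration C0
#'   (mg ml^-1 = mg cm^-3).
#' @param compound Compound label.
#' @param geometry Insert geometry used to derive the initial dose
#'   ID = C0 x apical volume.
#' @return An object of class `dose_spec` with fields
#'   `initial_concentration_mg_ml`, `initial_dose_mg`, `compound`.
#' @export
#' @examples
#' dose_spec(0.5, "ps_49nm") # 0.5 mg/ml in 0.5 ml apical -> ID = 0.25 mg
dose_spec <- function(initial_concentration_mg_ml, compound = "analyte",
                      geometry = insert_geometry()) {
  c0 <- as.numeric(initial_concentration_mg_ml)
  if (!is.finite(c0) || c0 <= 0) {
    stop("initial_concentration_mg_ml must be finite and > 0", call. = FALSE)
  }
  structure(list(
    initial_concentration_mg_ml = c0,
    initial_dose_mg = c0 * geometry$apical_volume_ml,
    compound = as.character(compound)
  ), class = "dose_spec")
}

#' One insert's translocation time series
#'
#' Basolateral concentration readings aligned to a sampling schedule, with
#' the geometry, dose and condition metadata needed for all downstream
#' kinetics. Readings below the limit of detection are stored as 0 and
#' flagged in `below_lod`.
#'
#' @param geometry An [insert_geometry()].
#' @param schedule A [sampling_schedule()].
#' @param dose A [dose_spec()].
#' @param concentrations_mg_ml Basolateral concentrations C_n (mg ml^-1),
#'   one per schedule timepoint, recorded before the withdrawn volume is
#'   replaced.
#' @param condition Barrier condition: one of `"control"` (blank membrane),
#'   `"bewo"`, `"hpec"`, `"coculture"`.
#' @param regime Exposure regime: `"static"` or `"shaken"`.
#' @param replicate_id Replicate label.
#' @param lod_mg_ml Limit of detection (mg ml^-1) for this compound, or
#'   `NA` to skip LOD flagging.
#' @param validate Raise on invariant violations (default `TRUE`); with
#'   `FALSE` the object is built as-is so [validate_series()] can report
#'   findings.
#' @return An object of class `translocation_series`.
#' @export
translocation_series <- function(geometry, schedule, dose, concentrations_mg_ml,
                                 condition = "control", regime = "static",
                                 replicate_id = "r1", lod_mg_ml = NA_real_,
                                 validate = TRUE) {
  conc <- as.numeric(concentrations_mg_ml)
  below_lod <- rep(FALSE, length(conc))
  if (!is.na(lod_mg_ml)) {
    below_lod <- !is.na(conc) & conc < lod_mg_ml
    conc[below_lod] <- 0
  }
  x <- structure(list(
    geometry = geometry,
    schedule = schedule,
    dose = dose,
    concentrations_mg_ml = conc,
    below_lod = below_lod,
    condition = as.character(condition),
    regime = as.character(regime),
    replicate_id = as.character(replicate_id),
    lod_mg_ml = as.numeric(lod_mg_ml)
  ), class = "translocation_series")
  if (validate) {
    msg <- validate_series(x)
    if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  x
}

#' Validate a translocation series
#'
#' Checks every structural invariant of a [translocation_series()] and
#' returns findings as a character vector rather than raising, so callers
#' (e.g. file readers) can aggregate and report them. An empty vector means
#' the series is well formed.
#'
#' @param series A `translocation_series` (possibly built with
#'   `validate = FALSE`).
#' @return Character vector of findings; `character(0)` if valid.
#' @export
#' @examples
#' s <- translocation_series(insert_geometry(),
#'   sampling_schedule(c(0, 2, 4), 0.05),
#'   dose_spec(0.01), c(0, 1e-4, 2e-4))
#' validate_series(s) # character(0)
validate_series <- function(series) {
  out <- character()
  out <- c(out, schedule_findings(series$schedule, series$geometry))
  n_t <- length(series$schedule$times_h)
  n_c <- length(series$concentrations_mg_ml)
  if (n_t != n_c) {
    out <- c(out, sprintf("concentrations length (%d) != times length (%d)", n_c, n_t))
  }
  bad <- !is.na(series$concentrations_mg_ml) &
    series$concentrations_mg_ml < 0 & !series$below_lod
  if (any(bad)) out <- c(out, "negative concentration not flagged below-LOD")
  if (!series$condition %in% CONDITION_LEVELS) {
    out <- c(out, sprintf("unknown condition '%s'", series$condition))
  }
  if (!series$regime %in% REGIME_LEVELS) {
    out <- c(out, sprintf("unknown regime '%s'", series$regime))
  }
  rel <- abs(series$dose$initial_dose_mg -
               series$dose$initial_concentration_mg_ml * series$geometry$apical_volume_ml)
  if (rel > 1e-9 * series$dose$initial_dose_mg) {
    out <- c(out, "initial dose inconsistent with C0 x apical volume")
  }
  out
}

#' @export
print.translocation_series <- function(x, ...) {
  cat(sprintf("<translocation_series> %s / %s / %s (%s): %d timepoints, C0 = %.3g mg/ml\n",
              x$dose$compound, x$condition, x$regime, x$replicate_id,
              length(x$schedule$times_h), x$dose$initial_concentration_mg_ml))
  invisible(x)
}

#' TEER measurement record
#'
#' @param total_resistance_ohm Resistance of the insert with cells (Ohm).
#' @param blank_resistance_ohm Intrinsic resistance of the blank
#'   (collagen-coated, cell-free) insert (Ohm).
#' @param membrane_area_cm2 Membrane area (cm^2).
#' @return An object of class `teer_record`.
#' @export
teer_record <- function(total_resistance_ohm, blank_resistance_ohm,
                        membrane_area_cm2 = 1.12) {
  v <- c(total_resistance_ohm, blank_resistance_ohm, membrane_area_cm2)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all teer_record fields must be finite and > 0", call. = FALSE)
  }
  structure(list(total_resistance_ohm = total_resistance_ohm,
                 blank_resistance_ohm = blank_resistance_ohm,
                 membrane_area_cm2 = membrane_area_cm2),
            class = "teer_record")
}

#' Nanoparticle specification
#'
#' Nominal (manufacturer) diameter, material density and dosing mass
#' concentration of a monodisperse spherical particle suspension. Nominal
#' diameter, not hydrodynamic diameter, is used for dosimetry.
#'
#' @param diameter_nm Nominal particle diameter (nm).
#' @param density_g_cm3 Material density (g cm^-3); polystyrene is 1.05.
#' @param mass_concentration_mg_ml Dosing mass concentration (mg ml^-1).
#' @param label Particle label.
#' @return An object of class `particle_spec`.
#' @export
#' @examples
#' particle_spec(49, 1.05, 0.5)
particle_spec <- function(diameter_nm, density_g_cm3 = 1.05,
                          mass_concentration_mg_ml, label = "particle") {
  v <- c(diameter_nm, density_g_cm3, mass_concentration_mg_ml)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("all particle_spec fields must be finite and > 0", call. = FALSE)
  }
  structure(list(diameter_nm = diameter_nm,
                 density_g_cm3 = density_g_cm3,
                 mass_concentration_mg_ml = mass_concentration_mg_ml,
                 label = as.character(label)),
            class = "particle_spec")
}

#' Cell seeding density
#'
#' Cells applied per unit membrane area.
#'
#' @param cells Number of cells seeded.
#' @param membrane_area_cm2 Membrane growth area (cm^2).
#' @return Seeding density (cells cm^-2).
#' @export
#' @examples
#' seeding_density(1.5e5, 1.12) # ~1.34e5 cells/cm^2
seeding_density <- function(cells, membrane_area_cm2 = 1.12) {
  stopifnot(is.numeric(cells), cells > 0, membrane_area_cm2 > 0)
  cells / membrane_area_cm2
}
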