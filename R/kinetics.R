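# Translocation kinetics: sampling-corrected cumulative transported mass,
# percent of initial dose, permeability coefficients, membrane-corrected
# apparent permeability, TEER normalisation and the series-resistance
# additivity diagnostic.

#' Cumulative transported mass, corrected for withdrawn samples
#'
#' Under a sample-and-replace schedule the mass transported to the
#' basolateral chamber by timepoint n is
#' \deqn{\Delta Q_n = C_n V_w + \sum_{j=1}^{n-1} V_s C_j}
#' where \eqn{C_n} is the basolateral concentration recorded (pre-
#' replacement) at \eqn{t_n}, \eqn{V_w} the basolateral (well) volume and
#' \eqn{V_s} the sample volume. The sum restores the mass removed in
#' earlier draws. This reconstruction is exact for a well-mixed receiver
#' chamber regardless of the transport kinetics.
#'
#' If the schedule contains t = 0 the reading there is treated as a
#' pre-dose blank: it is subtracted from all readings (floored at zero)
#' before the correction is applied.
#'
#' @param series A [translocation_series()].
#' @param blank_correct Subtract the t = 0 reading as a blank
#'   (default `TRUE`; a no-op when the t = 0 reading is zero or absent).
#' @return Numeric vector of cumulative transported mass (mg), one entry
#'   per schedule timepoint.
#' @export
#' @examples
#' s <- translocation_series(insert_geometry(),
#'   sampling_schedule(c(1, 2), 0.05), dose_spec(0.01),
#'   c(0.001, 0.002))
#' cumulative_mass(s) # 0.0015, 0.00305
cumulative_mass <- function(series, blank_correct = TRUE) {
  conc <- series$concentrations_mg_ml
  times <- series$schedule$times_h
  if (length(conc) != length(times)) {
    stop("concentrations and schedule times differ in length", call. = FALSE)
  }
  if (blank_correct && length(times) && times[1] == 0) {
    conc <- pmax(conc - conc[1], 0)
  }
  v_w <- series$geometry$basolateral_volume_ml
  v_s <- series$schedule$sample_volume_ml
  n <- length(conc)
  if (!n) return(numeric(0))
  prior <- c(0, cumsum(conc))[seq_len(n)] # sum of C_j for j < n
  conc * v_w + v_s * prior
}

#' Percent of the initial dose transported
#'
#' Expresses cumulative transported mass as a percentage of the initial
#' apical dose ID = C0 x apical volume. Values can legitimately exceed the
#' static equilibrium fraction (see [equilibrium_fraction()]) because each
#' withdrawal keeps the apical-to-basolateral gradient alive; values above
#' it are flagged via the `"exceeds_equilibrium"` attribute, never clipped.
#'
#' @param x A [translocation_series()], or a numeric vector of cumulative
#'   masses (mg) if `dose` is supplied.
#' @param dose A [dose_spec()]; required when `x` is numeric.
#' @param ... Passed to [cumulative_mass()] when `x` is a series.
#' @return Numeric vector of percent-of-ID values with a logical
#'   `exceeds_equilibrium` attribute (per timepoint) when `x` is a series.
#' @export
percent_of_initial_dose <- function(x, dose = NULL, ...) {
  if (inherits(x, "translocation_series")) {
    dq <- cumulative_mass(x, ...)
    dose <- x$dose
    eq <- equilibrium_fraction(x$geometry)
  } else {
    dq <- as.numeric(x)
    eq <- NA_real_
  }
  if (is.null(dose) || !inherits(dose, "dose_spec")) {
    stop("a dose_spec is required", call. = FALSE)
  }
  id <- dose$initial_dose_mg
  if (!is.finite(id) || id <= 0) stop("initial dose must be > 0", call. = FALSE)
  pct <- 100 * dq / id
  if (is.finite(eq)) attr(pct, "exceeds_equilibrium") <- pct > 100 * eq + 1e-9
  pct
}

#' Static equilibrium fraction of the initial dose
#'
#' With no sampling, passive transport equilibrates the two chambers at a
#' common concentration, leaving the fraction
#' \eqn{V_b / (V_a + V_b)} of the initial dose in the basolateral chamber
#' (75\% for the default 0.5 ml / 1.5 ml insert).
#'
#' @param geometry An [insert_geometry()].
#' @return Fraction in (0, 1).
#' @export
#' @examples
#' equilibrium_fraction(insert_geometry()) # 0.75
equilibrium_fraction <- function(geometry = insert_geometry()) {
  v_a <- geometry$apical_volume_ml
  v_b <- geometry$basolateral_volume_ml
  v_b / (v_a + v_b)
}

#' Permeability coefficient from a translocation series
#'
#' The permeability across the whole barrier (membrane plus any cell
#' layers) is the secant-from-origin estimate
#' \deqn{P = \frac{\Delta Q / \Delta t}{A \, C_0}}
#' with \eqn{\Delta Q} the cumulative transported mass at the named
#' timepoint, \eqn{\Delta t} the elapsed seconds since dosing, A the
#' membrane area and \eqn{C_0} the initial apical concentration (treated
#' as constant; apical depletion biases the estimate upward-shrinking over
#' time, which is why early timepoints are preferred).
#'
#' @param series A [translocation_series()].
#' @param at_time_h Timepoint (h) at which to evaluate; must be a schedule
#'   timepoint and > 0.
#' @param ... Passed to [cumulative_mass()].
#' @return Permeability (cm s^-1).
#' @export
permeability <- function(series, at_time_h, ...) {
  times <- series$schedule$times_h
  if (at_time_h <= 0) stop("at_time_h must be > 0", call. = FALSE)
  i <- match_time(at_time_h, times)
  dq <- cumulative_mass(series, ...)[i]
  dt_s <- hours_to_seconds(times[i])
  a <- series$geometry$membrane_area_cm2
  c0 <- series$dose$initial_concentration_mg_ml
  (dq / dt_s) / (a * c0)
}

match_time <- function(at_time_h, times_h, tol = 1e-9) {
  i <- which(abs(times_h - at_time_h) <= tol * max(1, abs(at_time_h)))
  if (length(i) != 1) {
    stop(sprintf("timepoint %g h not in schedule (%s)", at_time_h,
                 paste(times_h, collapse = ", ")), call. = FALSE)
  }
  i
}

#' Membrane-corrected apparent permeability
#'
#' Treats the blank membrane and the cell layer(s) as resistances in
#' series: \deqn{P_e = \frac{1}{1/P_c - 1/P_m}} where \eqn{P_c} is the
#' permeability across membrane plus cells and \eqn{P_m} across the blank
#' membrane. At the pole \eqn{P_c \ge P_m} (possible with measurement
#' noise) the cell-layer permeability is not identifiable and `NA` is
#' returned rather than an unphysical negative value. \eqn{P_c = 0} maps
#' to \eqn{P_e = 0}.
#'
#' @param p_c Permeability across membrane plus cells (cm s^-1), >= 0.
#' @param p_m Permeability across the blank membrane (cm s^-1), > 0.
#' @return Apparent permeability of the cell layer(s) (cm s^-1), or
#'   `NA_real_` when not computable.
#' @export
#' @examples
#' apparent_permeability(10e-6, 30e-6) # 15e-6
apparent_permeability <- function(p_c, p_m) {
  if (length(p_c) != 1 || length(p_m) != 1) {
    return(mapply(apparent_permeability, p_c, p_m))
  }
  if (is.na(p_c) || is.na(p_m)) return(NA_real_)
  if (p_c < 0 || p_m <= 0) stop("need p_c >= 0 and p_m > 0", call. = FALSE)
  if (p_c == 0) return(0)
  if (p_c >= p_m) return(NA_real_) # pole: cell resistance not identifiable
  1 / (1 / p_c - 1 / p_m)
}

#' Combine layer permeabilities in series
#'
#' Layers stacked in the transport path behave as resistances in series:
#' \deqn{1/P_{combined} = \sum_i 1/P_i.}
#'
#' @param layer_permeabilities Numeric vector of layer permeabilities
#'   (cm s^-1), all > 0.
#' @return Combined permeability (cm s^-1).
#' @export
#' @examples
#' series_composition(c(10e-6, 10e-6)) # 5e-6
series_composition <- function(layer_permeabilities) {
  p <- as.numeric(layer_permeabilities)
  if (!length(p) || anyNA(p) || any(p <= 0)) {
    stop("all layer permeabilities must be > 0", call. = FALSE)
  }
  1 / sum(1 / p)
}

#' Additivity diagnostic for stacked barriers
#'
#' Ratio of the observed co-culture resistance to the resistance predicted
#' by stacking the individual layers in series:
#' \deqn{\frac{1/P_{e,co}}{\sum_i 1/P_{e,i}}.}
#' A value of 1 means the layers are perfectly additive; 0.5 means the
#' co-culture is no tighter than one of two identical layers.
#'
#' @param pe_coculture Observed co-culture apparent permeability (cm s^-1).
#' @param pe_layers Numeric vector of single-layer apparent permeabilities.
#' @return Dimensionless resistance ratio.
#' @export
additivity_deviation <- function(pe_coculture, pe_layers) {
  if (is.na(pe_coculture) || pe_coculture <= 0) {
    stop("pe_coculture must be > 0", call. = FALSE)
  }
  (1 / pe_coculture) / (1 / series_composition(pe_layers))
}

#' Blank-subtracted, area-corrected TEER
#'
#' Subtracts the intrinsic resistance of the blank insert membrane from
#' the total resistance (membrane with cells) and multiplies by the
#' membrane area. Negative results (blank exceeding total, possible with
#' measurement error) are returned as-is with a warning, never clamped.
#'
#' @param record A [teer_record()].
#' @return Area-corrected cell-layer resistance (Ohm cm^2).
#' @export
#' @examples
#' teer_normalized(teer_record(445, 100, 1.12)) # 386.4
teer_normalized <- function(record) {
  out <- (record$total_resistance_ohm - record$blank_resistance_ohm) *
    record$membrane_area_cm2
  if (out < 0) {
    warning("blank resistance exceeds total resistance; returning negative TEER",
            call. = FALSE)
  }
  out
}

#' Sodium-fluorescein exclusion endpoint
#'
#' Barrier-integrity endpoint: percent of the initial Na-F dose found
#' basolaterally after a 3 h incubation. In the usual single-draw assay
#' (schedule = 3 h only) the withdrawn-mass correction degenerates to
#' \eqn{\Delta Q = C V_w}.
#'
#' @param series A [translocation_series()] whose schedule contains a 3 h
#'   timepoint.
#' @return Percent of initial dose at 3 h.
#' @export
naf_exclusion_endpoint <- function(series) {
  i <- match_time(3, series$schedule$times_h)
  percent_of_initial_dose(series)[i]
}

#' Full per-insert kinetic analysis
#'
#' Computes the cumulative-mass series, percent-of-ID series, the
#' permeability at every positive timepoint, and (when a blank-membrane
#' permeability is supplied) the membrane-corrected apparent permeability
#' at a reference timepoint.
#'
#' @param series A [translocation_series()].
#' @param p_m Blank-membrane permeability (cm s^-1) for the same compound,
#'   or `NULL` to skip the membrane correction.
#' @param pe_time_h Reference timepoint (h) for the apparent permeability
#'   (default 2 h).
#' @return An object of class `permeability_result`: a list with `time_h`,
#'   `concentration_mg_ml`, `below_lod`, `cumulative_mass_mg`,
#'   `percent_id`, `p_cm_s` (NA at t = 0), `pe_cm_s`, `pe_time_h` and a
#'   character vector `flags` (subset of `"below_lod"`, `"pe_undefined"`,
#'   `"exceeds_equilibrium"`).
#' @export
permeability_result <- function(series, p_m = NULL, pe_time_h = 2) {
  msg <- validate_series(series)
  if (length(msg)) stop(paste(msg, collapse = "; "), call. = FALSE)
  times <- series$schedule$times_h
  dq <- cumulative_mass(series)
  pct <- percent_of_initial_dose(series)
  p <- rep(NA_real_, length(times))
  pos <- which(times > 0)
  for (i in pos) p[i] <- permeability(series, times[i])
  flags <- character()
  if (any(series$below_lod)) flags <- c(flags, "below_lod")
  if (any(attr(pct, "exceeds_equilibrium"), na.rm = TRUE)) {
    flags <- c(flags, "exceeds_equilibrium")
  }
  pe <- NA_real_
  if (!is.null(p_m)) {
    p_c <- p[match_time(pe_time_h, times)]
    pe <- apparent_permeability(p_c, p_m)
    if (is.na(pe) && p_c > 0) flags <- c(flags, "pe_undefined")
  }
  structure(list(
    time_h = times,
    concentration_mg_ml = series$concentrations_mg_ml,
    below_lod = series$below_lod,
    cumulative_mass_mg = dq,
    percent_id = as.numeric(pct),
    p_cm_s = p,
    pe_cm_s = pe,
    pe_time_h = pe_time_h,
    flags = flags,
    series = series
  ), class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> %s / %s / %s\n", x$series$dose$compound,
              x$series$condition, x$series$regime))
  df <- data.frame(time_h = x$time_h, percent_id = signif(x$percent_id, 4),
                   p_cm_s = signif(x$p_cm_s, 4))
  print(df, row.names = FALSE)
  if (!is.na(x$pe_cm_s)) {
    cat(sprintf("Pe(%g h) = %.4g cm/s\n", x$pe_time_h, x$pe_cm_s))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
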