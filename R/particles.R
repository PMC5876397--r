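# Nanoparticle dosimetry: mass-to-number concentration conversion under the
# spherical monodisperse assumption, and applied-dose bookkeeping.

#' Particle number concentration from mass concentration
#'
#' For monodisperse spheres of nominal diameter d and material density rho,
#' \deqn{N = \frac{C_{mass}}{\rho \, (\pi/6) d^3}.}
#' Units are reconciled internally (nm -> cm, g -> mg); the result is
#' particles per ml.
#'
#' @param spec A [particle_spec()].
#' @return Number concentration (particles ml^-1).
#' @export
#' @examples
#' number_concentration(particle_spec(49, 1.05, 0.5))   # ~7.73e12
#' number_concentration(particle_spec(70, 1.05, 0.05))  # ~2.65e11
number_concentration <- function(spec) {
  d_cm <- spec$diameter_nm * 1e-7
  mass_per_particle_mg <- spec$density_g_cm3 * 1000 * (pi / 6) * d_cm^3
  spec$mass_concentration_mg_ml / mass_per_particle_mg
}

#' Applied particle dose for an insert
#'
#' @param spec A [particle_spec()].
#' @param geometry An [insert_geometry()]; the apical volume receives the
#'   dose.
#' @return An object of class `particle_dose` with `number_concentration`
#'   (particles ml^-1) and `total_particles_applied`.
#' @export
particle_dose <- function(spec, geometry = insert_geometry()) {
  n <- number_concentration(spec)
  structure(list(spec = spec,
                 number_concentration = n,
                 total_particles_applied = n * geometry$apical_volume_ml),
            class = "particle_dose")
}

#' @export
print.particle_dose <- function(x, ...) {
  cat(sprintf("<particle_dose> %s: %.3g particles/ml, %.3g particles applied\n",
              x$spec$label, x$number_concentration, x$total_particles_applied))
  invisible(x)
}

#' Translocated particle number from a percent-of-dose value
#'
#' @param percent_id Percent of the initial dose transported (>= 0).
#' @param dose A [particle_dose()].
#' @return Number of particles transported.
#' @export
#' @examples
#' d <- particle_dose(particle_spec(49, 1.05, 0.5))
#' percent_id_to_particle_flux(2, d) # 2% of the applied particles
percent_id_to_particle_flux <- function(percent_id, dose) {
  if (any(!is.finite(percent_id)) || any(percent_id < 0)) {
    stop("percent_id must be finite and >= 0", call. = FALSE)
  }
  percent_id / 100 * dose$total_particles_applied
}

#' Particle dose table
#'
#' Dose metrics for a set of particle specifications, rounded to 3
#' significant figures for reporting.
#'
#' @param specs List of [particle_spec()] objects.
#' @param geometry An [insert_geometry()].
#' @return data.frame with one row per particle: label, diameter, density,
#'   mass concentration, number concentration and total particles applied.
#' @export
particle_dose_table <- function(specs, geometry = insert_geometry()) {
  rows <- lapply(specs, function(s) {
    d <- particle_dose(s, geometry)
    data.frame(label = s$label,
               diameter_nm = s$diameter_nm,
               density_g_cm3 = s$density_g_cm3,
               mass_concentration_mg_ml = s$mass_concentration_mg_ml,
               number_concentration_per_ml = signif(d$number_concentration, 3),
               total_particles_applied = signif(d$total_particles_applied, 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
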