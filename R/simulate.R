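# Two-compartment barrier-transport simulator. Between sampling events the
# well-mixed donor/receiver pair follows first-order exchange with an exact
# closed form; at each scheduled event the basolateral concentration is
# recorded (optionally with multiplicative noise), a fixed volume is
# withdrawn and replaced with fresh (analyte-free) medium. Ground truth is
# kept noiseless so every estimator can be checked against it.

#' Layered barrier model
#'
#' A barrier is a stack of layers in the transport path (blank membrane
#' plus zero or more cell layers); its effective permeability is the
#' series (harmonic) composition of the layers, so it can never exceed the
#' leakiest layer.
#'
#' @param layer_permeabilities Named numeric vector of layer
#'   permeabilities (cm s^-1), e.g. `c(membrane = 30e-6, bewo = 2e-6)`.
#' @return An object of class `barrier_model` with
#'   `effective_permeability`.
#' @export
#' @examples
#' barrier_model(c(membrane = 30e-6, bewo = 2e-6, hpec = 9e-6))
barrier_model <- function(layer_permeabilities) {
  p <- layer_permeabilities
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    names(p) <- paste0("layer", seq_along(p))
  }
  eff <- series_composition(p)
  structure(list(layer_permeabilities = p, effective_permeability = eff),
            class = "barrier_model")
}

#' @export
print.barrier_model <- function(x, ...) {
  cat("<barrier_model>", paste(sprintf("%s=%.3g", names(x$layer_permeabilities),
                                       x$layer_permeabilities), collapse = " + "),
      sprintf("-> Peff=%.3g cm/s\n", x$effective_permeability))
  invisible(x)
}

#' Simulation configuration for one insert design
#'
#' @param geometry An [insert_geometry()].
#' @param schedule A [sampling_schedule()].
#' @param dose A [dose_spec()].
#' @param barrier A [barrier_model()].
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise applied to recorded concentrations (>= 0; truth is
#'   kept noiseless). Noisy readings are truncated at zero; truncations
#'   are counted in the simulation truth.
#' @param n_replicates Number of replicate inserts (>= 1).
#' @param rng_seed Integer seed; replicate streams are split
#'   deterministically by replicate index.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = insert_geometry(),
                       schedule = sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 0.05),
                       dose = dose_spec(0.01),
                       barrier = barrier_model(c(membrane = 30e-6)),
                       noise_cv = 0, n_replicates = 1, rng_seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  # rebind the dose to this geometry so ID = C0 x apical volume holds
  dose <- dose_spec(dose$initial_concentration_mg_ml, dose$compound, geometry)
  structure(list(geometry = geometry, schedule = schedule, dose = dose,
                 barrier = barrier, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Closed-form basolateral mass between sampling events
#'
#' For two well-mixed compartments exchanging across a barrier with
#' permeability P and area A (flux \eqn{J = P A (C_a - C_b)}), the
#' basolateral mass relaxes exponentially towards the equilibrium split:
#' \deqn{M_b(t) = M_{eq} + (M_b(0) - M_{eq}) e^{-P A (1/V_a + 1/V_b) t}}
#' with \eqn{M_{eq} = (M_a(0) + M_b(0)) V_b / (V_a + V_b)}. Exact between
#' events; P = 0 gives a constant.
#'
#' @param t_s Elapsed time (s), >= 0.
#' @param p Barrier permeability (cm s^-1), >= 0.
#' @param geometry An [insert_geometry()].
#' @param m_apical0_mg Apical mass at the start of the interval (mg).
#' @param m_baso0_mg Basolateral mass at the start of the interval (mg).
#' @return Basolateral mass at time t (mg).
#' @export
closed_form_basolateral_mass <- function(t_s, p, geometry,
                                         m_apical0_mg, m_baso0_mg = 0) {
  stopifnot(t_s >= 0, p >= 0)
  v_a <- geometry$apical_volume_ml
  v_b <- geometry$basolateral_volume_ml
  a <- geometry$membrane_area_cm2
  m_eq <- (m_apical0_mg + m_baso0_mg) * v_b / (v_a + v_b)
  k <- p * a * (1 / v_a + 1 / v_b)
  m_eq + (m_baso0_mg - m_eq) * exp(-k * t_s)
}

#' Simulate one insert through a sampling schedule
#'
#' Advances the closed-form two-compartment dynamics between scheduled
#' events. At each event, in order: the basolateral concentration is read
#' (truth = M_b / V_b; the recorded value gets multiplicative Gaussian
#' noise with CV `noise_cv`, truncated at 0), the sample volume is
#' withdrawn (removing V_s x C of true mass) and replaced with fresh
#' analyte-free medium. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (splits the RNG stream and labels the
#'   series).
#' @param condition,regime Labels attached to the emitted series.
#' @param lod_mg_ml Limit of detection applied to the recorded (noisy)
#'   concentrations; `NA` disables flagging.
#' @return A list with `series` (a [translocation_series()]) and `truth`
#'   (class `sim_truth`): data.frame with per-event apical mass,
#'   basolateral mass pre-sampling, withdrawn mass, cumulative net
#'   transported mass, plus attributes `initial_dose_mg` and
#'   `n_truncated`.
#' @export
simulate_insert <- function(config, replicate = 1L, condition = "control",
                            regime = "static", lod_mg_ml = NA_real_) {
  geom <- config$geometry
  sched <- config$schedule
  times <- sched$times_h
  v_b <- geom$basolateral_volume_ml
  v_s <- sched$sample_volume_ml
  p_eff <- config$barrier$effective_permeability

  set.seed((config$rng_seed + 7919L * as.integer(replicate)) %% .Machine$integer.max)

  m_a <- config$dose$initial_dose_mg
  m_b <- 0
  t_prev <- 0
  n <- length(times)
  c_true <- c_obs <- withdrawn <- apical <- baso_pre <- net <- numeric(n)
  cum_withdrawn <- 0
  n_trunc <- 0L

  for (i in seq_len(n)) {
    dt_s <- hours_to_seconds(times[i] - t_prev)
    m_b_new <- closed_form_basolateral_mass(dt_s, p_eff, geom, m_a, m_b)
    m_a <- m_a - (m_b_new - m_b)
    m_b <- m_b_new
    t_prev <- times[i]

    c_true[i] <- m_b / v_b
    obs <- c_true[i]
    if (config$noise_cv > 0) {
      obs <- obs * (1 + config$noise_cv * stats::rnorm(1))
      if (obs < 0) {
        obs <- 0
        n_trunc <- n_trunc + 1L
      }
    }
    c_obs[i] <- obs
    apical[i] <- m_a
    baso_pre[i] <- m_b
    net[i] <- m_b + cum_withdrawn

    withdrawn[i] <- v_s * c_true[i]
    m_b <- m_b - withdrawn[i]
    cum_withdrawn <- cum_withdrawn + withdrawn[i]
  }

  series <- translocation_series(
    geometry = geom, schedule = sched, dose = config$dose,
    concentrations_mg_ml = c_obs, condition = condition, regime = regime,
    replicate_id = paste0("r", replicate), lod_mg_ml = lod_mg_ml)

  truth <- structure(data.frame(
    time_h = times,
    apical_mass_mg = apical,
    baso_mass_pre_sample_mg = baso_pre,
    withdrawn_mass_mg = withdrawn,
    net_transported_mass_mg = net,
    concentration_true_mg_ml = c_true
  ), class = c("sim_truth", "data.frame"))
  attr(truth, "initial_dose_mg") <- config$dose$initial_dose_mg
  attr(truth, "n_truncated") <- n_trunc

  list(series = series, truth = truth)
}

# Named sampling schedules used in the default study design.
study_schedule <- function(kind = c("fluorescence", "hplc")) {
  kind <- match.arg(kind)
  if (kind == "fluorescence") {
    sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), ul_to_ml(50))
  } else {
    sampling_schedule(c(0, 0.25, 1, 2, 6), ul_to_ml(200))
  }
}

condition_layers <- function(condition) {
  switch(condition,
         control = "membrane",
         bewo = c("membrane", "bewo"),
         hpec = c("membrane", "hpec"),
         coculture = c("membrane", "bewo", "hpec"),
         stop(sprintf("unknown condition label '%s'", condition), call. = FALSE))
}

#' Default synthetic study design
#'
#' A complete study design emulating a placental-barrier translocation
#' experiment: 6 compounds (two transcellular markers read by HPLC on a
#' 0/0.25/1/2/6 h schedule with 200 ul draws; two paracellular markers and
#' two polystyrene nanoparticle sizes read by fluorescence on a
#' 0/0.25/2/4/6/8/24 h schedule with 50 ul draws) crossed with 4 barrier
#' conditions (blank membrane, BeWo, HPEC, co-culture) and 2 regimes
#' (static and shaken, sharing identical kinetics), 4 replicates each.
#' Per-compound membrane permeabilities and per-layer apparent
#' permeabilities (1e-6 cm s^-1) are chosen so that fast transcellular
#' compounds approach the equilibrium fraction within hours, paracellular
#' markers are retained by the trophoblast layer, the 49 nm particles
#' translocate at the percent level and the 40 kDa dextran and 70 nm
#' particles stay below the detection limit across cell layers.
#'
#' @param n_replicates Replicates per condition x regime (default 4).
#' @param noise_cv Measurement CV (default 0.1).
#' @param seed Base RNG seed.
#' @param regimes Regimes to generate.
#' @return A list of class `study_design` with a `compounds` data.frame
#'   (columns compound, c0_mg_ml, schedule, p_membrane, pe_bewo, pe_hpec,
#'   lod_mg_ml; permeabilities in cm s^-1) and the design scalars.
#' @export
default_study_design <- function(n_replicates = 4, noise_cv = 0.1,
                                 seed = 20180329 %% 2147483647,
                                 regimes = c("static", "shaken")) {
  compounds <- data.frame(
    compound = c("antipyrine", "indomethacin", "naf", "fitc_dextran",
                 "ps_49nm", "ps_70nm"),
    c0_mg_ml = c(0.0188, 0.0358, 0.00188, 0.2, 0.5, 0.05),
    schedule = c("hplc", "hplc", "fluorescence", "fluorescence",
                 "fluorescence", "fluorescence"),
    p_membrane = c(60, 40, 30, 15, 3, 1) * 1e-6,
    pe_bewo = c(112.1, 39.5, 2.0, 0.005, 0.15, 0.002) * 1e-6,
    pe_hpec = c(83.6, 19.0, 9.0, 0.5, 0.2, 0.002) * 1e-6,
    stringsAsFactors = FALSE
  )
  compounds$lod_mg_ml <- 1e-3 * compounds$c0_mg_ml
  structure(list(compounds = compounds,
                 conditions = CONDITION_LEVELS,
                 regimes = match.arg(regimes, REGIME_LEVELS, several.ok = TRUE),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv,
                 seed = as.integer(seed),
                 geometry = insert_geometry()),
            class = "study_design")
}

#' Generate a complete synthetic study
#'
#' Simulates every (compound x condition x regime x replicate) insert of a
#' study design. Static and shaken arms share identical transport
#' parameters (an empirically supported null for simple horizontal
#' shaking), so any downstream static-vs-shaken significance is a false
#' positive by construction. Deterministic given the design seed.
#'
#' @param design A [default_study_design()] (possibly modified).
#' @return An object of class `synthetic_study`: list with `series` (list
#'   of [translocation_series()]), `truth` (parallel list of `sim_truth`),
#'   and `design`.
#' @export
generate_study <- function(design = default_study_design()) {
  series <- list()
  truth <- list()
  idx <- 0L
  for (ci in seq_len(nrow(design$compounds))) {
    row <- design$compounds[ci, ]
    sched <- study_schedule(row$schedule)
    dose <- dose_spec(row$c0_mg_ml, row$compound, design$geometry)
    for (cond in design$conditions) {
      layers <- condition_layers(cond)
      p <- c(membrane = row$p_membrane, bewo = row$pe_bewo, hpec = row$pe_hpec)
      barrier <- barrier_model(p[layers])
      for (reg in design$regimes) {
        for (r in seq_len(design$n_replicates)) {
          idx <- idx + 1L
          cfg <- sim_config(design$geometry, sched, dose, barrier,
                            noise_cv = design$noise_cv,
                            rng_seed = (design$seed + 1009L * idx) %% 2147483647)
          sim <- simulate_insert(cfg, replicate = r, condition = cond,
                                 regime = reg, lod_mg_ml = row$lod_mg_ml)
          key <- paste(row$compound, cond, reg, r, sep = "|")
          series[[key]] <- sim$series
          truth[[key]] <- sim$truth
        }
      }
    }
  }
  structure(list(series = series, truth = truth, design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d series (%d compounds x %d conditions x %d regimes x %d replicates)\n",
              length(x$series), nrow(x$design$compounds),
              length(x$design$conditions), length(x$design$regimes),
              x$design$n_replicates))
  invisible(x)
}
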