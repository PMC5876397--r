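# Shared fixture builders: everything is generated in code, no stored data.

default_geom <- function() insert_geometry()

fluor_schedule <- function() sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 0.05)

make_series <- function(conc, times = seq_along(conc), vs = 0.05,
                        c0 = 0.01, ...) {
  translocation_series(default_geom(), sampling_schedule(times, vs),
                       dose_spec(c0), conc, ...)
}

# Random but valid simulation configuration for property-style tests.
random_sim_config <- function() {
  geom <- insert_geometry(
    membrane_area_cm2 = stats::runif(1, 0.3, 5),
    apical_volume_ml = stats::runif(1, 0.2, 2),
    basolateral_volume_ml = stats::runif(1, 0.5, 4))
  n_t <- sample(3:8, 1)
  times <- sort(stats::runif(n_t, 0.1, 24))
  vs <- stats::runif(1, 0.01, 0.3 * geom$basolateral_volume_ml)
  sim_config(
    geometry = geom,
    schedule = sampling_schedule(c(0, times), vs),
    dose = dose_spec(10^stats::runif(1, -4, 0)),
    barrier = barrier_model(c(membrane = 10^stats::runif(1, -7, -4))),
    noise_cv = 0)
}
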