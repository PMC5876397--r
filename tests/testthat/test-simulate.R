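test_that("closed-form basolateral mass has the right limits", {
  geom <- default_geom()
  expect_equal(closed_form_basolateral_mass(0, 3e-5, geom, 0.005, 0.001), 0.001)
  expect_equal(closed_form_basolateral_mass(1e4, 0, geom, 0.005, 0.001), 0.001)
  # long-time limit: the basolateral chamber holds its volume share (75%)
  m_inf <- closed_form_basolateral_mass(1e9, 3e-5, geom, 0.005, 0)
  expect_equal(m_inf, 0.75 * 0.005, tolerance = 1e-12)
})

test_that("mass is conserved at every event for random configurations", {
  set.seed(101)
  for (i in 1:40) {
    cfg <- random_sim_config()
    sim <- simulate_insert(cfg)
    tr <- sim$truth
    id <- attr(tr, "initial_dose_mg")
    cum_withdrawn_prev <- c(0, cumsum(tr$withdrawn_mass_mg))[seq_len(nrow(tr))]
    total <- tr$apical_mass_mg + tr$baso_mass_pre_sample_mg + cum_withdrawn_prev
    expect_equal(total, rep(id, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("cumulative-mass reconstruction matches simulator truth exactly (noiseless)", {
  set.seed(202)
  for (i in 1:100) {
    cfg <- random_sim_config()
    sim <- simulate_insert(cfg)
    dq <- cumulative_mass(sim$series)
    truth <- sim$truth$net_transported_mass_mg
    rel <- abs(dq - truth) / pmax(abs(truth), 1e-300)
    expect_lt(max(rel[truth > 0]), 1e-9)
    expect_equal(dq[truth == 0], truth[truth == 0])
  }
})

test_that("with no withdrawal the simulator equals the closed form at all timepoints", {
  geom <- default_geom()
  sched <- sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 1e-12)
  # a vanishing draw stands in for V_s = 0 (the schedule requires V_s > 0)
  cfg <- sim_config(geom, sched, dose_spec(0.01),
                    barrier_model(c(membrane = 2e-5)), noise_cv = 0)
  sim <- simulate_insert(cfg)
  expected <- vapply(sched$times_h, function(t) {
    closed_form_basolateral_mass(hours_to_seconds(t), 2e-5, geom, 0.005)
  }, numeric(1))
  expect_equal(sim$truth$baso_mass_pre_sample_mg, expected, tolerance = 1e-9)
})

test_that("an impermeable barrier transports nothing", {
  cfg <- sim_config(barrier = barrier_model(c(membrane = 1e-300)), noise_cv = 0.1)
  sim <- simulate_insert(cfg)
  expect_equal(sim$series$concentrations_mg_ml,
               rep(0, length(sim$series$schedule$times_h)), tolerance = 1e-250)
  expect_equal(max(abs(as.numeric(percent_of_initial_dose(sim$series)))), 0,
               tolerance = 1e-250)
})

test_that("the simulator is deterministic given its seed", {
  cfg <- sim_config(noise_cv = 0.15, rng_seed = 99L)
  a <- simulate_insert(cfg, replicate = 2)
  b <- simulate_insert(cfg, replicate = 2)
  expect_identical(a$series$concentrations_mg_ml, b$series$concentrations_mg_ml)
  c <- simulate_insert(cfg, replicate = 3)
  expect_false(identical(a$series$concentrations_mg_ml,
                         c$series$concentrations_mg_ml))
})

test_that("barrier effective permeability is the harmonic composition", {
  b <- barrier_model(c(membrane = 30e-6, bewo = 2e-6, hpec = 9e-6))
  expect_equal(b$effective_permeability,
               1 / (1 / 30e-6 + 1 / 2e-6 + 1 / 9e-6))
  expect_lte(b$effective_permeability, min(b$layer_permeabilities))
})

test_that("estimating Pe from noiseless simulations recovers the cell-layer composition", {
  geom <- default_geom()
  sched <- sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 0.05)
  dose <- dose_spec(0.01)
  p_m <- 30e-6
  pe_true <- c(bewo = 8e-6, hpec = 12e-6)
  cell <- sim_config(geom, sched, dose,
                     barrier_model(c(membrane = p_m, pe_true)), noise_cv = 0)
  ctrl <- sim_config(geom, sched, dose,
                     barrier_model(c(membrane = p_m)), noise_cv = 0)
  est <- estimate_pe(list(simulate_insert(cell, condition = "coculture")$series),
                     list(simulate_insert(ctrl)$series), at_time_h = 0.25)
  expect_equal(est$pe_median, series_composition(pe_true), tolerance = 0.05)
})

test_that("generate_study emits the full labelled design deterministically", {
  design <- default_study_design(n_replicates = 2, noise_cv = 0.05, seed = 5L)
  study <- generate_study(design)
  expect_length(study$series, 6 * 4 * 2 * 2)
  conds <- vapply(study$series, function(s) s$condition, character(1))
  expect_setequal(unique(conds), c("control", "bewo", "hpec", "coculture"))
  regs <- vapply(study$series, function(s) s$regime, character(1))
  expect_setequal(unique(regs), c("static", "shaken"))
  findings <- unlist(lapply(study$series, validate_series))
  expect_length(findings, 0)
  # same seed, same study
  study2 <- generate_study(design)
  expect_identical(
    lapply(study$series, function(s) s$concentrations_mg_ml),
    lapply(study2$series, function(s) s$concentrations_mg_ml))
})

test_that("a leaky blank-membrane arm approaches the equilibrium fraction", {
  design <- default_study_design(n_replicates = 1, noise_cv = 0, seed = 1L,
                                 regimes = "static")
  study <- generate_study(design)
  s <- study$series[["antipyrine|control|static|1"]]
  pct <- as.numeric(percent_of_initial_dose(s))
  final <- utils::tail(pct, 1)
  oracle <- 100 * closed_form_basolateral_mass(
    hours_to_seconds(6), 60e-6, design$geometry, s$dose$initial_dose_mg) /
    s$dose$initial_dose_mg
  # sample-and-replace keeps the gradient alive, so the cumulative value
  # sits at or slightly above the event-free closed form near equilibrium
  expect_gte(final + 1e-9, oracle)
  expect_gt(final, 70)
})

test_that("type-I error of the exact test on null studies is at or below nominal", {
  # static and shaken arms share identical kinetics by construction, so any
  # rejection when comparing two noisy 4-replicate arms is a false positive
  geom <- default_geom()
  sched <- sampling_schedule(c(0, 0.25, 2, 4, 6, 8, 24), 0.05)
  cfg <- sim_config(geom, sched, dose_spec(0.01),
                    barrier_model(c(membrane = 1e-5)), noise_cv = 0.1)
  n_studies <- 2000
  set.seed(314)
  seeds <- sample.int(2^30, n_studies)
  reject <- logical(n_studies)
  for (i in seq_len(n_studies)) {
    cfg$rng_seed <- seeds[i]
    endpoints <- vapply(1:8, function(r) {
      utils::tail(as.numeric(percent_of_initial_dose(
        simulate_insert(cfg, replicate = r)$series)), 1)
    }, numeric(1))
    p <- mann_whitney_exact(endpoints[1:4], endpoints[5:8])$p_two_sided
    reject[i] <- p <= 0.05
  }
  rate <- mean(reject)
  # the achievable exact level at 4 vs 4 is 2/70; check the observed rate is
  # consistent with it and below the nominal 5%
  ci <- stats::binom.test(sum(reject), n_studies, p = 2 / 70)$conf.int
  expect_lt(rate, 0.05)
  expect_true(2 / 70 >= ci[1] && 2 / 70 <= ci[2])
})
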