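test_that("cumulative mass applies the withdrawn-sample correction", {
  # single timepoint: no prior draws to restore
  s1 <- make_series(0.002, times = 1, vs = 0.05)
  expect_equal(cumulative_mass(s1), 0.003)
  # two timepoints: second entry restores the first draw's mass
  s2 <- make_series(c(0.001, 0.002), times = c(1, 2), vs = 0.05)
  expect_equal(cumulative_mass(s2), c(0.0015, 0.002 * 1.5 + 0.05 * 0.001))
  # all-zero readings
  s0 <- make_series(rep(0, 4), times = 1:4)
  expect_equal(cumulative_mass(s0), rep(0, 4))
})

test_that("a nonzero t = 0 reading is treated as a pre-dose blank", {
  blank <- 2e-5
  s <- make_series(c(blank, 0.001 + blank, 0.002 + blank), times = c(0, 1, 2))
  ref <- make_series(c(0, 0.001, 0.002), times = c(0, 1, 2))
  expect_equal(cumulative_mass(s), cumulative_mass(ref), tolerance = 1e-12)
})

test_that("cumulative mass is non-decreasing for nonnegative readings", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    s <- make_series(cumsum(stats::runif(n, 0, 1e-3)) * sample(c(1, 1, 0), 1),
                     times = sort(stats::runif(n, 0.1, 24)),
                     vs = stats::runif(1, 0.01, 0.4))
    expect_true(all(diff(cumulative_mass(s)) >= -1e-15))
  }
})

test_that("percent of initial dose scales cumulative mass by ID", {
  s <- make_series(c(0.001, 0.002), times = c(1, 2), c0 = 0.01)
  id <- 0.01 * 0.5
  expect_equal(as.numeric(percent_of_initial_dose(s)),
               100 * cumulative_mass(s) / id)
  expect_equal(percent_of_initial_dose(id, dose = dose_spec(0.01)), 100)
  expect_equal(percent_of_initial_dose(0, dose = dose_spec(0.01)), 0)
  expect_error(percent_of_initial_dose(c(0.1), dose = NULL), "dose_spec")
})

test_that("equilibrium fraction is the basolateral volume share", {
  expect_equal(equilibrium_fraction(insert_geometry()), 0.75)
  expect_equal(equilibrium_fraction(insert_geometry(apical_volume_ml = 1,
                                                    basolateral_volume_ml = 1)), 0.5)
  # scale invariance
  expect_equal(equilibrium_fraction(insert_geometry(apical_volume_ml = 1,
                                                    basolateral_volume_ml = 3)), 0.75)
})

test_that("permeability is the secant-from-origin estimate", {
  # constructed identity: dQ(2 h) = A * C0 * 7200 => P = 1
  a <- 1.12; c0 <- 0.01
  conc2 <- a * c0 * 7200 / 1.5 # single-timepoint reading giving that dQ
  s <- make_series(conc2, times = 2, c0 = c0)
  expect_equal(permeability(s, 2), 1.0, tolerance = 1e-12)
  # all-zero series
  s0 <- make_series(rep(0, 3), times = c(1, 2, 3))
  expect_equal(permeability(s0, 2), 0)
  # guard rails
  expect_error(permeability(s0, 0), "> 0")
  expect_error(permeability(s0, 5), "not in schedule")
})

test_that("apparent permeability follows the series-resistance relation", {
  expect_equal(apparent_permeability(10e-6, 30e-6), 15e-6)
  # membrane much leakier than cells: Pe -> Pc
  expect_equal(apparent_permeability(1e-6, 1e-6 * 1e6), 1e-6, tolerance = 1e-4)
  # pole and zero
  expect_true(is.na(apparent_permeability(3e-5, 3e-5)))
  expect_true(is.na(apparent_permeability(4e-5, 3e-5)))
  expect_equal(apparent_permeability(0, 3e-5), 0)
  expect_error(apparent_permeability(-1e-6, 3e-5), "p_c >= 0")
})

test_that("Pe exceeds Pc strictly for any finite membrane", {
  set.seed(7)
  for (i in 1:50) {
    p_c <- 10^stats::runif(1, -7, -4)
    p_m <- p_c * 10^stats::runif(1, 0.05, 3)
    pe <- apparent_permeability(p_c, p_m)
    expect_gt(pe, p_c)
  }
})

test_that("series composition and membrane correction are inverses", {
  expect_equal(series_composition(c(10e-6, 10e-6)), 5e-6)
  expect_equal(series_composition(7e-6), 7e-6)
  expect_equal(series_composition(c(3e-6, 9e-6, 1e-6)),
               series_composition(c(1e-6, 3e-6, 9e-6)))
  expect_error(series_composition(c(1e-6, 0)), "> 0")
  set.seed(11)
  for (i in 1:100) {
    pe <- 10^stats::runif(1, -8, -3)
    pm <- 10^stats::runif(1, -8, -3)
    combined <- series_composition(c(pe, pm))
    expect_equal(apparent_permeability(combined, pm), pe,
                 tolerance = 1e-9)
  }
})

test_that("additivity deviation flags non-additive stacked barriers", {
  layers <- c(10e-6, 30e-6)
  expect_equal(additivity_deviation(series_composition(layers), layers), 1.0)
  # co-culture no tighter than one of two identical layers -> 0.5
  expect_equal(additivity_deviation(10e-6, c(10e-6, 10e-6)), 0.5)
  expect_error(additivity_deviation(0, layers), "> 0")
})

test_that("TEER normalisation subtracts the blank and corrects for area", {
  expect_equal(teer_normalized(teer_record(445, 100, 1.12)), 386.4)
  expect_equal(teer_normalized(teer_record(100, 100, 1.12)), 0)
  expect_warning(out <- teer_normalized(teer_record(90, 100, 1.12)), "negative")
  expect_equal(out, -10 * 1.12)
})

test_that("Na-F exclusion endpoint matches the closed-form oracle", {
  geom <- default_geom()
  dose <- dose_spec(0.00188, "naf")
  for (p_true in c(1e-7, 3e-5)) {
    m_b <- closed_form_basolateral_mass(hours_to_seconds(3), p_true, geom,
                                        dose$initial_dose_mg)
    oracle_pct <- 100 * m_b / dose$initial_dose_mg
    s <- translocation_series(geom, sampling_schedule(3, 0.05), dose,
                              m_b / geom$basolateral_volume_ml)
    expect_equal(naf_exclusion_endpoint(s), oracle_pct, tolerance = 1e-9)
  }
  # a tight barrier leaks under 1% in 3 h
  m_tight <- closed_form_basolateral_mass(hours_to_seconds(3), 1e-7, geom,
                                          dose$initial_dose_mg)
  s_tight <- translocation_series(geom, sampling_schedule(3, 0.05), dose,
                                  m_tight / geom$basolateral_volume_ml)
  expect_lt(naf_exclusion_endpoint(s_tight), 1)
  # wrong schedule is a lookup error
  s_bad <- make_series(c(0.001), times = 2)
  expect_error(naf_exclusion_endpoint(s_bad), "not in schedule")
})

test_that("permeability_result assembles all per-insert outputs", {
  cfg <- sim_config(dose = dose_spec(0.01),
                    barrier = barrier_model(c(membrane = 30e-6, bewo = 5e-6)),
                    noise_cv = 0)
  s <- simulate_insert(cfg)$series
  res <- permeability_result(s, p_m = 30e-6)
  expect_s3_class(res, "permeability_result")
  expect_equal(res$cumulative_mass_mg, cumulative_mass(s))
  expect_equal(sum(!is.na(res$p_cm_s)), sum(res$time_h > 0))
  expect_true(is.finite(res$pe_cm_s))
  # with P_c below the membrane permeability the correction inflates P
  expect_gt(res$pe_cm_s, res$p_cm_s[res$time_h == res$pe_time_h])
})
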