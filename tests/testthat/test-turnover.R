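test_that("no ATP means no turnover events", {
  atp <- const_atp(0, 50)
  sim <- simulate_pulsed_remodeling(atp, remodeler_kinetics(), 20, seed = 3)
  expect_equal(nrow(sim$events), 0L)
  unw <- simulate_unwinding(atp, helicase_kinetics(), 50, seed = 3)
  expect_true(all(is.na(unw$onset)))
  expect_false(any(unw$completed))
})

test_that("with negligible hydrolysis time and no cap, event counts are Poisson", {
  # near-zero cycle time disables the gating, so the binding process is a
  # plain Poisson process with rate k_on * [ATP]
  kin <- remodeler_kinetics(k_on = 0.02,
                            hydrolysis = list(dist = "fixed", value = 1e-9),
                            max_steps = 1e6)
  atp <- const_atp(25, 20)           # rate 0.5 s^-1, T = 20 s -> mean 10
  sim <- simulate_pulsed_remodeling(atp, kin, 1000, seed = 5)
  counts <- tabulate(sim$events$trace, nbins = 1000)
  lambda <- 0.02 * 25 * 20
  se <- sqrt(lambda / 1000)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  expect_lt(abs(var(counts) - lambda) / lambda, 0.2)
})

test_that("gated turnover counts match the renewal-process closed form on a pulsed toy", {
  # constant ATP c inside pulses, zero outside, fixed cycle time h:
  # P(>= k bindings in a pulse) = P(Gamma(k, k_on*c) < d - (k-1)*h)
  d <- 0.5; h <- 0.15; c0 <- 50; k_on <- 0.08
  atp <- square_atp(c0, duration = d, period = 10, n = 3)
  kin <- remodeler_kinetics(k_on = k_on,
                            hydrolysis = list(dist = "fixed", value = h),
                            max_steps = 1e6)
  n_tr <- 3000
  sim <- simulate_pulsed_remodeling(atp, kin, n_tr, pulse_period = 10,
                                    seed = 11)
  lam <- k_on * c0
  p_ge <- function(k) pgamma(d - (k - 1) * h, shape = k, rate = lam)
  n_pulse_cells <- 3 * n_tr
  counts <- table(factor(sim$events$pulse, levels = 0:2),
                  factor(sim$events$trace, levels = seq_len(n_tr)))
  for (k in 1:3) {
    emp <- mean(counts >= k)
    se <- sqrt(p_ge(k) * (1 - p_ge(k)) / n_pulse_cells)
    expect_lt(abs(emp - p_ge(k)), 4 * se + 1e-4)
  }
})

test_that("turnover simulation is reproducible under a seed", {
  atp <- square_atp(80, 0.2, 5, 4)
  kin <- remodeler_kinetics(k_on = 0.05)
  s1 <- simulate_pulsed_remodeling(atp, kin, 30, pulse_period = 5, seed = 42)
  s2 <- simulate_pulsed_remodeling(atp, kin, 30, pulse_period = 5, seed = 42)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$paths, s2$paths)
})

test_that("turnover statistics are normalised and the single-turnover limit holds", {
  atp <- square_atp(400, 0.02, 10, 6)
  kin <- remodeler_kinetics(k_on = 0.05)
  sim <- simulate_pulsed_remodeling(atp, kin, 400, pulse_period = 10,
                                    seed = 8)
  s <- sim$stats
  expect_equal(s$p0 + s$p1 + s$p_multi, 1)
  expect_gte(s$compound_fraction, 0)
  expect_lte(s$compound_fraction, 1)
  # period >> cycle time and a short pulse: non-empty pulses are single
  expect_gte(s$p1 / (s$p1 + s$p_multi), 0.99)
})

test_that("unwinding speed follows Michaelis-Menten kinetics", {
  kin <- helicase_kinetics(vmax = 1, km = 40, k_init = 50, cv_speed = 0.3)
  atp <- const_atp(40, 60)            # [ATP] = km -> mean speed vmax/2
  unw <- simulate_unwinding(atp, kin, 1000, seed = 13)
  speeds <- 1 / unw$duration[unw$completed]
  expect_gt(length(speeds), 900)
  se <- sd(speeds) / sqrt(length(speeds))
  expect_lt(abs(mean(speeds) - 0.5), 3 * se)
  # saturating ATP: rates centred on vmax
  unw_sat <- simulate_unwinding(const_atp(4000, 60), kin, 500, seed = 14)
  sp_sat <- 1 / unw_sat$duration[unw_sat$completed]
  expect_lt(abs(mean(sp_sat) - 1), 3 * sd(sp_sat) / sqrt(length(sp_sat)))
})

test_that("pulse-regime statistics behave monotonically in pulse duration", {
  cond <- single_turnover_conditions(n_pulses = 4L)
  kin <- remodeler_kinetics(k_on = 0.013)
  tab <- pulse_regime_table(kin, cond$photolysis, cond$scavenger,
                            cond$caged0, cond$power_density,
                            durations = c(0.005, 0.03, 0.09, 0.18),
                            period = 8, n_pulses = 4L, n_mc = 250, seed = 2)
  expect_gt(tab$p0[1], 0.95)                      # duration -> 0: P(0) -> 1
  expect_true(all(diff(tab$p_multi) >= -0.01))    # P(>=2) non-decreasing
  expect_equal(tab$p0 + tab$p1 + tab$p_multi, rep(1, 4))
  expect_warning(
    pulse_regime_table(kin, cond$photolysis, cond$scavenger, cond$caged0,
                       cond$power_density, durations = 0.05, period = 0.5,
                       n_pulses = 2L, n_mc = 5, seed = 1),
    "straddle")
})

test_that("binding-rate calibration reaches one turnover per first pulse", {
  cond <- single_turnover_conditions()
  atp <- single_turnover_atp(0.09, cond)
  kin <- calibrate_k_on(atp, remodeler_kinetics(), pulse_period = cond$period,
                        n_traces = 200, seed = 4)
  sim <- simulate_pulsed_remodeling(atp, kin, 400,
                                    pulse_period = cond$period,
                                    pulse_t0 = cond$t0, seed = 5)
  first_pulse <- sum(sim$events$pulse == 0L) / 400
  expect_gt(first_pulse, 0.8)
  expect_lt(first_pulse, 1.25)
})
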