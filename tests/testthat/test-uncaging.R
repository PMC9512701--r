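test_that("photolysis rate constant matches the dimensional-analysis value and is linear in intensity", {
  # frozen oracle: photon flux x decadic cross-section x quantum yield at
  # eps = 4000 M^-1 cm^-1, phi = 0.07, lambda = 360 nm, I = 10 W cm^-2
  p <- photolysis_params(molar_absorptivity = 4000, quantum_yield = 0.07)
  expect_equal(photolysis_rate_constant(p, 10, 360), 19.402093,
               tolerance = 1e-6)
  expect_identical(photolysis_rate_constant(p, 0), 0)
  I <- c(0.5, 3, 47)
  expect_equal(photolysis_rate_constant(p, 2 * I) /
                 photolysis_rate_constant(p, I), rep(2, 3))
  expect_error(photolysis_rate_constant(p, -1), "non-negative")
  expect_error(photolysis_rate_constant(p, 1, wavelength = 600), "300-450")
})

test_that("dark protocols produce no free NTP anywhere", {
  prot <- illumination_protocol(0, total_duration = 5)
  fld <- simulate_well_mixed(prot, fix_phot(), fix_scav_lin(), 1000, dt = 0.05)
  expect_true(all(fld$data$free == 0))
  expect_equal(effective_concentration(fld), 0)
})

test_that("well-mixed solver reproduces the closed-form steady state within 0.1%", {
  phot <- fix_phot(); scav <- fix_scav_lin()
  prot <- illumination_protocol(5, total_duration = 15)
  fld <- simulate_well_mixed(prot, phot, scav, 10000, dt = 0.01)
  ss <- steady_state_free(phot, scav, 10000, 5)
  expect_gt(ss, 0)
  expect_equal(tail(fld$data$free, 1), ss, tolerance = 1e-3)
  # full Michaelis-Menten steady state too (slower relaxation near Vmax)
  scav_mm <- scavenger_params(10)
  prot_long <- illumination_protocol(5, total_duration = 60)
  fld2 <- simulate_well_mixed(prot_long, phot, scav_mm, 10000, dt = 0.02)
  expect_equal(tail(fld2$data$free, 1),
               steady_state_free(phot, scav_mm, 10000, 5), tolerance = 1e-3)
})

test_that("post-pulse decay is exponential at the linearized scavenging rate", {
  phot <- fix_phot(); scav <- fix_scav_lin()
  prot <- illumination_protocol(50, pulses = list(duration = 0.1, period = 8,
                                                  n = 1))
  fld <- simulate_well_mixed(prot, phot, scav, 10000, dt = 0.005)
  d <- fld$data[fld$data$time > 0.15 & fld$data$free > 1e-9, ]
  fit <- lm(log(free) ~ time, data = d)
  expect_equal(unname(-coef(fit)[2]), scav$k_scav, tolerance = 0.01)
})

test_that("closed-system mass balance holds to 1e-6 and dt misuse errors", {
  phot <- fix_phot(); scav <- scavenger_params(10)
  prot <- illumination_protocol(20, pulses = list(duration = 0.2, period = 2,
                                                  n = 3))
  fld <- simulate_well_mixed(prot, phot, scav, 500, dt = 0.01,
                             reservoir = FALSE)
  total <- with(fld$data, caged + free + consumed)
  expect_lt(max(abs(total - 500)) / 500, 1e-6)
  expect_true(all(fld$data$free >= 0))
  expect_error(simulate_well_mixed(prot, phot, scav, 500, dt = 0.05),
               "does not resolve")
})

test_that("effective concentration of a pulsed protocol matches the duty-cycle closed form", {
  phot <- fix_phot(); scav <- fix_scav_lin()
  k_unc <- photolysis_rate_constant(phot, 100)
  caged0 <- 10000
  prot <- illumination_protocol(100, pulses = list(duration = 0.09,
                                                   period = 8, n = 12))
  fld <- simulate_well_mixed(prot, phot, scav, caged0, dt = 0.0045)
  # piecewise closed form per period: exponential rise over the pulse,
  # exponential decay after; average over one period
  ks <- scav$k_scav; d <- 0.09; P <- 8
  fss <- k_unc * caged0 / ks
  rise_int <- fss * (d - (1 - exp(-ks * d)) / ks)
  peak <- fss * (1 - exp(-ks * d))
  decay_int <- peak / ks * (1 - exp(-ks * (P - d)))
  analytic <- (rise_int + decay_int) / P
  expect_equal(effective_concentration(fld), analytic, tolerance = 0.02)
})

test_that("low-power response is linear and scavenger doubling halves the steady state", {
  phot <- fix_phot(); scav <- fix_scav_lin()
  prot1 <- illumination_protocol(1, total_duration = 20)
  prot2 <- illumination_protocol(2, total_duration = 20)
  f1 <- simulate_well_mixed(prot1, phot, scav, 10000, dt = 0.02)
  f2 <- simulate_well_mixed(prot2, phot, scav, 10000, dt = 0.02)
  e1 <- effective_concentration(f1, window = c(10, 20))
  e2 <- effective_concentration(f2, window = c(10, 20))
  expect_equal(e2 / e1, 2, tolerance = 0.01)
  expect_equal(steady_state_free(phot, fix_scav_lin(20), 10000, 5),
               steady_state_free(phot, fix_scav_lin(10), 10000, 5) / 2)
})

test_that("uniform illumination with reflecting boundaries reduces to the well-mixed solution", {
  phot <- fix_phot(); scav <- fix_scav_lin(); diff <- diffusion_params(300)
  prot <- illumination_protocol(5, wavelength = 360, spot = c(Inf, Inf),
                                total_duration = 4)
  sp <- simulate_spatial(prot, phot, scav, diff, 10000,
                         grid = list(extent = 20, nx = 41),
                         boundary = "reflecting",
                         times = seq(0, 4, by = 0.25))
  wm <- simulate_well_mixed(prot, phot, scav, 10000, dt = 0.002)
  wm_at <- approx(wm$data$time, wm$data$free, xout = sp$times)$y
  prof <- sp$free
  # spatially flat
  expect_lt(max(apply(prof[-1, ], 1, function(r) diff(range(r)) /
                        max(mean(r), 1e-12))), 1e-6)
  # equal to the 0-D solution within 0.5%
  rel <- abs(rowMeans(prof[-1, ]) - wm_at[-1]) / wm_at[-1]
  expect_lt(max(rel), 0.005)
})

test_that("steady-state profile outside the spot decays with the analytic length", {
  scav <- fix_scav_lin(); diff <- diffusion_params(300)
  L <- decay_length(scav, diff)
  phot <- fix_phot()
  prot <- illumination_protocol(5, spot = c(60, 60), total_duration = 30)
  sp <- simulate_spatial(prot, phot, scav, diff, 10000,
                         grid = list(extent = 30 + 5.5 * L,
                                     nx = 2 * ceiling((30 + 5.5 * L) / (L / 12)) + 1),
                         times = c(0, 15, 30))
  prof <- sp$free[nrow(sp$free), ]
  x <- sp$grid$x
  x0 <- 30 + L
  f <- approx(x, prof, xout = c(x0, x0 + L))$y
  expect_equal(f[2] / f[1], exp(-1), tolerance = 0.02)
  # grid-too-coarse guard
  expect_error(simulate_spatial(prot, phot, scav, diff, 10000,
                                grid = list(extent = 30 + 6 * L, nx = 21)),
               "too coarse")
})

test_that("two-fold decay distance with the stated default constants brackets the printed scale", {
  scav <- scavenger_params(activity = 10, vmax_per_unit = 16.7, km = 120)
  diff <- diffusion_params(300)
  two_fold <- decay_length(scav, diff) * log(2)
  expect_gt(two_fold, 3)
  expect_lt(two_fold, 30)
})

test_that("photolysis calibration hits its target effective concentration", {
  scav <- scavenger_params(10)
  phot <- calibrate_photolysis(photolysis_params(), scav, 2000, 5, 40)
  expect_equal(steady_state_free(phot, scav, 2000, 5), 40, tolerance = 1e-9)
  prot <- illumination_protocol(5, total_duration = 10)
  fld <- simulate_well_mixed(prot, phot, scav, 2000, dt = 0.01)
  expect_equal(tail(fld$data$free, 1), 40, tolerance = 1e-3)
})
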