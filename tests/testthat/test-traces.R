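test_that("state paths map to piecewise-constant FRET plateaus", {
  # empty path: constant at the initial level
  p0 <- state_path(numeric(0), numeric(0), 0.25, 5)
  f0 <- fret_from_state(p0, frame_rate = 10)
  expect_true(all(f0$fret == 0.25))
  # three 0.1 steps from 0.3: plateaus at 0.3 / 0.4 / 0.5 / 0.6
  p <- state_path(c(1, 2.5, 3.2), rep(0.1, 3), 0.3, 5)
  f <- fret_from_state(p, frame_rate = 10)
  expect_setequal(round(unique(f$fret), 10), c(0.3, 0.4, 0.5, 0.6))
  expect_equal(f$fret[f$time < 1], rep(0.3, sum(f$time < 1)))
  expect_equal(tail(f$fret, 1), 0.6)
  expect_error(fret_from_state(p, mapping = function(s) rep(NA_real_, length(s))),
               "unmapped")
})

test_that("unwinding FRET decays linearly and crosses the midpoint at half time", {
  f <- unwinding_fret(onset = 2, duration = 4, e_high = 0.9, e_low = 0.1,
                      t_end = 10, frame_rate = 100)
  mid_t <- f$time[which.min(abs(f$fret - 0.5))]
  expect_equal(mid_t, 2 + 4 / 2, tolerance = 0.02)
  expect_equal(attr(f, "donor_loss_time"), 6)
  expect_true(all(f$fret[f$time <= 2] == 0.9))
})

test_that("noiseless synthesis inverts exactly through the forward-model equations", {
  om <- optical_model(beta = 0.12, alpha = 0.06, gamma_d = 1.3, sigma = 0,
                      aa_interleave = 1)
  ideal <- data.frame(time = seq(0, 10, 0.1),
                      fret = rep(c(0.3, 0.5, 0.7), length.out = 101))
  tr <- synthesize_fret_trace(ideal, om, total_intensity = 1000,
                              bleaching = FALSE)
  e_rec <- (tr$I_DA - om$beta * tr$I_DD - om$alpha * tr$I_AA) /
    (tr$I_DA - om$beta * tr$I_DD - om$alpha * tr$I_AA + tr$I_DD / om$gamma_d)
  expect_equal(e_rec, ideal$fret, tolerance = 1e-12)
})

test_that("photobleach times follow the configured exponential survival", {
  om <- optical_model(sigma = 0, bleach_half_life = c(donor = 180,
                                                      acceptor = 90))
  ideal <- data.frame(time = c(0, 0.1), fret = c(0.5, 0.5))
  set.seed(77)
  ts <- synthesize_trace_set(rep(list(ideal), 2000), om)
  ann <- ts$annotations
  expect_lt(abs(median(ann$donor_bleach) - 180) / 180, 0.05)
  ks_d <- ks.test(ann$donor_bleach, pexp, log(2) / 180)
  ks_a <- ks.test(ann$acceptor_bleach, pexp, log(2) / 90)
  expect_gt(ks_d$p.value, 0.01)
  expect_gt(ks_a$p.value, 0.01)
})

test_that("donor-strand loss silences donor-excited channels but not direct excitation", {
  om <- optical_model(sigma = 0, alpha = 0, beta = 0, aa_interleave = 1)
  ideal <- unwinding_fret(onset = 1, duration = 2, e_high = 0.9,
                          e_low = 0.1, t_end = 10, frame_rate = 10)
  tr <- synthesize_fret_trace(ideal, om, total_intensity = 1000,
                              bleaching = FALSE)
  after <- tr$time > 3.05
  expect_true(all(tr$I_DD[after] == 0))
  expect_true(all(tr$I_DA[after] == 0))
  expect_true(all(tr$I_AA[after] > 0))
})

test_that("AFS synthesis produces the configured piecewise-linear elongation", {
  win <- rbind(c(10, 20), c(40, 50))
  prof <- elongation_profile(win, rate = 10, t_end = 60, dt = 0.05)
  expect_true(!is.unsorted(prof$bp))
  expect_equal(max(prof$bp), 10 * 20, tolerance = 0.01)
  # zero elongation: flat apart from noise
  flat <- synthesize_afs_trace(elongation_profile(win, 0, 60), sigma = 2,
                               seed = 1)
  expect_lt(abs(mean(diff(flat$position))), 0.05)
  # noiseless: slope -rate * rise_per_bp inside windows, 0 outside
  tr <- synthesize_afs_trace(prof, rise_per_bp = 0.34, sigma = 0)
  sl_in <- coef(lm(position ~ time, tr[tr$time > 10 & tr$time < 20, ]))[2]
  sl_out <- coef(lm(position ~ time, tr[tr$time > 25 & tr$time < 35, ]))[2]
  expect_equal(unname(sl_in), -10 * 0.34, tolerance = 1e-8)
  expect_equal(unname(sl_out), 0, tolerance = 1e-10)
  # noisy: slope recovered within 3 standard errors
  trn <- synthesize_afs_trace(prof, rise_per_bp = 0.34, sigma = 5, seed = 9)
  fit <- lm(position ~ time, trn[trn$time > 10 & trn$time < 20, ])
  expect_lt(abs(coef(fit)[2] + 3.4), 3 * summary(fit)$coefficients[2, 2])
})
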