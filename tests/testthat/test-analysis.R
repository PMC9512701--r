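test_that("channel correction is the identity with trivial parameters", {
  fr <- data.frame(trace = 1, time = 0:9 / 10, I_DD = 500 + 0:9,
                   I_DA = 300 - 0:9, I_AA = rep(800, 10))
  cc <- correct_channels(fr, correction_params(0, 0, 1), noise_floor = 0)
  expect_equal(cc$donor, fr$I_DD)
  expect_equal(cc$acceptor, fr$I_DA)
  expect_equal(cc$fret, fr$I_DA / (fr$I_DA + fr$I_DD))
})

test_that("correction inverts the synthesis forward model to machine precision", {
  om <- optical_model(beta = 0.1, alpha = 0.05, gamma_d = 1.2, sigma = 0,
                      aa_interleave = 1)
  e_true <- seq(0.2, 0.8, length.out = 60)
  ideal <- data.frame(time = seq_along(e_true) / 10, fret = e_true)
  ts <- synthesize_trace_set(list(ideal, ideal), om, seed = 2,
                             bleaching = FALSE)
  cc <- correct_channels(ts, correction_from_optical(om))
  expect_false(any(cc$masked))
  expect_lt(max(abs(cc$fret - rep(e_true, 2))), 1e-9)
})

test_that("post-bleach frames are masked and acceptor-bleached traces read near-zero FRET", {
  om <- optical_model(beta = 0, alpha = 0, gamma_d = 1, sigma = 0,
                      aa_interleave = 1)
  # donor-only signal: acceptor gone -> E ~ 0 on unmasked frames
  fr <- data.frame(trace = 1, time = 0:49 / 10, I_DD = rep(1000, 50),
                   I_DA = rep(0, 50), I_AA = rep(0, 50))
  cc <- correct_channels(fr, correction_params(0, 0, 1))
  expect_true(all(abs(cc$fret[!cc$masked]) < 1e-9))
  # dead channels are masked, not errored
  fr2 <- fr; fr2$I_DD <- 1e-3
  cc2 <- correct_channels(rbind(fr), correction_params(0, 0, 1),
                          noise_floor = 10)
  expect_false(any(cc2$masked))
})

test_that("the acceptor excitation ratio classifies unwound molecules and recovers the completed fraction", {
  om <- optical_model(beta = 0.08, alpha = 0.05, gamma_d = 1, sigma = 8,
                      aa_interleave = 1)
  set.seed(91)
  n <- 1000
  done <- runif(n) < 0.6
  ideals <- lapply(seq_len(n), function(i) {
    if (done[i]) unwinding_fret(0.5, 1.5, 0.85, 0.15, t_end = 6,
                                frame_rate = 10)
    else unwinding_fret(NA, NA, 0.85, 0.15, t_end = 6, frame_rate = 10)
  })
  ts <- synthesize_trace_set(ideals, om, seed = 92, bleaching = FALSE)
  cr <- cy5_ratio(ts, window = 10)
  expect_lt(abs(cr$fraction_unwound - mean(done)), 0.03)
  # ratios of unwound molecules collapse to the direct-excitation floor
  pm <- cr$per_molecule
  expect_gt(min(pm$ratio_before), max(pm$ratio_after[pm$unwound]))
})

test_that("a sensitised channel at the crosstalk floor yields a ratio near alpha", {
  om <- optical_model(beta = 0, alpha = 0.07, gamma_d = 1, sigma = 0,
                      aa_interleave = 1)
  ideal <- unwinding_fret(0.1, 0.2, 0.85, 0.15, t_end = 10, frame_rate = 10)
  tr <- synthesize_fret_trace(ideal, om, bleaching = FALSE)
  late <- tr$time > 1
  expect_equal(mean(tr$I_DA[late]) / mean(tr$I_AA[late]), 0.07,
               tolerance = 1e-9)
})

test_that("unwinding rates are the reciprocal transit times", {
  om <- optical_model(beta = 0, alpha = 0, gamma_d = 1, sigma = 0,
                      aa_interleave = 1)
  ideals <- rep(list(unwinding_fret(2, 4, 0.85, 0.15, t_end = 10,
                                    frame_rate = 10)), 5)
  ts <- synthesize_trace_set(ideals, om, seed = 3, bleaching = FALSE)
  cc <- correct_channels(ts, correction_from_optical(om))
  re <- unwinding_rate(cc)
  expect_equal(re$n, 5L)
  # departure at ~2 s (below 0.75), loss at 6 s: rate ~ 1/4, frame-quantised
  expect_true(all(abs(re$per_trace$rate - 0.25) < 0.02))
  expect_equal(re$sem, 0)
})

test_that("a Michaelis constant is recovered from a synthetic titration", {
  kin <- helicase_kinetics(vmax = 1.2, km = 35, k_init = 50, cv_speed = 0.25)
  conc <- c(5, 10, 20, 40, 80, 160, 320, 640)
  rates <- vapply(seq_along(conc), function(i) {
    unw <- simulate_unwinding(const_atp(conc[i], 120), kin, 200,
                              seed = 100 + i)
    mean(unw$rate[unw$completed])
  }, numeric(1))
  fit <- fit_mm_titration(conc, rates)
  expect_lt(abs(fit$km - 35) / 35, 0.15)
  expect_lt(abs(fit$vmax - 1.2) / 1.2, 0.1)
})

test_that("rate-matching maps power to effective concentration", {
  # identical Michaelis-Menten curves up to an abscissa rescale x c
  km <- 50; vmax <- 1
  atp <- exp(seq(log(2), log(800), length.out = 150))
  rate_vs_atp <- data.frame(atp = atp, rate = vmax * atp / (km + atp))
  c_scale <- 12.5
  power <- seq(0.2, 8, length.out = 12)
  rate_vs_power <- data.frame(power = power,
                              rate = vmax * c_scale * power /
                                (km + c_scale * power))
  map <- effective_atp_mapping(rate_vs_power, rate_vs_atp)
  ok <- !map$flagged
  expect_gt(sum(ok), 8)
  expect_lt(max(abs(map$effective_atp[ok] / map$power[ok] - c_scale) /
                  c_scale), 0.02)
  # a rate above the titration plateau is flagged, not extrapolated
  map2 <- effective_atp_mapping(
    data.frame(power = c(1, 2), rate = c(0.5, 0.999)), rate_vs_atp)
  expect_true(map2$flagged[2])
  expect_true(is.na(map2$effective_atp[2]))
  expect_error(effective_atp_mapping(
    data.frame(power = 1:3, rate = c(0.2, 0.1, 0.3)), rate_vs_atp),
    "monotone")
})

test_that("AFS elongation rates separate uncaging-on from uncaging-off windows", {
  win <- rbind(c(60, 120), c(180, 240))
  prof <- elongation_profile(win, rate = 8, t_end = 300, dt = 0.02)
  tr <- synthesize_afs_trace(prof, rise_per_bp = 0.34, sigma = 6, seed = 41)
  res <- afs_elongation(tr, uncaging_windows = win, rise_per_bp = 0.34)
  on <- res$on_rates; off <- res$off_rates
  expect_lt(abs(mean(on) - 8), 3 * sd(on) / sqrt(length(on)) + 0.2)
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)) + 0.2)
  # noiseless trace: windowed rates equal the set rate exactly (mid-window)
  tr0 <- synthesize_afs_trace(prof, rise_per_bp = 0.34, sigma = 0)
  res0 <- afs_elongation(tr0, uncaging_windows = win, rise_per_bp = 0.34)
  core <- res0$rates[res0$rates$phase == "on" &
                       res0$rates$t_mid > 75 & res0$rates$t_mid < 105, ]
  expect_equal(core$rate, rep(8, nrow(core)), tolerance = 0.02)
  expect_error(afs_elongation(tr[1:50, ], win), "filter span")
})

test_that("the median filter suppresses single-sample outliers", {
  t <- seq(0, 120, by = 0.05)
  pos <- rep(0, length(t)); pos[1200] <- 50      # one-sample spike
  res <- afs_elongation(data.frame(time = t, position = pos),
                        uncaging_windows = rbind(c(60, 90)))
  expect_lt(max(abs(res$smoothed$position)), 1e-6)
})
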