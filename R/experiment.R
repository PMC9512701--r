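#' Study conditions for the pulsed single-turnover remodeling experiment
#'
#' Returns the parameter set used throughout the package for the pulsed
#' single-turnover simulations: uncaging photochemistry anchored so that
#' continuous 5 W cm^-2 uncaging of 2 mM caged ATP against 10 U ml^-1
#' hexokinase sustains 40 uM effective free ATP (the measured effective
#' concentration of the continuous-uncaging titration); pulses of 100
#' W cm^-2 on a 10 mM caged-ATP reservoir every 8 s with an 8-s baseline
#' before the first pulse; scavenging strong enough that the post-pulse free
#' ATP of a 90-ms pulse is consumed within roughly one hydrolysis time
#' (50 U ml^-1), the design point of the single-turnover regime; hydrolysis
#' completion uniform on 0.2-0.6 s; a 5-Hz camera with per-channel noise of
#' 10 (1 percent of the total intensity, i.e. FRET noise of about 0.014);
#' and step detection at its full temporal resolution (3-frame plateaus).
#'
#' @param n_pulses Pulses per trace (default 8).
#' @return List of condition objects: `photolysis`, `scavenger`, `caged0`,
#'   `power_density`, `period`, `t0`, `n_pulses`, `frame_rate`, `om`
#'   (optical model), `min_size`, `min_dwell`.
#' @export
single_turnover_conditions <- function(n_pulses = 8L) {
  scav_anchor <- scavenger_params(10)
  phot <- calibrate_photolysis(photolysis_params(), scav_anchor,
                               caged0 = 2000, power_density = 5,
                               target_free = 40)
  list(photolysis = phot,
       scavenger = scavenger_params(50),
       caged0 = 10000, power_density = 100,
       period = 8, t0 = 8, n_pulses = as.integer(n_pulses),
       frame_rate = 5,
       om = optical_model(sigma = 10, frame_rate = 5),
       min_size = 3L, min_dwell = 5L)
}

#' Free-ATP time series for one pulsed single-turnover condition
#'
#' @param duration Pulse duration, s.
#' @param cond Conditions from [single_turnover_conditions()].
#' @return Data frame `time`, `free` (uM) from the well-mixed uncaging model.
#' @export
single_turnover_atp <- function(duration, cond = single_turnover_conditions()) {
  prot <- illumination_protocol(cond$power_density,
                                pulses = list(duration = duration,
                                              period = cond$period,
                                              n = cond$n_pulses,
                                              t0 = cond$t0))
  fld <- simulate_well_mixed(prot, cond$photolysis, cond$scavenger,
                             cond$caged0, dt = min(duration / 20, 0.01))
  free_ntp_series(fld)
}

#' Simulate and analyse one pulse-duration condition end to end
#'
#' Chemistry, gated stochastic stepping, synthetic three-channel traces,
#' channel correction, step detection and first-step collection for one
#' pulse duration of the single-turnover experiment.
#'
#' @param duration Pulse duration, s.
#' @param kinetics A (calibrated) [remodeler_kinetics()].
#' @param n_traces Number of molecules.
#' @param seed Integer seed.
#' @param cond Conditions from [single_turnover_conditions()].
#' @return List with `sizes` (first-step FRET changes), `n_excluded`,
#'   `stats` (`turnover_stats` of the underlying simulation).
#' @export
single_turnover_condition_run <- function(duration, kinetics, n_traces = 500,
                                          seed = 1,
                                          cond = single_turnover_conditions()) {
  atp <- single_turnover_atp(duration, cond)
  sim <- simulate_pulsed_remodeling(atp, kinetics, n_traces,
                                    frame_rate = cond$frame_rate,
                                    pulse_period = cond$period,
                                    pulse_t0 = cond$t0, seed = seed)
  ideals <- lapply(sim$paths, fret_from_state, frame_rate = cond$frame_rate)
  traces <- synthesize_trace_set(ideals, cond$om, seed = seed + 1L)
  cc <- correct_channels(traces, correction_from_optical(cond$om))
  fits <- lapply(split(cc, cc$trace), function(d) {
    y <- d$fret[!d$masked]
    if (length(y) >= 10L) find_steps(y, min_size = cond$min_size) else NULL
  })
  fs <- first_step_sizes(Filter(Negate(is.null), fits),
                         min_dwell = cond$min_dwell)
  list(sizes = fs$sizes, n_excluded = fs$n_excluded, stats = sim$stats)
}

#' The pulsed single-turnover experiment across pulse durations
#'
#' Runs the full simulated experiment of the pulse-duration comparison:
#' calibrates the binding rate on the 90-ms condition (one turnover per
#' pulse on average in the first cycle), simulates every requested duration,
#' fits the 180-ms (or longest-duration) first-step histogram with a free
#' two-Gaussian mixture and the other durations with the second component's
#' centre and width fixed to that reference fit, and reports the
#' compound-step fraction per duration.
#'
#' @param durations Pulse durations, s (default 0.03, 0.09, 0.18).
#' @param n_traces Traces per condition (default 500).
#' @param seed Integer seed.
#' @param cond Conditions from [single_turnover_conditions()].
#' @param calib_traces Monte-Carlo traces used in the binding-rate
#'   calibration (default 300).
#' @return List with `table` (data frame: duration, compound_fraction,
#'   n_first_steps), `fits` (list of `mixture_fit`), `kinetics` (calibrated),
#'   `reference` (the free fit of the longest duration).
#' @export
single_turnover_experiment <- function(durations = c(0.03, 0.09, 0.18),
                                       n_traces = 500, seed = 1,
                                       cond = single_turnover_conditions(),
                                       calib_traces = 300) {
  atp90 <- single_turnover_atp(0.09, cond)
  kin <- calibrate_k_on(atp90, remodeler_kinetics(),
                        pulse_period = cond$period,
                        n_traces = calib_traces, seed = seed)
  ref_d <- max(durations)
  runs <- lapply(seq_along(durations), function(i)
    single_turnover_condition_run(durations[i], kin, n_traces,
                                  seed = seed + 10L * i, cond = cond))
  names(runs) <- sprintf("%g", durations)
  ref <- fit_two_gaussians(runs[[sprintf("%g", ref_d)]]$sizes)
  fits <- lapply(seq_along(durations), function(i) {
    if (durations[i] == ref_d) return(ref)
    fit_two_gaussians(runs[[i]]$sizes,
                      fix_component2 = c(ref$mean[2], ref$sigma[2]))
  })
  tab <- data.frame(duration = durations,
                    compound_fraction =
                      vapply(fits, function(f) f$compound_fraction,
                             numeric(1)),
                    n_first_steps =
                      vapply(runs, function(r) length(r$sizes), numeric(1)))
  list(table = tab, fits = fits, kinetics = kin, reference = ref,
       runs = runs)
}
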