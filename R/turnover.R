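#' Remodeler stepping kinetics
#'
#' Parameters of the productive-binding / hydrolysis cycle of an ATP-dependent
#' chromatin remodeler observed as discrete FRET steps.
#'
#' @param k_on Productive NTP binding rate constant, uM^-1 s^-1. A free
#'   calibration parameter; see [calibrate_k_on()].
#' @param hydrolysis Hydrolysis-completion-time distribution: a list with
#'   `dist` one of `"uniform"` (elements `min`, `max`, s), `"exponential"`
#'   (`mean`, s) or `"fixed"` (`value`, s). Default uniform on 0.2-0.6 s,
#'   the reported range of mean ATP hydrolysis times for Chd1.
#' @param step_size FRET change per elementary hydrolysis step (default 0.1).
#' @param max_steps Processivity cap: number of steps after which the enzyme
#'   stops binding productively (default 6; beyond this the acceptor passes
#'   the donor and the monotone FRET-increase phase ends).
#' @return An object of class `remodeler_kinetics`.
#' @export
remodeler_kinetics <- function(k_on = 0.05,
                               hydrolysis = list(dist = "uniform",
                                                 min = 0.2, max = 0.6),
                               step_size = 0.1, max_steps = 6L) {
  stopifnot(k_on > 0, step_size > 0, max_steps >= 1)
  hydrolysis$dist <- match.arg(hydrolysis$dist,
                               c("uniform", "exponential", "fixed"))
  if (hydrolysis$dist == "uniform")
    stopifnot(hydrolysis$min > 0, hydrolysis$min <= hydrolysis$max)
  structure(list(k_on = k_on, hydrolysis = hydrolysis,
                 step_size = step_size, max_steps = as.integer(max_steps)),
            class = "remodeler_kinetics")
}

.draw_hydrolysis <- function(h, n = 1L) {
  switch(h$dist,
         uniform = stats::runif(n, h$min, h$max),
         exponential = stats::rexp(n, 1 / h$mean),
         fixed = rep(h$value, n))
}

#' Helicase unwinding kinetics
#'
#' Michaelis-Menten dependence of the unwinding speed on free ATP, with FRET
#' decaying from `e_high` to `e_low` over the unwinding interval and loss of
#' the donor-labelled strand on completion.
#'
#' @param vmax Maximal unwinding rate, s^-1 (reciprocal of the minimal
#'   high-FRET-to-strand-loss transit time at saturating ATP).
#' @param km Michaelis constant for ATP, uM.
#' @param e_high,e_low FRET levels before and at the end of unwinding.
#' @param k_init Initiation rate constant, s^-1, scaled by the same
#'   Michaelis-Menten ATP factor (exponential waiting to unwinding onset).
#' @param cv_speed Coefficient of variation of the per-molecule speed
#'   multiplier (log-normal, mean 1); 0 for deterministic speeds.
#' @return An object of class `helicase_kinetics`.
#' @export
helicase_kinetics <- function(vmax = 1.3, km = 50, e_high = 0.85,
                              e_low = 0.15, k_init = 0.5, cv_speed = 0.3) {
  stopifnot(vmax > 0, km > 0, e_high > e_low, k_init > 0, cv_speed >= 0)
  structure(list(vmax = vmax, km = km, e_high = e_high, e_low = e_low,
                 k_init = k_init, cv_speed = cv_speed),
            class = "helicase_kinetics")
}

# piecewise-linear interpolator for an atp series (data.frame time, free)
.atp_fun <- function(atp) {
  stopifnot(is.data.frame(atp), all(c("time", "free") %in% names(atp)))
  stats::approxfun(atp$time, atp$free, rule = 2)
}

#' Simulate remodeler stepping driven by a free-NTP time series
#'
#' Draws productive ATP-binding events from an inhomogeneous Poisson process
#' with rate `k_on * [ATP](t)`, gated by enzyme availability: while a
#' hydrolysis cycle is in progress (a drawn completion time after binding) no
#' new productive binding occurs. Each completion advances the FRET state by
#' one `step_size`. Completions falling inside the same camera frame are
#' merged into one compound step in the emitted state path.
#'
#' @param atp Data frame with columns `time` (s) and `free` (uM) covering the
#'   protocol; typically [free_ntp_series()] of a [simulate_well_mixed()]
#'   field. Linearly interpolated between samples.
#' @param kinetics A [remodeler_kinetics()].
#' @param n_traces Number of molecules to simulate.
#' @param frame_rate Camera frame rate, Hz (default 10; sets the compound-step
#'   merge window of one frame).
#' @param pulse_period Pulse period in s used to attribute events to pulses
#'   for the turnover statistics (`NA` to skip attribution).
#' @param pulse_t0 Start time of the first pulse, s (default 0).
#' @param seed Integer seed; identical inputs and seed give identical event
#'   lists.
#' @param e0 Initial FRET state (default 0.3, the low-FRET starting level of
#'   the entry-side labelling scheme).
#' @return A list with `paths` (list of `state_path` objects), `events` (long
#'   data frame: trace, binding_time, completion_time, pulse), and `stats`
#'   (a `turnover_stats` object, see [turnover_stats()]).
#' @export
simulate_pulsed_remodeling <- function(atp, kinetics, n_traces,
                                       frame_rate = 10, pulse_period = NA,
                                       pulse_t0 = 0, seed = 1, e0 = 0.3) {
  stopifnot(n_traces >= 1)
  t_end <- max(atp$time)
  afun <- .atp_fun(atp)
  lambda_max <- kinetics$k_on * max(atp$free)
  set.seed(seed)
  ev_list <- vector("list", n_traces)
  paths <- vector("list", n_traces)
  for (tr in seq_len(n_traces)) {
    bind <- numeric(0); comp <- numeric(0)
    if (lambda_max > 0) {
      # batch thinning: candidate arrivals of the bounding homogeneous
      # process, kept with probability lambda(t)/lambda_max
      n_cand <- stats::rpois(1, lambda_max * t_end)
      cand <- sort(stats::runif(n_cand, 0, t_end))
      cand <- cand[stats::runif(n_cand) <
                     kinetics$k_on * afun(cand) / lambda_max]
      # gating walk: reject candidates during an ongoing cycle
      busy_until <- 0; nstep <- 0L
      for (tb in cand) {
        if (tb < busy_until) next
        if (nstep >= kinetics$max_steps) break
        h <- .draw_hydrolysis(kinetics$hydrolysis)
        bind <- c(bind, tb); comp <- c(comp, tb + h)
        nstep <- nstep + 1L
        busy_until <- tb + h
      }
    }
    keep <- comp <= t_end
    bind <- bind[keep]; comp <- comp[keep]
    ev_list[[tr]] <- if (length(bind))
      data.frame(trace = tr, binding_time = bind, completion_time = comp)
    else NULL
    paths[[tr]] <- .emit_path(comp, kinetics$step_size, e0,
                              1 / frame_rate, t_end)
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(trace = integer(0), binding_time = numeric(0),
                         completion_time = numeric(0))
  events$pulse <- if (is.na(pulse_period)) rep(NA_integer_, nrow(events))
                  else as.integer(floor((events$binding_time - pulse_t0) /
                                          pulse_period))
  stats <- turnover_stats(events, paths, n_traces,
                          n_pulses = if (is.na(pulse_period)) NA_integer_
                                     else as.integer(ceiling((t_end - pulse_t0) /
                                                               pulse_period)))
  list(paths = paths, events = events, stats = stats)
}

# build a piecewise-constant state path from completion times, merging
# completions that share a camera frame into one compound step
.emit_path <- function(completions, step_size, e0, frame_dt, t_end) {
  if (length(completions) == 0L)
    return(state_path(numeric(0), numeric(0), e0, t_end))
  frame <- floor(completions / frame_dt)
  agg <- vapply(split(seq_along(completions), frame), function(i)
    c(t = max(completions[i]), n = length(i)), numeric(2))
  times <- unname(agg["t", ]); n_merged <- unname(agg["n", ])
  o <- order(times)
  state_path(times[o], step_size * n_merged[o], e0, t_end,
             n_merged = as.integer(n_merged[o]))
}

#' Ground-truth state path of one molecule
#'
#' Piecewise-constant state versus time: the state jumps by `sizes[i]` at
#' `times[i]` starting from `state0`.
#'
#' @param times Strictly increasing event times, s.
#' @param sizes Step sizes (state units) applied at each event time.
#' @param state0 Initial state value.
#' @param t_end End of the observation, s.
#' @param n_merged Optional integer vector: number of elementary turnovers
#'   merged into each emitted step (1 for a simple step).
#' @return An object of class `state_path`.
#' @export
state_path <- function(times, sizes, state0, t_end,
                       n_merged = rep(1L, length(times))) {
  stopifnot(length(times) == length(sizes),
            !is.unsorted(times, strictly = TRUE) || length(times) <= 1L)
  structure(list(times = times, sizes = sizes, state0 = state0,
                 t_end = t_end, n_merged = n_merged,
                 states = state0 + cumsum(c(0, sizes))),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path> %d events over %.3g s, state %.3g -> %.3g\n",
              length(x$times), x$t_end, x$state0,
              x$states[length(x$states)]))
  invisible(x)
}

#' Per-pulse turnover statistics
#'
#' Summarises simulated turnover events: the distribution of turnovers per
#' pulse, the compound-step fraction (fraction of emitted steps merging two
#' or more elementary turnovers) and the processive-trace fraction (traces
#' averaging at least half a step per pulse).
#'
#' @param events Event table with columns `trace`, `completion_time`, `pulse`.
#' @param paths List of `state_path` objects (for merged-step counting).
#' @param n_traces Number of simulated traces.
#' @param n_pulses Number of pulses in the protocol (NA if not pulsed).
#' @return An object of class `turnover_stats`: list with `p0`, `p1`,
#'   `p_multi` (per-pulse turnover-count probabilities; they sum to 1),
#'   `compound_fraction`, `processive_fraction`, `mean_turnovers_per_pulse`
#'   and the per-pulse count table.
#' @export
turnover_stats <- function(events, paths, n_traces, n_pulses = NA) {
  n_merged <- unlist(lapply(paths, function(p) p$n_merged))
  compound <- if (length(n_merged)) mean(n_merged >= 2L) else 0
  if (!is.na(n_pulses) && n_pulses >= 1L) {
    # turnovers per (trace, pulse) cell, including empty cells
    counts <- integer(n_traces * n_pulses)
    if (nrow(events)) {
      ok <- events$pulse >= 0 & events$pulse < n_pulses
      idx <- (events$trace[ok] - 1L) * n_pulses + events$pulse[ok] + 1L
      tab <- table(idx)
      counts[as.integer(names(tab))] <- as.integer(tab)
    }
    p0 <- mean(counts == 0L); p1 <- mean(counts == 1L)
    p_multi <- mean(counts >= 2L)
    per_trace <- rowSums(matrix(counts, n_traces, n_pulses, byrow = TRUE))
    processive <- mean(per_trace / n_pulses >= 0.5)
    mean_per_pulse <- mean(counts)
  } else {
    p0 <- p1 <- p_multi <- processive <- mean_per_pulse <- NA_real_
    counts <- NULL
  }
  structure(list(p0 = p0, p1 = p1, p_multi = p_multi,
                 compound_fraction = compound,
                 processive_fraction = processive,
                 mean_turnovers_per_pulse = mean_per_pulse,
                 counts = counts, n_traces = n_traces, n_pulses = n_pulses),
            class = "turnover_stats")
}

#' @export
print.turnover_stats <- function(x, ...) {
  cat(sprintf(paste0("<turnover_stats> P(0)=%.3f P(1)=%.3f P(>=2)=%.3f ",
                     "compound=%.3f processive=%.3f\n"),
              x$p0, x$p1, x$p_multi, x$compound_fraction,
              x$processive_fraction))
  invisible(x)
}

#' Simulate helicase unwinding driven by a free-ATP time series
#'
#' Each molecule waits an exponential time to unwinding onset with hazard
#' `k_init * [ATP](t) / (km + [ATP](t))`, then unwinds at instantaneous speed
#' `vmax * [ATP](t) / (km + [ATP](t))` (fraction of the duplex per second)
#' times a per-molecule log-normal speed multiplier with mean 1. Unwinding
#' completes when the integrated progress reaches 1; the donor-labelled
#' strand is then lost.
#'
#' @param atp Data frame `time`, `free` (uM); constant concentrations can be
#'   passed as a two-row frame.
#' @param kinetics A [helicase_kinetics()].
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @param dt Integration step for progress accumulation, s.
#' @return A data frame, one row per molecule: `onset` (s, NA if none),
#'   `duration` (s, NA if not completed within the record), `completed`
#'   (logical), `rate` (1/duration, s^-1, NA if not completed).
#' @export
simulate_unwinding <- function(atp, kinetics, n_molecules, seed = 1,
                               dt = 0.05) {
  t_end <- max(atp$time)
  afun <- .atp_fun(atp)
  grid <- seq(0, t_end, by = dt)
  mm <- afun(grid) / (kinetics$km + afun(grid))
  # cumulative onset hazard and cumulative speed on the grid
  cum_haz <- c(0, cumsum(kinetics$k_init * (head(mm, -1) + tail(mm, -1)) / 2 * dt))
  cum_speed <- c(0, cumsum(kinetics$vmax * (head(mm, -1) + tail(mm, -1)) / 2 * dt))
  set.seed(seed)
  onset <- duration <- rate <- rep(NA_real_, n_molecules)
  completed <- logical(n_molecules)
  sdlog <- sqrt(log(1 + kinetics$cv_speed^2))
  for (i in seq_len(n_molecules)) {
    u <- stats::rexp(1)
    if (u >= cum_haz[length(cum_haz)]) next  # no onset within record
    onset[i] <- stats::approx(cum_haz, grid, xout = u, ties = "ordered")$y
    mult <- if (kinetics$cv_speed > 0)
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
    # progress from onset: mult * (cum_speed(t) - cum_speed(onset)) = 1
    target <- stats::approx(grid, cum_speed, xout = onset[i],
                            ties = "ordered")$y + 1 / mult
    if (target <= cum_speed[length(cum_speed)]) {
      t_done <- stats::approx(cum_speed, grid, xout = target,
                              ties = "ordered")$y
      duration[i] <- t_done - onset[i]
      completed[i] <- TRUE
      rate[i] <- 1 / duration[i]
    }
  }
  data.frame(molecule = seq_len(n_molecules), onset = onset,
             duration = duration, completed = completed, rate = rate)
}

#' Calibrate the remodeler binding rate for a processive pulsed regime
#'
#' Tunes `k_on` so that the mean number of turnovers in the first pulse
#' cycle of the reference pulsed protocol reaches a target (default 1:
#' every pulse typically drives one elementary step, the definition of a
#' processive single-turnover regime used for the 90-ms pulse condition).
#' The first cycle is used so the processivity cap, which molecules hit in
#' later pulses, does not bias the calibration. Monotone bisection on
#' Monte-Carlo estimates.
#'
#' @param atp Free-ATP series of the reference (90-ms) pulsed protocol.
#' @param kinetics A [remodeler_kinetics()] whose `k_on` is the starting
#'   point.
#' @param pulse_period Pulse period, s.
#' @param target Mean turnovers per pulse to reach (default 1).
#' @param n_traces Monte-Carlo traces per evaluation (default 200).
#' @param seed Integer seed.
#' @param tol Relative tolerance on the achieved mean (default 0.05).
#' @return The input `remodeler_kinetics` with calibrated `k_on`.
#' @export
calibrate_k_on <- function(atp, kinetics, pulse_period, target = 1,
                           n_traces = 200, seed = 1, tol = 0.05) {
  # only the first pulse cycle matters for the calibration metric
  t0 <- if (any(atp$free > 0)) atp$time[which(atp$free > 0)[1]] else 0
  atp1 <- atp[atp$time <= t0 + pulse_period, , drop = FALSE]
  eval_mean <- function(k_on) {
    k <- kinetics; k$k_on <- k_on
    sim <- simulate_pulsed_remodeling(atp1, k, n_traces,
                                      pulse_period = pulse_period,
                                      pulse_t0 = t0, seed = seed)
    sum(sim$events$pulse == 0L) / n_traces
  }
  lo <- kinetics$k_on / 64; hi <- kinetics$k_on * 64
  while (eval_mean(hi) < target && hi < kinetics$k_on * 1e4) hi <- hi * 4
  while (eval_mean(lo) > target && lo > kinetics$k_on * 1e-4) lo <- lo / 4
  for (it in 1:30) {
    mid <- sqrt(lo * hi)
    m <- eval_mean(mid)
    if (abs(m - target) <= tol * target) { kinetics$k_on <- mid; return(kinetics) }
    if (m < target) lo <- mid else hi <- mid
  }
  kinetics$k_on <- sqrt(lo * hi)
  kinetics
}

#' Turnover statistics across pulse durations
#'
#' Re-simulates the uncaging chemistry and the gated stochastic stepping for
#' each pulse duration and tabulates the single-turnover statistics,
#' including the residual post-pulse free NTP carried by the chemistry model
#' into the binding window.
#'
#' @param kinetics A [remodeler_kinetics()].
#' @param photolysis,scavenger Parameter objects for the uncaging chemistry.
#' @param caged0 Caged reservoir, uM.
#' @param power_density Uncaging pulse power density, W cm^-2.
#' @param durations Pulse durations to test, s.
#' @param period Pulse period, s (should exceed the longest hydrolysis time).
#' @param n_pulses Pulses per simulated trace (default 8).
#' @param n_mc Monte-Carlo traces per duration (default 500).
#' @param seed Integer seed.
#' @param frame_rate Camera frame rate, Hz.
#' @return Data frame, one row per duration: `duration`, `p0`, `p1`,
#'   `p_multi`, `compound_fraction`, `processive_fraction`,
#'   `mean_turnovers_per_pulse`, `peak_atp` (uM).
#' @export
pulse_regime_table <- function(kinetics, photolysis, scavenger, caged0,
                               power_density, durations, period,
                               n_pulses = 8L, n_mc = 500L, seed = 1,
                               frame_rate = 10) {
  stopifnot(all(durations < period))
  h <- kinetics$hydrolysis
  t_max <- switch(h$dist, uniform = h$max, exponential = 3 * h$mean,
                  fixed = h$value)
  if (period <= t_max)
    warning("pulse period does not exceed the hydrolysis time; turnovers can straddle pulses")
  rows <- lapply(seq_along(durations), function(i) {
    d <- durations[i]
    prot <- illumination_protocol(power_density,
                                  pulses = list(duration = d, period = period,
                                                n = n_pulses))
    fld <- simulate_well_mixed(prot, photolysis, scavenger, caged0,
                               dt = min(d / 20, 0.02))
    atp <- free_ntp_series(fld)
    sim <- simulate_pulsed_remodeling(atp, kinetics, n_mc,
                                      frame_rate = frame_rate,
                                      pulse_period = period,
                                      seed = seed + i)
    s <- sim$stats
    data.frame(duration = d, p0 = s$p0, p1 = s$p1, p_multi = s$p_multi,
               compound_fraction = s$compound_fraction,
               processive_fraction = s$processive_fraction,
               mean_turnovers_per_pulse = s$mean_turnovers_per_pulse,
               peak_atp = max(atp$free))
  })
  do.call(rbind, rows)
}

#' Serialise state paths as a long event table
#'
#' @param paths List of `state_path` objects.
#' @return Data frame `trace`, `time`, `state`, `step_size`, `n_merged`.
#' @export
paths_to_table <- function(paths) {
  rows <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(p$times) == 0L) return(NULL)
    data.frame(trace = i, time = p$times,
               state = p$states[-1L], step_size = p$sizes,
               n_merged = p$n_merged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trace = integer(0), time = numeric(0),
                      state = numeric(0), step_size = numeric(0),
                      n_merged = integer(0))
  out
}
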