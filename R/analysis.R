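#' Channel-correction parameters
#'
#' @param alpha Direct-excitation correction: fraction of the
#'   direct-excitation acceptor signal appearing in the FRET channel.
#' @param beta Donor-into-acceptor bleedthrough fraction.
#' @param gamma Scale applied to the donor channel to equalise quantum
#'   yields/detection efficiencies.
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(alpha = 0, beta = 0, gamma = 1) {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1, gamma > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "correction_params")
}

#' Correction parameters matching an optical model
#'
#' The exact inverse of the [synthesize_fret_trace()] forward model.
#'
#' @param om An [optical_model()].
#' @return A [correction_params()].
#' @export
correction_from_optical <- function(om) {
  correction_params(alpha = om$alpha, beta = om$beta, gamma = 1 / om$gamma_d)
}

#' Apply channel corrections and compute FRET
#'
#' Corrects the sensitised-emission channel for donor bleedthrough and
#' acceptor direct excitation, scales the donor channel, and computes
#' `E = acceptor' / (acceptor' + donor')`. Frames whose corrected total
#' intensity falls below the noise floor (post-bleach) are masked rather
#' than errored; E values outside [-0.1, 1.1] are clamped and flagged.
#'
#' @param traces A `trace_set` from [synthesize_trace_set()] or a long data
#'   frame with columns `trace`, `time`, `I_DD`, `I_DA`, `I_AA`.
#' @param p A [correction_params()].
#' @param noise_floor Absolute total-intensity threshold below which frames
#'   are masked; default 0.25 of the median corrected total.
#' @return Long data frame `trace`, `frame`, `time`, `donor`, `acceptor`,
#'   `fret`, `masked`, `flagged`.
#' @export
correct_channels <- function(traces, p, noise_floor = NULL) {
  fr <- if (inherits(traces, "trace_set")) traces$frames else traces
  need <- c("trace", "time", "I_DD", "I_DA", "I_AA")
  if (!all(need %in% names(fr)))
    stop("traces must provide columns ", paste(need, collapse = ", "))
  acceptor <- fr$I_DA - p$beta * fr$I_DD - p$alpha * fr$I_AA
  donor <- p$gamma * fr$I_DD
  total <- acceptor + donor
  if (is.null(noise_floor)) noise_floor <- 0.25 * stats::median(total)
  masked <- total < noise_floor
  e <- ifelse(masked, NA_real_, acceptor / total)
  flagged <- !masked & (e < -0.1 | e > 1.1)
  e <- pmin(pmax(e, -0.1), 1.1)
  data.frame(trace = fr$trace,
             frame = if ("frame" %in% names(fr)) fr$frame else
               stats::ave(fr$time, fr$trace, FUN = seq_along),
             time = fr$time, donor = donor, acceptor = acceptor,
             fret = e, masked = masked, flagged = flagged)
}

# Otsu-style threshold on a continuous sample: maximise between-class
# variance over candidate cuts
.otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(NA_real_)
  cuts <- (x[-n] + x[-1]) / 2
  csum <- cumsum(x)[-n]
  k <- seq_len(n - 1L)
  m1 <- csum / k
  m2 <- (csum[n - 1L] + x[n] - csum) / (n - k)
  bcv <- k * (n - k) * (m1 - m2)^2
  cuts[which.max(bcv)]
}

#' Acceptor direct-vs-sensitised intensity ratio and unwinding classification
#'
#' Computes, per molecule, the ratio of the mean sensitised acceptor
#' intensity (donor excitation) to the mean direct-excitation acceptor
#' intensity over an early and a late window. Because the donor-labelled
#' strand dissociates on unwinding completion, the sensitised signal is lost
#' while direct excitation persists, so the late-window ratio separates
#' intact from unwound molecules. Molecules without detectable acceptor
#' (mean direct signal below `aa_min`) are excluded. The class boundary is
#' the Otsu-style threshold on the pooled log-ratios.
#'
#' @param traces A `trace_set` or long frame with `trace`, `I_DA`, `I_AA`.
#' @param window Number of frames in the early/late windows (default 20).
#' @param aa_min Minimum mean direct-excitation acceptor signal for a
#'   molecule to be included; default 5 times the optical-model AA noise if
#'   available, otherwise 0.
#' @return List with `per_molecule` (data frame: `trace`, `ratio_before`,
#'   `ratio_after`, `unwound`, `excluded`), `threshold` (on the ratio scale)
#'   and `fraction_unwound`.
#' @export
cy5_ratio <- function(traces, window = 20L, aa_min = NULL) {
  fr <- if (inherits(traces, "trace_set")) traces$frames else traces
  if (is.null(aa_min))
    aa_min <- if (inherits(traces, "trace_set"))
      5 * traces$om$sigma[["AA"]] else 0
  split_fr <- split(fr, fr$trace)
  rows <- lapply(split_fr, function(d) {
    n <- nrow(d)
    w <- min(window, floor(n / 2))
    head_i <- seq_len(w); tail_i <- (n - w + 1L):n
    aa_all <- mean(d$I_AA)
    data.frame(trace = d$trace[1],
               ratio_before = mean(d$I_DA[head_i]) / mean(d$I_AA[head_i]),
               ratio_after = mean(d$I_DA[tail_i]) / mean(d$I_AA[tail_i]),
               excluded = aa_all < aa_min)
  })
  pm <- do.call(rbind, rows)
  ok <- !pm$excluded
  lr <- log(pmax(c(pm$ratio_before[ok], pm$ratio_after[ok]), 1e-6))
  thr <- exp(.otsu_threshold(lr))
  pm$unwound <- ifelse(ok, pm$ratio_after < thr, NA)
  list(per_molecule = pm, threshold = thr,
       fraction_unwound = mean(pm$unwound[ok]))
}

#' Per-trace unwinding rates from corrected FRET traces
#'
#' The unwinding rate of a molecule is the reciprocal of the transit time
#' from the departure from the high-FRET level to donor-strand loss (the
#' start of the final masked run, where both donor-excited channels have
#' fallen to the noise floor). Departure is detected as the first frame with
#' `E < e_high - delta` and then corrected back to the `e_high` crossing by
#' local linear extrapolation, so that for a steady FRET decay the transit
#' equals the full unwinding interval. Traces that never complete are
#' excluded and counted.
#'
#' @param corrected Output of [correct_channels()].
#' @param e_high High-FRET starting level; `NULL` to estimate per trace as
#'   the median of the first 10 unmasked frames.
#' @param delta Departure threshold below `e_high` (default 0.1).
#' @return An object of class `rate_estimate`: list with `per_trace` (data
#'   frame `trace`, `departure`, `loss`, `rate`), `mean`, `sem`, `n`,
#'   `n_excluded`.
#' @export
unwinding_rate <- function(corrected, e_high = NULL, delta = 0.1) {
  rows <- lapply(split(corrected, corrected$trace), function(d) {
    d <- d[order(d$time), ]
    unmasked <- which(!d$masked)
    if (length(unmasked) < 10L)
      return(data.frame(trace = d$trace[1], departure = NA, loss = NA,
                        rate = NA))
    eh <- if (is.null(e_high))
      stats::median(d$fret[unmasked[1:10]]) else e_high
    dep_i <- which(!d$masked & d$fret < eh - delta)
    # donor loss = start of the trailing masked run
    loss_i <- if (d$masked[nrow(d)]) max(unmasked) + 1L else NA_integer_
    if (!length(dep_i) || is.na(loss_i) || d$time[loss_i] <= d$time[dep_i[1]])
      return(data.frame(trace = d$trace[1], departure = NA, loss = NA,
                        rate = NA))
    dep <- d$time[dep_i[1]]; loss <- d$time[loss_i]
    # extrapolate the crossing back to e_high using the local decay slope
    seg <- d[!d$masked & d$time >= dep &
               d$time <= min(dep + (loss - dep) / 2, loss), ]
    if (nrow(seg) >= 3L) {
      sl <- stats::coef(stats::lm(fret ~ time, data = seg))[2]
      if (is.finite(sl) && sl < 0)
        dep <- max(dep - (eh - d$fret[dep_i[1]]) / (-sl), d$time[1])
    }
    if (loss <= dep)
      return(data.frame(trace = d$trace[1], departure = NA, loss = NA,
                        rate = NA))
    data.frame(trace = d$trace[1], departure = dep, loss = loss,
               rate = 1 / (loss - dep))
  })
  pt <- do.call(rbind, rows)
  ok <- is.finite(pt$rate)
  r <- pt$rate[ok]
  structure(list(per_trace = pt, mean = mean(r),
                 sem = stats::sd(r) / sqrt(length(r)), n = length(r),
                 n_excluded = sum(!ok)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3g +/- %.2g s^-1 (n = %d, %d excluded)\n",
              x$mean, x$sem, x$n, x$n_excluded))
  invisible(x)
}

#' Michaelis-Menten fit of a titration curve
#'
#' Fits `rate = vmax * conc / (km + conc)` to aggregate rates versus
#' substrate concentration.
#'
#' @param conc Substrate concentrations, uM.
#' @param rate Measured rates, s^-1.
#' @return List with `vmax`, `km` and the underlying `nls` fit.
#' @export
fit_mm_titration <- function(conc, rate) {
  stopifnot(length(conc) == length(rate), length(conc) >= 3L)
  d <- data.frame(conc = conc, rate = rate)
  start <- list(vmax = max(rate) * 1.2,
                km = conc[which.min(abs(rate - max(rate) / 2))])
  fit <- stats::nls(rate ~ vmax * conc / (km + conc), data = d,
                    start = start, algorithm = "port",
                    lower = c(vmax = 1e-9, km = 1e-9))
  co <- stats::coef(fit)
  list(vmax = unname(co["vmax"]), km = unname(co["km"]), fit = fit)
}

#' Map uncaging power to effective free-NTP concentration
#'
#' Matches the rate measured at each uncaging power against a reference
#' rate-versus-concentration titration: the effective concentration at a
#' power is the concentration at which the reference curve attains the same
#' rate (monotone linear interpolation). Rates outside the reference range
#' are flagged and not extrapolated.
#'
#' @param rate_vs_power Data frame `power` (W cm^-2), `rate` (s^-1), rates
#'   monotone non-decreasing in power.
#' @param rate_vs_atp Data frame `atp` (uM), `rate` (s^-1), rates monotone
#'   non-decreasing in atp.
#' @return Data frame `power`, `rate`, `effective_atp` (uM, NA when
#'   flagged), `flagged`.
#' @export
effective_atp_mapping <- function(rate_vs_power, rate_vs_atp) {
  rp <- rate_vs_power[order(rate_vs_power$power), ]
  ra <- rate_vs_atp[order(rate_vs_atp$atp), ]
  if (is.unsorted(rp$rate)) stop("rate_vs_power rates must be monotone non-decreasing")
  if (is.unsorted(ra$rate)) stop("rate_vs_atp rates must be monotone non-decreasing")
  lo <- min(ra$rate); hi <- max(ra$rate)
  flagged <- rp$rate < lo | rp$rate > hi
  eff <- rep(NA_real_, nrow(rp))
  if (any(!flagged))
    eff[!flagged] <- stats::approx(ra$rate, ra$atp, xout = rp$rate[!flagged],
                                   ties = "ordered")$y
  data.frame(power = rp$power, rate = rp$rate, effective_atp = eff,
             flagged = flagged)
}

#' AFS elongation-rate extraction
#'
#' Smooths a bead-position trace with a 10-s running-median filter followed
#' by Savitzky-Golay filtering (3-s window, polynomial order 3), then
#' computes average elongation rates over consecutive 6.25-s windows within
#' the 30-s intervals before and after each switching-on of the uncaging
#' laser (slope of the smoothed position, converted to bp/s).
#'
#' @param trace Data frame `time` (s, uniform sampling), `position` (nm).
#' @param uncaging_windows Two-column matrix/data frame of on-window start
#'   and end times, s.
#' @param rise_per_bp Tether-length change per transcribed bp, nm
#'   (default 0.34); elongation rates are `-slope / rise_per_bp`.
#' @param median_window Running-median span, s (default 10).
#' @param sg_window Savitzky-Golay span, s (default 3).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param rate_window Rate-averaging window, s (default 6.25).
#' @param interval Length of the before/after intervals around each laser
#'   switch-on, s (default 30).
#' @return List with `smoothed` (data frame `time`, `position`), `rates`
#'   (data frame `t_mid`, `rate` bp/s, `phase` "on"/"off", `switch` index)
#'   and the two rate histogms' samples split by phase.
#' @export
afs_elongation <- function(trace, uncaging_windows, rise_per_bp = 0.34,
                           median_window = 10, sg_window = 3, sg_order = 3,
                           rate_window = 6.25, interval = 30) {
  t <- trace$time; x <- trace$position
  dt <- stats::median(diff(t))
  span <- max(t) - min(t)
  if (span < max(median_window, sg_window))
    stop("trace shorter than the filter span")
  k_med <- max(3L, 2L * floor(median_window / dt / 2) + 1L)
  if (k_med > length(x)) stop("trace shorter than the median filter span")
  sm <- stats::runmed(x, k_med, endrule = "median")
  n_sg <- max(sg_order + 2L, 2L * floor(sg_window / dt / 2) + 1L)
  if (n_sg %% 2L == 0L) n_sg <- n_sg + 1L
  sm <- signal::sgolayfilt(sm, p = sg_order, n = n_sg)
  uw <- as.matrix(uncaging_windows)
  rate_rows <- list()
  for (s in seq_len(nrow(uw))) {
    t_on <- uw[s, 1]
    for (phase in c("off", "on")) {
      t0 <- if (phase == "off") t_on - interval else t_on
      t1 <- t0 + interval
      starts <- seq(t0, t1 - rate_window, by = rate_window)
      for (ws in starts) {
        sel <- t >= ws & t < ws + rate_window
        if (sum(sel) < 3L) next
        slope <- stats::coef(stats::lm(sm[sel] ~ t[sel]))[2]
        rate_rows[[length(rate_rows) + 1L]] <-
          data.frame(t_mid = ws + rate_window / 2,
                     rate = -unname(slope) / rise_per_bp,
                     phase = phase, switch = s)
      }
    }
  }
  rates <- do.call(rbind, rate_rows)
  list(smoothed = data.frame(time = t, position = sm), rates = rates,
       on_rates = rates$rate[rates$phase == "on"],
       off_rates = rates$rate[rates$phase == "off"])
}
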