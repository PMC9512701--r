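#' Optical model for synthetic smFRET traces
#'
#' Detection parameters of the three-channel smFRET forward model:
#' donor-excitation donor (I_DD), donor-excitation acceptor (I_DA) and
#' direct-excitation acceptor (I_AA) channels with crosstalk, photobleaching
#' and additive Gaussian noise.
#'
#' @param beta Bleedthrough of the donor signal into the acceptor channel
#'   (fraction in [0, 1)).
#' @param alpha Direct excitation of the acceptor by the donor laser,
#'   expressed as a fraction of the direct-excitation acceptor signal.
#' @param gamma_d Detection/quantum-yield scale of the donor channel relative
#'   to the acceptor channel.
#' @param sigma Additive Gaussian noise s.d. per channel, signal units
#'   (scalar or length-3 for DD/DA/AA).
#' @param bleach_half_life Named numeric: photobleaching half-lives in s for
#'   `donor` and `acceptor` under the active lasers (defaults 180 s and 90 s,
#'   the Cy3/Cy5 values at 10 W cm^-2).
#' @param frame_rate Camera frame rate, Hz.
#' @param aa_interleave Record one direct-excitation acceptor frame every
#'   `aa_interleave` donor-excitation frames (1 = parallel recording;
#'   default 10). Between measurements the last I_AA value is carried
#'   forward.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(beta = 0.1, alpha = 0.05, gamma_d = 1,
                          sigma = 30,
                          bleach_half_life = c(donor = 180, acceptor = 90),
                          frame_rate = 10, aa_interleave = 10L) {
  stopifnot(beta >= 0, beta < 1, alpha >= 0, alpha < 1, gamma_d > 0,
            all(sigma >= 0), all(bleach_half_life > 0), frame_rate > 0,
            aa_interleave >= 1)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  structure(list(beta = beta, alpha = alpha, gamma_d = gamma_d,
                 sigma = stats::setNames(sigma, c("DD", "DA", "AA")),
                 bleach_half_life = bleach_half_life,
                 frame_rate = frame_rate,
                 aa_interleave = as.integer(aa_interleave)),
            class = "optical_model")
}

#' Ideal FRET series from a ground-truth state path
#'
#' Samples the piecewise-constant state path at frame times, optionally
#' through a state-to-FRET mapping. For unwinding-type paths use
#' [unwinding_fret()] instead (monotone linear decay).
#'
#' @param path A [state_path()] whose states are FRET values (or mapped to
#'   FRET by `mapping`).
#' @param frame_rate Sampling rate, Hz.
#' @param mapping Function applied to state values to obtain FRET in [0, 1]
#'   (default identity). Must return finite values for every state.
#' @return Data frame `time`, `fret`.
#' @export
fret_from_state <- function(path, frame_rate = 10, mapping = identity) {
  times <- seq(0, path$t_end, by = 1 / frame_rate)
  e <- mapping(path$states)
  if (any(!is.finite(e))) stop("state-to-FRET mapping left states unmapped")
  idx <- findInterval(times, path$times) + 1L
  data.frame(time = times, fret = e[idx])
}

#' Ideal FRET series for a helicase-unwinding molecule
#'
#' FRET stays at `e_high` until `onset`, decays linearly to `e_low` over
#' `duration`, after which the donor strand is lost (flagged for the
#' synthesiser; FRET is undefined past completion).
#'
#' @param onset Unwinding onset time, s (NA for a molecule that never
#'   initiates).
#' @param duration Unwinding duration, s (NA if not completed).
#' @param e_high,e_low FRET before and at the end of unwinding.
#' @param t_end Record length, s.
#' @param frame_rate Sampling rate, Hz.
#' @return Data frame `time`, `fret`, plus attribute `donor_loss_time`
#'   (NA if the strand is retained).
#' @export
unwinding_fret <- function(onset, duration, e_high, e_low, t_end,
                           frame_rate = 10) {
  times <- seq(0, t_end, by = 1 / frame_rate)
  if (is.na(onset)) {
    fret <- rep(e_high, length(times)); loss <- NA_real_
  } else if (is.na(duration)) {
    # started but did not finish: extrapolate the linear decay to record end
    fret <- pmax(e_low,
                 e_high - (e_high - e_low) * pmax(times - onset, 0) /
                   (t_end - onset + .Machine$double.eps))
    loss <- NA_real_
  } else {
    frac <- pmin(pmax((times - onset) / duration, 0), 1)
    fret <- e_high - (e_high - e_low) * frac
    loss <- onset + duration
  }
  structure(data.frame(time = times, fret = fret), donor_loss_time = loss)
}

#' Synthesise a three-channel smFRET trace from an ideal FRET series
#'
#' Forward model per frame: `I_DD = gamma_d * (1 - E) * I_tot`,
#' `I_DA = E * I_tot + beta * I_DD + alpha * I_AA`, with `I_AA` the
#' direct-excitation acceptor signal. Stochastic photobleaching times are
#' drawn from exponential survival with the configured half-lives. After
#' donor bleach (or donor-strand loss) I_DD and I_DA drop to the noise
#' floor; after acceptor bleach FRET is lost channel-wise (full donor signal,
#' no sensitised emission, no direct acceptor signal). Gaussian noise is
#' added per channel.
#'
#' @param ideal Data frame `time`, `fret` (e.g. from [fret_from_state()]),
#'   optionally carrying a `donor_loss_time` attribute.
#' @param om An [optical_model()].
#' @param total_intensity Total photon signal I_tot per frame (a.u.).
#' @param aa_intensity Direct-excitation acceptor signal (a.u.); default
#'   `0.8 * total_intensity`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param bleaching If `FALSE`, photobleaching is disabled.
#' @return Data frame `frame`, `time`, `I_DD`, `I_DA`, `I_AA`, `aa_measured`
#'   with attributes `truth` (list: ideal fret, donor_bleach, acceptor_bleach,
#'   donor_loss_time).
#' @export
synthesize_fret_trace <- function(ideal, om, total_intensity = 1000,
                                  aa_intensity = 0.8 * total_intensity,
                                  seed = NULL, bleaching = TRUE) {
  stopifnot(total_intensity > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- ideal$time; e <- ideal$fret
  n <- length(t)
  loss <- attr(ideal, "donor_loss_time")
  if (is.null(loss)) loss <- NA_real_
  if (bleaching) {
    t_d <- stats::rexp(1, log(2) / om$bleach_half_life[["donor"]])
    t_a <- stats::rexp(1, log(2) / om$bleach_half_life[["acceptor"]])
  } else t_d <- t_a <- Inf
  donor_dark <- t >= t_d | (!is.na(loss) & t >= loss)
  acceptor_dark <- t >= t_a
  i_dd <- om$gamma_d * (1 - e) * total_intensity
  i_aa <- rep(aa_intensity, n)
  # acceptor bleach: no FRET acceptor -> donor recovers fully, I_AA dark
  i_dd[acceptor_dark & !donor_dark] <- om$gamma_d * total_intensity
  i_aa[acceptor_dark] <- 0
  i_da <- e * total_intensity
  i_da[acceptor_dark] <- 0
  # donor bleach / strand loss kills donor-excited channels, I_AA persists
  i_dd[donor_dark] <- 0
  da_sens <- i_da; da_sens[donor_dark] <- 0
  i_da <- da_sens + om$beta * i_dd + om$alpha * i_aa
  if (om$sigma[["DD"]] > 0) i_dd <- i_dd + stats::rnorm(n, 0, om$sigma[["DD"]])
  if (om$sigma[["DA"]] > 0) i_da <- i_da + stats::rnorm(n, 0, om$sigma[["DA"]])
  if (om$sigma[["AA"]] > 0) i_aa <- i_aa + stats::rnorm(n, 0, om$sigma[["AA"]])
  aa_measured <- (seq_len(n) - 1L) %% om$aa_interleave == 0L
  if (om$aa_interleave > 1L) {
    # carry the last measured direct-excitation frame forward
    idx <- cummax(ifelse(aa_measured, seq_len(n), 0L))
    idx[idx == 0L] <- 1L
    i_aa <- i_aa[idx]
  }
  out <- data.frame(frame = seq_len(n), time = t, I_DD = i_dd, I_DA = i_da,
                    I_AA = i_aa, aa_measured = aa_measured)
  attr(out, "truth") <- list(fret = e, donor_bleach = t_d,
                             acceptor_bleach = t_a, donor_loss_time = loss)
  out
}

#' Synthesise a set of smFRET traces with ground-truth annotations
#'
#' @param ideals List of ideal FRET series (see [synthesize_fret_trace()]).
#' @param om An [optical_model()].
#' @param seed Integer seed; per-trace seeds are derived from it.
#' @param ... Passed to [synthesize_fret_trace()].
#' @return An object of class `trace_set`: list with `frames` (long data
#'   frame with `trace` column), `annotations` (one row per trace:
#'   donor/acceptor bleach times, donor-loss time) and `truth` (list of
#'   ideal FRET vectors).
#' @export
synthesize_trace_set <- function(ideals, om, seed = 1, ...) {
  set.seed(seed)
  frames <- vector("list", length(ideals))
  ann <- vector("list", length(ideals))
  truth <- vector("list", length(ideals))
  for (i in seq_along(ideals)) {
    tr <- synthesize_fret_trace(ideals[[i]], om, seed = NULL, ...)
    tru <- attr(tr, "truth")
    tr$trace <- i
    frames[[i]] <- tr
    ann[[i]] <- data.frame(trace = i, donor_bleach = tru$donor_bleach,
                           acceptor_bleach = tru$acceptor_bleach,
                           donor_loss_time = tru$donor_loss_time)
    truth[[i]] <- tru$fret
  }
  structure(list(frames = do.call(rbind, frames),
                 annotations = do.call(rbind, ann),
                 truth = truth, om = om),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d traces, %d frames total\n",
              nrow(x$annotations), nrow(x$frames)))
  invisible(x)
}

#' Elongation profile (transcribed base pairs vs time) from uncaging windows
#'
#' Constant elongation rate inside the uncaging windows, zero outside.
#'
#' @param windows Two-column matrix or data frame of window start/end times, s.
#' @param rate Elongation rate inside windows, bp s^-1.
#' @param t_end Record length, s.
#' @param dt Sampling interval, s.
#' @return Data frame `time`, `bp` (monotone non-decreasing).
#' @export
elongation_profile <- function(windows, rate, t_end, dt = 0.02) {
  times <- seq(0, t_end, by = dt)
  windows <- as.matrix(windows)
  active <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows)))
    active <- active | (times >= windows[i, 1] & times < windows[i, 2])
  bp <- cumsum(c(0, rate * active[-length(active)] * dt))
  data.frame(time = times, bp = bp)
}

#' Synthesise an AFS bead-position trace from an elongation profile
#'
#' Bead position decreases by `rise_per_bp` per transcribed base pair
#' (transcription pulls the bead toward the surface), with optional linear
#' drift and additive Gaussian tracking noise.
#'
#' @param elongation Data frame `time`, `bp`, monotone non-decreasing
#'   (e.g. from [elongation_profile()]).
#' @param rise_per_bp Tether-length change per transcribed bp, nm
#'   (default 0.34).
#' @param sigma Tracking noise s.d., nm.
#' @param drift Linear drift rate, nm s^-1 (default 0), or a function of
#'   time returning nm.
#' @param baseline Starting position, nm.
#' @param seed Integer seed (`NULL` to use current RNG state).
#' @return Data frame `time`, `position` (nm) with attribute `truth`
#'   (noise-free position).
#' @export
synthesize_afs_trace <- function(elongation, rise_per_bp = 0.34, sigma = 5,
                                 drift = 0, baseline = 0, seed = NULL) {
  if (is.unsorted(elongation$bp)) stop("elongation profile must be monotone non-decreasing")
  if (!is.null(seed)) set.seed(seed)
  t <- elongation$time
  dr <- if (is.function(drift)) drift(t) else drift * t
  clean <- baseline - elongation$bp * rise_per_bp + dr
  pos <- clean + if (sigma > 0) stats::rnorm(length(t), 0, sigma) else 0
  structure(data.frame(time = t, position = pos), truth = clean)
}
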