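# Physical constants (SI)
.AVOGADRO <- 6.02214076e23
.PLANCK   <- 6.62607015e-34   # J s
.C_LIGHT  <- 2.99792458e8     # m s^-1

#' Illumination protocol for an uncaging experiment
#'
#' Describes the uncaging laser: power density, wavelength, the illuminated
#' rectangular spot, and the temporal pattern (continuous or a pulse train).
#' Coordinates are spot-centred, in micrometres, with the spot edges at
#' +/- width/2 and +/- height/2.
#'
#' @param power_density Uncaging power density in W cm^-2.
#' @param wavelength Uncaging wavelength in nm (near-UV, 300-450 nm).
#' @param spot Numeric length-2, spot width x height in um. Use `Inf` for
#'   uniform illumination of the whole domain.
#' @param pulses `NULL` for continuous illumination, or a list with elements
#'   `duration` (on-time per pulse, s), `period` (pulse-to-pulse interval, s),
#'   `n` (number of pulses) and optional `t0` (baseline delay before the
#'   first pulse, s; default 0). Pulse k is on during
#'   `[t0 + (k-1)*period, t0 + (k-1)*period + duration)`.
#' @param total_duration Total simulated/observed time in s. Defaults to
#'   `pulses$n * pulses$period` for pulsed protocols and must be given for
#'   continuous ones.
#' @return An object of class `illumination_protocol`.
#' @examples
#' illumination_protocol(100, pulses = list(duration = 0.09, period = 8, n = 10))
#' @export
illumination_protocol <- function(power_density, wavelength = 360,
                                  spot = c(180, 60), pulses = NULL,
                                  total_duration = NULL) {
  stopifnot(is.numeric(power_density), length(power_density) == 1L,
            power_density >= 0, is.finite(power_density))
  if (wavelength < 300 || wavelength > 450)
    stop("wavelength must lie in the near-UV uncaging band (300-450 nm)")
  if (length(spot) != 2L || any(spot <= 0))
    stop("spot must be positive width x height in um")
  if (!is.null(pulses)) {
    stopifnot(is.list(pulses))
    if (is.null(pulses$n)) pulses$n <- 1L
    if (is.null(pulses$t0)) pulses$t0 <- 0
    if (pulses$duration <= 0 || pulses$period <= 0 || pulses$t0 < 0)
      stop("pulse duration and period must be positive, t0 non-negative")
    if (pulses$duration > pulses$period)
      stop("pulse duration cannot exceed the period")
    if (is.null(total_duration))
      total_duration <- pulses$t0 + pulses$n * pulses$period
    if (total_duration < pulses$t0 + (pulses$n - 1) * pulses$period +
          pulses$duration)
      stop("total_duration shorter than the pulse train")
  } else if (is.null(total_duration)) {
    stop("total_duration must be given for continuous protocols")
  }
  structure(list(power_density = power_density, wavelength = wavelength,
                 spot = as.numeric(spot), pulses = pulses,
                 total_duration = total_duration),
            class = "illumination_protocol")
}

#' Is the uncaging laser on at time t?
#'
#' @param protocol An [illumination_protocol()].
#' @param t Times in s (vectorised).
#' @return Instantaneous power density (W cm^-2) at each time.
#' @export
illumination_at <- function(protocol, t) {
  if (is.null(protocol$pulses)) {
    on <- t >= 0 & t < protocol$total_duration
  } else {
    p <- protocol$pulses
    tp <- t - p$t0
    phase <- tp - floor(tp / p$period) * p$period
    on <- phase < p$duration & tp >= 0 & tp < p$n * p$period
  }
  protocol$power_density * as.numeric(on)
}

# boundaries of constant-illumination segments covering [0, total_duration]
.protocol_segments <- function(protocol) {
  td <- protocol$total_duration
  if (is.null(protocol$pulses)) return(sort(unique(c(0, td))))
  p <- protocol$pulses
  starts <- p$t0 + (seq_len(p$n) - 1) * p$period
  b <- sort(unique(c(0, starts, pmin(starts + p$duration, td), td)))
  b[b <= td]
}

#' Photolysis (uncaging) parameters for a caged NTP
#'
#' Molar absorptivity and photolysis quantum yield of the cage at the uncaging
#' wavelength. The printed values for DMNPE-type cages vary between sources;
#' the defaults here are literature-style placeholders and should be treated
#' as calibration parameters. The `efficiency` factor absorbs everything the
#' plain photochemistry does not capture (notably the dilution of uncaging
#' that occurs only in the thin evanescent excitation layer into the full
#' flow-cell depth); calibrate it with [calibrate_photolysis()] against a
#' measured effective concentration.
#'
#' @param molar_absorptivity Decadic molar absorptivity, M^-1 cm^-1.
#' @param quantum_yield Photolysis quantum yield in (0, 1].
#' @param efficiency Dimensionless scale in (0, 1] applied to the photolysis
#'   rate constant (default 1).
#' @return An object of class `photolysis_params`.
#' @export
photolysis_params <- function(molar_absorptivity = 4000, quantum_yield = 0.07,
                              efficiency = 1) {
  stopifnot(molar_absorptivity > 0, quantum_yield > 0, quantum_yield <= 1,
            efficiency > 0)
  structure(list(molar_absorptivity = molar_absorptivity,
                 quantum_yield = quantum_yield, efficiency = efficiency),
            class = "photolysis_params")
}

#' Scavenger (NTP-consuming enzyme) parameters
#'
#' Michaelis-Menten consumption of free NTP by a scavenging enzyme such as
#' hexokinase. One enzyme unit converts 1 umol substrate per minute at
#' saturation, i.e. 1 U ml^-1 contributes 16.7 uM s^-1 to Vmax.
#'
#' @param activity Enzyme activity in U ml^-1.
#' @param vmax_per_unit Saturated consumption rate per unit activity,
#'   uM s^-1 per U ml^-1 (default 16.7, the manufacturer unit convention).
#' @param km Michaelis constant for the NTP, uM (default 120).
#' @param mode `"full_MM"` for Michaelis-Menten consumption or
#'   `"linearized"` for the first-order approximation with rate constant
#'   `k_scav = activity * vmax_per_unit / km` (valid for free NTP << km).
#' @return An object of class `scavenger_params`.
#' @export
scavenger_params <- function(activity = 10, vmax_per_unit = 16.7, km = 120,
                             mode = c("full_MM", "linearized")) {
  mode <- match.arg(mode)
  stopifnot(activity > 0, vmax_per_unit > 0, km > 0)
  structure(list(activity = activity, vmax_per_unit = vmax_per_unit, km = km,
                 mode = mode, vmax = activity * vmax_per_unit,
                 k_scav = activity * vmax_per_unit / km),
            class = "scavenger_params")
}

# instantaneous consumption rate (uM/s) for free NTP concentration f (uM)
.scavenge_rate <- function(scavenger, f) {
  if (scavenger$mode == "linearized") scavenger$k_scav * f
  else scavenger$vmax * f / (scavenger$km + f)
}

#' Diffusion parameters for free NTP
#'
#' @param D Diffusion coefficient of the free nucleotide in um^2 s^-1
#'   (default 300, typical for ATP in aqueous buffer).
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(D = 300) {
  stopifnot(D > 0)
  structure(list(D = D), class = "diffusion_params")
}

#' First-order photolysis rate constant
#'
#' Converts light intensity and cage photochemistry into the first-order rate
#' constant for uncaging, `k_unc = ln(10) * epsilon * phi * I * lambda /
#' (N_A * h * c)` (with the molar absorptivity converted to a per-molecule
#' absorption cross-section), scaled by the calibration `efficiency`. The
#' rate is strictly linear in the power density: free NTP generation is
#' proportional to the uncaging laser intensity.
#'
#' @param photolysis A [photolysis_params()].
#' @param power_density Power density in W cm^-2.
#' @param wavelength Wavelength in nm.
#' @return Rate constant in s^-1 (same length as `power_density`).
#' @export
photolysis_rate_constant <- function(photolysis, power_density,
                                     wavelength = 360) {
  if (any(power_density < 0)) stop("power density must be non-negative")
  if (wavelength < 300 || wavelength > 450)
    stop("wavelength must lie in 300-450 nm")
  sigma <- log(10) * photolysis$molar_absorptivity * 1000 / .AVOGADRO  # cm^2
  photon_energy <- .PLANCK * .C_LIGHT / (wavelength * 1e-9)           # J
  flux <- power_density / photon_energy                               # cm^-2 s^-1
  sigma * photolysis$quantum_yield * photolysis$efficiency * flux
}

#' Closed-form steady-state free NTP under continuous uncaging
#'
#' With a constant caged reservoir, production `k_unc * caged0` balances
#' scavenging. In linearized mode `free_ss = k_unc * caged0 / k_scav`; in
#' full Michaelis-Menten mode `free_ss = km * P / (Vmax - P)` with
#' `P = k_unc * caged0` (infinite if production exceeds Vmax).
#'
#' @param photolysis,scavenger Parameter objects.
#' @param caged0 Caged NTP reservoir concentration, uM.
#' @param power_density W cm^-2.
#' @param wavelength nm.
#' @return Steady-state free NTP, uM.
#' @export
steady_state_free <- function(photolysis, scavenger, caged0, power_density,
                              wavelength = 360) {
  k_unc <- photolysis_rate_constant(photolysis, power_density, wavelength)
  P <- k_unc * caged0
  if (scavenger$mode == "linearized") return(P / scavenger$k_scav)
  ifelse(P >= scavenger$vmax, Inf, scavenger$km * P / (scavenger$vmax - P))
}

#' Calibrate photolysis efficiency against a target effective concentration
#'
#' Sets the `efficiency` factor of a [photolysis_params()] so that continuous
#' uncaging at the stated conditions reaches a given steady-state free-NTP
#' concentration. Used to anchor the placeholder photochemistry to a measured
#' effective concentration (e.g. 40 uM at 5 W cm^-2 with 10 mM caged ATP and
#' 10 U ml^-1 hexokinase).
#'
#' @param photolysis A [photolysis_params()] whose efficiency is to be set.
#' @param scavenger A [scavenger_params()].
#' @param caged0 Caged reservoir, uM.
#' @param power_density W cm^-2 at which the target is specified.
#' @param target_free Target steady-state free NTP, uM (must be < Vmax-limited
#'   maximum in full MM mode).
#' @param wavelength nm.
#' @return The input `photolysis_params` with calibrated `efficiency`.
#' @export
calibrate_photolysis <- function(photolysis, scavenger, caged0, power_density,
                                 target_free, wavelength = 360) {
  stopifnot(target_free > 0, caged0 > 0, power_density > 0)
  P_needed <- .scavenge_rate(scavenger, target_free)
  k_needed <- P_needed / caged0
  base <- photolysis
  base$efficiency <- 1
  k_raw <- photolysis_rate_constant(base, power_density, wavelength)
  photolysis$efficiency <- k_needed / k_raw
  photolysis
}

#' Simulate well-mixed (0-D) uncaging kinetics
#'
#' Integrates `d[free]/dt = k_unc(t)*[caged] - v_scav([free])` over the
#' illumination protocol, with the caged compound either held at a constant
#' reservoir concentration (default; the mM-scale caged pool dwarfs the
#' uM-scale uncaged product) or depleted in a closed system (for mass-balance
#' checks). Uses adaptive stiff-capable integration (lsoda) on each
#' constant-illumination segment.
#'
#' @param protocol An [illumination_protocol()].
#' @param photolysis A [photolysis_params()].
#' @param scavenger A [scavenger_params()].
#' @param caged0 Initial caged NTP, uM.
#' @param dt Output sampling interval, s. For pulsed protocols must resolve
#'   the shortest pulse with at least 20 points.
#' @param reservoir If `TRUE` (default) the caged pool is a constant
#'   reservoir; if `FALSE` the system is closed and caged NTP is depleted.
#' @return A `chemical_field` (0-D) with columns `time`, `caged`, `free`,
#'   `consumed` in its `$data`.
#' @export
simulate_well_mixed <- function(protocol, photolysis, scavenger, caged0,
                                dt = NULL, reservoir = TRUE) {
  stopifnot(caged0 > 0)
  if (!is.null(protocol$pulses)) {
    max_dt <- protocol$pulses$duration / 20
    if (is.null(dt)) dt <- max_dt
    if (dt > max_dt * (1 + 1e-9))
      stop(sprintf("dt = %g does not resolve the %g-s pulse; use dt <= %g",
                   dt, protocol$pulses$duration, max_dt))
  } else if (is.null(dt)) {
    dt <- protocol$total_duration / 1000
  }
  k_unc0 <- photolysis_rate_constant(photolysis, protocol$power_density,
                                     protocol$wavelength)
  deriv <- function(t, y, parms) {
    ku <- parms$k_on_segment
    cg <- if (reservoir) caged0 else y[["caged"]]
    prod <- ku * cg
    cons <- .scavenge_rate(scavenger, max(y[["free"]], 0))
    dcaged <- if (reservoir) 0 else -prod
    list(c(caged = dcaged, free = prod - cons, consumed = cons))
  }
  bounds <- .protocol_segments(protocol)
  y <- c(caged = caged0, free = 0, consumed = 0)
  out_t <- c(0); out_y <- matrix(y, nrow = 1)
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    on <- illumination_at(protocol, (t0 + t1) / 2) > 0
    # dark segments need no finer sampling than the scavenging timescale
    dt_seg <- if (on) dt else max(dt, 0.005)
    times <- unique(c(seq(t0, t1, by = dt_seg), t1))
    sol <- deSolve::ode(y = y, times = times, func = deriv,
                        parms = list(k_on_segment = if (on) k_unc0 else 0),
                        method = "lsoda", rtol = 1e-9, atol = 1e-9)
    y <- sol[nrow(sol), -1L]
    out_t <- c(out_t, sol[-1L, 1L])
    out_y <- rbind(out_y, unname(sol[-1L, -1L, drop = FALSE]))
  }
  data <- data.frame(time = out_t, caged = out_y[, 1L], free = out_y[, 2L],
                     consumed = out_y[, 3L])
  data$free <- pmax(data$free, 0)
  if (!reservoir) {
    total <- data$caged + data$free + data$consumed
    rel_err <- max(abs(total - caged0)) / caged0
    if (rel_err > 1e-5)
      stop(sprintf(paste0("mass balance violated (relative error %.2g); the ",
                          "integration is unstable, try dt <= %g"),
                   rel_err, dt / 10))
  }
  structure(list(dimension = 0L, data = data, grid = NULL,
                 protocol = protocol, reservoir = reservoir),
            class = "chemical_field")
}

# second-difference Laplacian with Dirichlet-0 ("absorbing") or Neumann
# ("reflecting") outer boundaries, 1-D
.laplacian_1d <- function(f, dx, boundary) {
  n <- length(f)
  left  <- c(if (boundary == "reflecting") f[1] else 0, f[-n])
  right <- c(f[-1], if (boundary == "reflecting") f[n] else 0)
  (left - 2 * f + right) / dx^2
}

#' Characteristic decay length of free NTP outside the illuminated spot
#'
#' In the linearized-scavenging regime the steady-state profile outside a
#' wide spot decays as `exp(-x / L)` with
#' `L = sqrt(D * km / (activity * vmax_per_unit))`.
#'
#' @param scavenger A [scavenger_params()].
#' @param diffusion A [diffusion_params()].
#' @return Decay length L in um.
#' @export
decay_length <- function(scavenger, diffusion) {
  sqrt(diffusion$D / scavenger$k_scav)
}

#' Simulate spatially resolved uncaging (1-D or 2-D)
#'
#' Method-of-lines solution of
#' `d[free]/dt = D lap([free]) + k_unc(x, t) [caged] - v_scav([free])`
#' with photolysis confined to the illuminated spot and the caged compound
#' treated as a constant reservoir. Second-order central differences in
#' space; adaptive stiff integration in time; outer boundary fixed at zero
#' free NTP (far-field sink) unless `boundary = "reflecting"`.
#'
#' @param protocol,photolysis,scavenger,diffusion Parameter objects.
#' @param caged0 Caged reservoir, uM.
#' @param grid List with `extent` (half-width of the domain, um, measured from
#'   the spot centre) and `nx` nodes (and `ny` for 2-D).
#' @param dimension `"1d"` or `"2d"`.
#' @param boundary `"absorbing"` (far-field sink, default) or `"reflecting"`.
#' @param times Output times, s. Default 100 samples over the protocol.
#' @return A `chemical_field` with `$grid` (node coordinates, um) and
#'   `$free` (times x nodes matrix; for 2-D, nodes in column-major x-fastest
#'   order).
#' @export
simulate_spatial <- function(protocol, photolysis, scavenger, diffusion,
                             caged0, grid = list(extent = 200, nx = 201),
                             dimension = c("1d", "2d"),
                             boundary = c("absorbing", "reflecting"),
                             times = NULL) {
  dimension <- match.arg(dimension)
  boundary <- match.arg(boundary)
  stopifnot(caged0 > 0)
  L <- decay_length(scavenger, diffusion)
  half_w <- protocol$spot[1] / 2
  if (is.finite(half_w) && boundary == "absorbing") {
    if (grid$extent < half_w + 5 * L)
      stop(sprintf("domain extent %g um too small: need spot half-width + 5 decay lengths = %g um",
                   grid$extent, half_w + 5 * L))
  }
  x <- seq(-grid$extent, grid$extent, length.out = grid$nx)
  dx <- x[2] - x[1]
  if (dx > L / 10 + 1e-12)
    stop(sprintf("grid spacing %g um too coarse for decay length %g um (need <= L/10)",
                 dx, L))
  k_unc0 <- photolysis_rate_constant(photolysis, protocol$power_density,
                                     protocol$wavelength)
  if (is.null(times))
    times <- seq(0, protocol$total_duration, length.out = 101)

  if (dimension == "1d") {
    in_spot <- abs(x) <= half_w
    nnode <- grid$nx
    deriv <- function(t, y, parms) {
      ku <- if (parms$on) k_unc0 else 0
      prod <- ku * caged0 * in_spot
      cons <- .scavenge_rate(scavenger, pmax(y, 0))
      list(diffusion$D * .laplacian_1d(y, dx, boundary) + prod - cons)
    }
    coords <- data.frame(x = x)
  } else {
    ny <- if (is.null(grid$ny)) grid$nx else grid$ny
    ey <- if (is.null(grid$extent_y)) grid$extent else grid$extent_y
    yv <- seq(-ey, ey, length.out = ny)
    dy <- yv[2] - yv[1]
    half_h <- protocol$spot[2] / 2
    xs <- rep(x, times = ny); ys <- rep(yv, each = grid$nx)
    in_spot <- abs(xs) <= half_w & abs(ys) <= half_h
    nnode <- grid$nx * ny
    deriv <- function(t, y, parms) {
      ku <- if (parms$on) k_unc0 else 0
      m <- matrix(pmax(y, 0), grid$nx, ny)
      lap <- (rbind(if (boundary == "reflecting") m[1, ] else 0, m[-grid$nx, ]) -
                2 * m +
              rbind(m[-1, ], if (boundary == "reflecting") m[grid$nx, ] else 0)) / dx^2 +
             (cbind(if (boundary == "reflecting") m[, 1] else 0, m[, -ny]) -
                2 * m +
              cbind(m[, -1], if (boundary == "reflecting") m[, ny] else 0)) / dy^2
      prod <- ku * caged0 * in_spot
      cons <- .scavenge_rate(scavenger, pmax(y, 0))
      list(as.vector(diffusion$D * lap) + prod - cons)
    }
    coords <- data.frame(x = xs, y = ys)
  }

  bounds <- .protocol_segments(protocol)
  y <- rep(0, nnode)
  free <- matrix(NA_real_, length(times), nnode)
  free[1, ] <- y
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    on <- illumination_at(protocol, (t0 + t1) / 2) > 0
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    sol <- deSolve::ode(y = y, times = seg_times, func = deriv,
                        parms = list(on = on), method = "lsoda",
                        rtol = 1e-7, atol = 1e-7)
    y <- sol[nrow(sol), -1L]
    idx <- match(round(seg_times, 10), round(times, 10))
    keep <- !is.na(idx)
    free[idx[keep], ] <- sol[keep, -1L, drop = FALSE]
  }
  free <- pmax(free, 0)
  structure(list(dimension = if (dimension == "1d") 1L else 2L,
                 data = NULL, times = times, grid = coords, free = free,
                 protocol = protocol, caged0 = caged0),
            class = "chemical_field")
}

#' Time-averaged mean free NTP over a region and window
#'
#' The effective concentration an enzyme in `region` experiences during
#' `window`: the spatial mean of free NTP over the region, averaged over time
#' (trapezoidal rule).
#'
#' @param field A `chemical_field` from [simulate_well_mixed()] or
#'   [simulate_spatial()].
#' @param region For spatial fields, a function of the coordinate data frame
#'   returning a logical node mask, or `NULL` for the illuminated spot.
#'   Ignored for 0-D fields.
#' @param window Length-2 numeric `c(t0, t1)` in s, or `NULL` for the full
#'   simulated time.
#' @return Effective free NTP concentration, uM.
#' @export
effective_concentration <- function(field, region = NULL, window = NULL) {
  if (field$dimension == 0L) {
    tt <- field$data$time; ff <- field$data$free
  } else {
    tt <- field$times
    if (is.null(region)) {
      hw <- field$protocol$spot / 2
      mask <- abs(field$grid$x) <= hw[1]
      if (!is.null(field$grid$y)) mask <- mask & abs(field$grid$y) <= hw[2]
    } else {
      mask <- region(field$grid)
    }
    if (!any(mask)) stop("empty region")
    ff <- rowMeans(field$free[, mask, drop = FALSE])
  }
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    if (sum(keep) < 2L) stop("window contains fewer than two samples")
    tt <- tt[keep]; ff <- ff[keep]
  }
  if (length(tt) < 2L) stop("field has fewer than two time samples")
  # trapezoidal time average
  sum(diff(tt) * (head(ff, -1) + tail(ff, -1)) / 2) / (tail(tt, 1) - tt[1])
}

#' Extract the free-NTP time series at the illuminated spot
#'
#' Convenience accessor: for 0-D fields the well-mixed series, for spatial
#' fields the spatial mean over the spot at each time.
#'
#' @param field A `chemical_field`.
#' @return Data frame with `time` and `free` (uM).
#' @export
free_ntp_series <- function(field) {
  if (field$dimension == 0L)
    return(data.frame(time = field$data$time, free = field$data$free))
  hw <- field$protocol$spot / 2
  mask <- abs(field$grid$x) <= hw[1]
  if (!is.null(field$grid$y)) mask <- mask & abs(field$grid$y) <= hw[2]
  data.frame(time = field$times,
             free = rowMeans(field$free[, mask, drop = FALSE]))
}

#' @export
print.chemical_field <- function(x, ...) {
  cat(sprintf("<chemical_field> %d-D, %s\n", x$dimension,
              if (x$dimension == 0L)
                sprintf("%d time points", nrow(x$data))
              else
                sprintf("%d time points x %d nodes", length(x$times),
                        nrow(x$grid))))
  invisible(x)
}

#' Export a chemical field as a tidy table
#'
#' @param field A `chemical_field`.
#' @return A data frame with `time`, coordinates (if spatial) and
#'   concentrations, suitable for writing as CSV.
#' @export
field_table <- function(field) {
  if (field$dimension == 0L) return(field$data)
  nt <- length(field$times); nn <- nrow(field$grid)
  out <- data.frame(time = rep(field$times, each = nn),
                    x = rep(field$grid$x, times = nt))
  if (!is.null(field$grid$y)) out$y <- rep(field$grid$y, times = nt)
  out$free <- as.vector(t(field$free))
  out
}
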