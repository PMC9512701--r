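# shared fixtures for the test suite; everything is generated in code

# quick linearized scavenger/photolysis pair with convenient round numbers
fix_scav_lin <- function(activity = 10)
  scavenger_params(activity = activity, mode = "linearized")

fix_phot <- function(efficiency = 1e-3)
  photolysis_params(efficiency = efficiency)

# constant-ATP series over [0, t_end]
const_atp <- function(conc, t_end)
  data.frame(time = c(0, t_end), free = c(conc, conc))

# square-wave ATP series: `conc` inside pulses, 0 outside, with sharp edges
square_atp <- function(conc, duration, period, n, t_end = n * period) {
  eps <- 1e-9
  t <- numeric(0); f <- numeric(0)
  for (k in seq_len(n)) {
    s <- (k - 1) * period
    if (s > 0) { t <- c(t, s - eps); f <- c(f, 0) }
    t <- c(t, s, s + duration, s + duration + eps)
    f <- c(f, conc, conc, 0)
  }
  if (t_end > max(t)) { t <- c(t, t_end); f <- c(f, 0) }
  keep <- t >= 0 & t <= t_end
  data.frame(time = t[keep], free = f[keep])
}

# noiseless staircase with known change points (indices of last plateau
# sample) and plateau levels
make_staircase <- function(levels, dwells, sigma = 0) {
  y <- rep(levels, dwells)
  if (sigma > 0) y <- y + rnorm(length(y), 0, sigma)
  list(y = y, cps = cumsum(dwells)[-length(dwells)], levels = levels)
}

# score detected change points against truth with a position tolerance
score_steps <- function(detected, truth, tol = 3) {
  if (length(truth) == 0)
    return(list(recall = NA, precision = as.numeric(length(detected) == 0)))
  hit <- vapply(truth, function(cp) any(abs(detected - cp) <= tol),
                logical(1))
  used <- vapply(detected, function(cp) any(abs(truth - cp) <= tol),
                 logical(1))
  list(recall = mean(hit),
       precision = if (length(detected)) mean(used) else 1)
}
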