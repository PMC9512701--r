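# running sums for O(1) segment SSR: SSR(i..j) = sum y^2 - (sum y)^2 / n
.seg_ssr <- function(cs, cs2, i, j) {
  n <- j - i + 1
  s <- cs[j + 1] - cs[i]
  s2 <- cs2[j + 1] - cs2[i]
  pmax(s2 - s^2 / n, 0)
}

# best split of segment [i, j] honouring a minimum sub-segment length;
# returns c(split_index_of_last_point_of_left_part, ssr_reduction) or NULL
.best_split <- function(cs, cs2, i, j, min_size) {
  if (j - i + 1 < 2 * min_size) return(NULL)
  ks <- (i + min_size - 1):(j - min_size)   # left part ends at k
  left <- .seg_ssr(cs, cs2, i, ks)
  right <- .seg_ssr(cs, cs2, ks + 1, j)
  total <- .seg_ssr(cs, cs2, i, j)
  red <- total - (left + right)
  b <- which.max(red)                        # earliest index wins ties
  c(split = ks[b], reduction = red[b])
}

# SSR of a piecewise-constant fit with change points after indices `cps`
.fit_ssr <- function(cs, cs2, cps, n) {
  b <- c(0, sort(cps), n)
  sum(vapply(seq_len(length(b) - 1L),
             function(k) .seg_ssr(cs, cs2, b[k] + 1, b[k + 1]), numeric(1)))
}

#' Chi-square change-point step detection with counter-fit acceptance
#'
#' Iterative greedy placement of change points: at each round the single
#' split that most reduces the residual sum of squares over the current
#' plateau set is added. Each candidate number of steps k is scored against
#' a counter-fit whose change points sit at the midpoints of the k-fit's
#' plateaus (where genuine steps are least likely); the score is the ratio
#' of counter-fit to fit chi-square. The k with the best score is accepted
#' if the score exceeds `acceptance_threshold`; otherwise zero steps are
#' reported. Ties in the split search resolve to the earliest index.
#'
#' @param series Numeric series (e.g. a corrected FRET trace), length >= 10.
#' @param max_steps Maximum number of change points to consider.
#' @param acceptance_threshold Minimum counter-fit/fit chi-square ratio for
#'   accepting steps. The default 1.6 holds the false-positive rate on flat
#'   noisy traces below 5 percent (see the methods vignette).
#' @param min_size Minimum plateau length in samples (default 3); steps
#'   closer together than this merge into one larger detected step.
#' @param step_t_min After the global acceptance test, individual steps whose
#'   size is smaller than `step_t_min` standard errors (from the residual
#'   noise and the flanking plateau lengths) are pruned, weakest first
#'   (default 3.5). Set to 0 to disable pruning.
#' @return An object of class `step_fit`: list with `changepoints` (indices
#'   of the last sample of each plateau), `means` (plateau means),
#'   `sizes` (step sizes, length = number of change points), `n_steps`,
#'   `score` (counter-fit ratio of the accepted fit), `fitted` (the
#'   piecewise-constant reconstruction), `ssr`.
#' @export
find_steps <- function(series, max_steps = 20L,
                       acceptance_threshold = 1.6, min_size = 3L,
                       step_t_min = 3.5) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("series too short for step detection (need >= 10 samples)")
  max_steps <- min(max_steps, floor(n / min_size) - 1L)
  cs <- c(0, cumsum(series))
  cs2 <- c(0, cumsum(series^2))
  cps <- integer(0)
  segs <- list(c(1L, n))
  ssr_path <- numeric(0)
  cp_path <- list()
  while (length(cps) < max_steps) {
    best <- NULL; best_seg <- 0L
    for (s in seq_along(segs)) {
      cand <- .best_split(cs, cs2, segs[[s]][1], segs[[s]][2], min_size)
      if (!is.null(cand) && (is.null(best) || cand["reduction"] > best["reduction"])) {
        best <- cand; best_seg <- s
      }
    }
    if (is.null(best) || best["reduction"] <= 0) break
    k <- unname(best["split"])
    seg <- segs[[best_seg]]
    segs[[best_seg]] <- c(seg[1], k)
    segs[[length(segs) + 1L]] <- c(k + 1L, seg[2])
    cps <- c(cps, k)
    cp_path[[length(cps)]] <- sort(cps)
    ssr_path <- c(ssr_path, .fit_ssr(cs, cs2, cps, n))
  }
  if (length(cps) == 0L)
    return(.step_fit(series, integer(0), cs, cs2, NA_real_))
  # counter-fit score per candidate k
  scores <- vapply(seq_along(cp_path), function(k) {
    fit_ssr <- ssr_path[k]
    b <- c(0L, cp_path[[k]], n)
    counter <- unique(pmax(pmin(floor((b[-length(b)] + b[-1]) / 2),
                                n - 1L), 1L))
    counter_ssr <- .fit_ssr(cs, cs2, counter, n)
    if (fit_ssr <= .Machine$double.eps * sum(series^2)) Inf
    else counter_ssr / fit_ssr
  }, numeric(1))
  k_best <- which.max(scores)
  if (scores[k_best] <= acceptance_threshold)
    return(.step_fit(series, integer(0), cs, cs2, max(scores)))
  cps_acc <- cp_path[[k_best]]
  if (step_t_min > 0)
    cps_acc <- .prune_steps(series, cps_acc, cs, cs2, step_t_min)
  .step_fit(series, cps_acc, cs, cs2, scores[k_best])
}

# drop steps whose size is insignificant against the residual noise,
# weakest first, refitting plateau means after each removal
.prune_steps <- function(series, cps, cs, cs2, t_min) {
  n <- length(series)
  repeat {
    if (length(cps) == 0L) return(cps)
    b <- c(0L, cps, n)
    lens <- diff(b)
    means <- (cs[b[-1] + 1] - cs[b[-length(b)] + 1]) / lens
    resid_sd <- sqrt(.fit_ssr(cs, cs2, cps, n) /
                       max(n - length(cps) - 1L, 1L))
    if (resid_sd <= 0) return(cps)
    sizes <- diff(means)
    se <- resid_sd * sqrt(1 / lens[-length(lens)] + 1 / lens[-1])
    tstat <- abs(sizes) / se
    if (min(tstat) >= t_min) return(cps)
    cps <- cps[-which.min(tstat)]
  }
}

.step_fit <- function(series, cps, cs, cs2, score) {
  n <- length(series)
  b <- c(0L, cps, n)
  means <- vapply(seq_len(length(b) - 1L), function(k)
    (cs[b[k + 1] + 1] - cs[b[k] + 1]) / (b[k + 1] - b[k]), numeric(1))
  fitted <- rep(means, diff(b))
  structure(list(changepoints = cps, means = means,
                 sizes = diff(means), n_steps = length(cps),
                 score = score, fitted = fitted,
                 ssr = sum((series - fitted)^2), n = n),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d steps (score %.3g), plateaus at %s\n",
              x$n_steps, x$score,
              paste(sprintf("%.3g", x$means), collapse = " / ")))
  invisible(x)
}

#' First-step sizes across a set of step fits
#'
#' Collects the size of the first detected step per trace, restricted to the
#' initial monotone-increase phase: each fit is truncated at its first
#' negative step (a FRET decrease cannot be distinguished from reversal or
#' dissociation), and plateaus shorter than `min_dwell` samples do not
#' qualify. Traces with no qualifying step are excluded and counted.
#'
#' @param fits List of `step_fit` objects (one per trace).
#' @param min_dwell Minimum plateau length in samples for the plateaus
#'   flanking the first step (default 5).
#' @return List with `sizes` (one value per qualifying trace), `n_excluded`,
#'   and `trace` (indices of contributing fits).
#' @export
first_step_sizes <- function(fits, min_dwell = 5L) {
  sizes <- numeric(0); idx <- integer(0); excluded <- 0L
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (f$n_steps == 0L) { excluded <- excluded + 1L; next }
    # truncate at the first FRET decrease
    neg <- which(f$sizes < 0)
    last_ok <- if (length(neg)) neg[1] - 1L else f$n_steps
    if (last_ok < 1L) { excluded <- excluded + 1L; next }
    b <- c(0L, f$changepoints, f$n)
    dwells <- diff(b)
    if (dwells[1] < min_dwell || dwells[2] < min_dwell) {
      excluded <- excluded + 1L; next
    }
    sizes <- c(sizes, f$sizes[1]); idx <- c(idx, i)
  }
  list(sizes = sizes, n_excluded = excluded, trace = idx)
}
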