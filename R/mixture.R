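#' Two-component Gaussian mixture fit of step sizes
#'
#' Maximum-likelihood EM fit of a two-Gaussian mixture to raw step sizes,
#' as used to decompose first-step histograms into an elementary-step
#' component and a larger compound-step component. Optionally the second
#' (larger-mean) component's centre and width are fixed — e.g. to the values
#' derived from a reference condition — leaving only its weight free.
#'
#' @param sizes Numeric sample of step sizes (n >= 50 recommended).
#' @param fix_component2 `NULL`, or numeric `c(mean, sigma)` fixing the
#'   second component; only the weights and the first component's parameters
#'   are then estimated.
#' @param method `"em"` for maximum-likelihood EM on the raw sizes, or
#'   `"histogram"` for least-squares fitting of two Gaussian peaks to the
#'   binned histogram (robust to sparse outliers; the form used for the
#'   published histograms).
#' @param bin_width Histogram bin width for `method = "histogram"`
#'   (default 0.02 signal units).
#' @param n_restarts Number of random EM restarts (default 10).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param sigma_floor Lower bound on the free component widths, guarding
#'   against the classical spike degeneracy of Gaussian-mixture likelihoods;
#'   default one fifth of the sample standard deviation.
#' @return An object of class `mixture_fit`: list with `weight`, `mean`,
#'   `sigma` (each length 2, component 1 = smaller mean),
#'   `compound_fraction` (weight of the larger-mean / fixed component),
#'   `loglik`, `converged`, `n`.
#' @export
fit_two_gaussians <- function(sizes, fix_component2 = NULL,
                              method = c("em", "histogram"),
                              n_restarts = 10L, max_iter = 500L,
                              tol = 1e-8, sigma_floor = NULL,
                              bin_width = 0.02) {
  method <- match.arg(method)
  x <- as.numeric(sizes)
  n <- length(x)
  if (n < 4L) stop("too few step sizes for a two-component fit")
  if (method == "histogram") {
    # EM (run quietly on the same sample) identifies the two modes; the
    # histogram least squares then refines from that starting point
    em <- tryCatch(fit_two_gaussians(x, fix_component2, method = "em",
                                     n_restarts = n_restarts),
                   error = function(e) NULL)
    return(.fit_two_gaussians_hist(x, fix_component2, bin_width, em))
  }
  if (is.null(sigma_floor))
    sigma_floor <- max(stats::sd(x), .Machine$double.eps) / 5
  sd_floor <- sigma_floor
  fixed <- !is.null(fix_component2)
  if (fixed) stopifnot(length(fix_component2) == 2L, fix_component2[2] > 0)

  run_em <- function(mu, sg, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      r2 <- d2 / tot
      w <- c(1 - mean(r2), mean(r2))
      w <- pmax(w, 1e-12); w <- w / sum(w)
      n1 <- sum(1 - r2); n2 <- sum(r2)
      if (n1 > 0) {
        mu[1] <- sum((1 - r2) * x) / n1
        sg[1] <- max(sqrt(sum((1 - r2) * (x - mu[1])^2) / n1), sd_floor)
      }
      if (!fixed && n2 > 0) {
        mu[2] <- sum(r2 * x) / n2
        sg[2] <- max(sqrt(sum(r2 * (x - mu[2])^2) / n2), sd_floor)
      }
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1))
        return(list(mu = mu, sg = sg, w = w, ll = ll, converged = TRUE))
      ll_old <- ll
    }
    list(mu = mu, sg = sg, w = w, ll = ll_old, converged = FALSE)
  }

  best <- NULL
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  s0 <- max(stats::sd(x) / 2, sd_floor)
  pk <- .two_density_peaks(x)
  km <- tryCatch(sort(stats::kmeans(x, 2, nstart = 5)$centers[, 1]),
                 error = function(e) qs)
  # a solution is degenerate when a component collapses to a low-weight
  # spike at the width floor
  ok_fit <- function(f)
    f$converged && !any(f$sg <= sd_floor * 1.001 & f$w < 0.05)
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1L && !is.null(pk)) pk else if (r == 1L) km
          else if (r == 2L) km else if (r == 3L) qs
          else sort(stats::runif(2, min(x), max(x)))
    sg <- c(s0, s0)
    if (fixed) { mu[2] <- fix_component2[1]; sg[2] <- fix_component2[2] }
    fit <- run_em(mu, sg, c(0.5, 0.5))
    if (is.null(best) || (ok_fit(fit) && !ok_fit(best)) ||
        (ok_fit(fit) == ok_fit(best) && fit$ll > best$ll))
      best <- fit
  }
  if (is.null(best) || !best$converged)
    stop(sprintf(paste0("EM did not converge in %d iterations over %d ",
                        "restarts (best log-likelihood %.4g); inspect the ",
                        "step-size sample"),
                 max_iter, n_restarts, if (is.null(best)) NA else best$ll))
  # order components by mean; the larger-mean one is the compound component
  o <- order(best$mu)
  if (fixed) o <- c(setdiff(1:2, 2), 2)  # fixed component stays component 2
  w <- best$w[o]; mu <- best$mu[o]; sg <- best$sg[o]
  structure(list(weight = w, mean = mu, sigma = sg,
                 compound_fraction = w[2], loglik = best$ll,
                 converged = best$converged, n = n,
                 fixed_component2 = fixed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> w = %.3f/%.3f, mu = %.3g/%.3g, ",
                     "sigma = %.3g/%.3g (compound fraction %.1f%%)\n"),
              x$weight[1], x$weight[2], x$mean[1], x$mean[2],
              x$sigma[1], x$sigma[2], 100 * x$compound_fraction))
  invisible(x)
}

# least-squares fit of two Gaussian peaks to the binned histogram; the
# compound fraction is the fitted area fraction of the larger-mean peak
.fit_two_gaussians_hist <- function(x, fix_component2, bin_width,
                                    em_init = NULL) {
  n <- length(x)
  fixed <- !is.null(fix_component2)
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  cts <- h$counts; mids <- h$mids
  pk <- .two_density_peaks(x)
  if (!is.null(em_init)) {
    mu0 <- em_init$mean; sg0 <- em_init$sigma; w0 <- em_init$weight
  } else if (!is.null(pk)) {
    mu0 <- pk
    cut <- mean(pk)
    w0 <- c(mean(x < cut), mean(x >= cut))
    sg0 <- c(stats::sd(x[x < cut]), stats::sd(x[x >= cut]))
    sg0[!is.finite(sg0)] <- stats::sd(x) / 2
  } else {
    mu0 <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    sg0 <- rep(stats::sd(x) / 2, 2); w0 <- c(0.5, 0.5)
  }
  sg0 <- pmax(sg0, bin_width / 2)
  if (fixed) { mu0[2] <- fix_component2[1]; sg0[2] <- fix_component2[2] }
  # parameters: logit(w2), mu1, log sg1 [, mu2, log sg2]
  p0 <- c(stats::qlogis(min(max(w0[2], 0.05), 0.95)), mu0[1], log(sg0[1]))
  if (!fixed) p0 <- c(p0, mu0[2], log(sg0[2]))
  model <- function(p) {
    w2 <- stats::plogis(p[1]); mu1 <- p[2]; sg1 <- exp(p[3])
    mu2 <- if (fixed) fix_component2[1] else p[4]
    sg2 <- if (fixed) fix_component2[2] else exp(p[5])
    n * bin_width * ((1 - w2) * stats::dnorm(mids, mu1, sg1) +
                       w2 * stats::dnorm(mids, mu2, sg2))
  }
  obj <- function(p) sum((cts - model(p))^2)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  p <- opt$par
  w2 <- stats::plogis(p[1])
  mu <- c(p[2], if (fixed) fix_component2[1] else p[4])
  sg <- c(exp(p[3]), if (fixed) fix_component2[2] else exp(p[5]))
  if (!fixed && mu[1] > mu[2]) {  # enforce component 1 = smaller mean
    mu <- rev(mu); sg <- rev(sg); w2 <- 1 - w2
  }
  structure(list(weight = c(1 - w2, w2), mean = mu, sigma = sg,
                 compound_fraction = w2, loglik = NA_real_,
                 sse = opt$value, converged = opt$convergence == 0L,
                 n = n, fixed_component2 = fixed, method = "histogram"),
            class = "mixture_fit")
}

# locations of the two tallest local maxima of a kernel density estimate,
# used to initialise the mixture at the visible histogram modes
.two_density_peaks <- function(x) {
  if (length(unique(x)) < 5L) return(NULL)
  d <- stats::density(x, n = 256)
  y <- d$y
  loc <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  if (length(loc) < 2L) return(NULL)
  loc <- loc[order(y[loc], decreasing = TRUE)][1:2]
  sort(d$x[loc])
}
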