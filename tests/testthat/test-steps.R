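test_that("a noiseless staircase is recovered exactly", {
  st <- make_staircase(c(0.3, 0.4, 0.5, 0.6), c(30, 25, 40, 20))
  fit <- find_steps(st$y)
  expect_equal(fit$n_steps, 3L)
  expect_equal(fit$changepoints, st$cps)
  expect_equal(fit$means, st$levels)
  expect_equal(fit$sizes, rep(0.1, 3))
  expect_equal(fit$ssr, 0)
})

test_that("flat noisy traces yield steps in fewer than 5% of cases", {
  set.seed(31)
  fp <- replicate(400, find_steps(rnorm(150))$n_steps > 0)
  expect_lt(mean(fp), 0.05)
  set.seed(32)
  fp2 <- replicate(200, find_steps(rnorm(600))$n_steps > 0)
  expect_lt(mean(fp2), 0.05)
})

test_that("step recall and precision reach 0.9 at step/sigma = 3 with 20-frame dwells", {
  set.seed(57)
  rec <- prec <- numeric(120)
  for (i in seq_along(rec)) {
    n_steps <- sample(3:6, 1)
    dwells <- sample(20:40, n_steps + 1, replace = TRUE)
    levels <- cumsum(c(0, rep(1, n_steps)))      # steps of 1, sigma 1/3
    st <- make_staircase(levels, dwells, sigma = 1 / 3)
    fit <- find_steps(st$y)
    sc <- score_steps(fit$changepoints, st$cps, tol = 3)
    rec[i] <- sc$recall; prec[i] <- sc$precision
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
})

test_that("re-running the detector on its own reconstruction reproduces the fit", {
  set.seed(8)
  st <- make_staircase(c(0, 1, 2.2, 3), c(30, 30, 30, 30), sigma = 0.25)
  fit <- find_steps(st$y)
  fit2 <- find_steps(fit$fitted)
  expect_equal(fit2$changepoints, fit$changepoints)
  expect_equal(fit2$means, fit$means, tolerance = 1e-12)
})

test_that("short series are rejected and zero steps is a valid result", {
  expect_error(find_steps(rnorm(5)), "too short")
  fit <- find_steps(rep(1, 50))
  expect_equal(fit$n_steps, 0L)
  expect_equal(fit$means, 1)
})

test_that("first-step collection respects the monotone phase and dwell rule", {
  # single-step fits: one 0.1 value each
  mk_fit <- function(levels, dwells) find_steps(rep(levels, dwells))
  fits <- list(mk_fit(c(0.3, 0.4), c(20, 20)),
               mk_fit(c(0.3, 0.4), c(15, 25)))
  fs <- first_step_sizes(fits)
  expect_equal(fs$sizes, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(fs$n_excluded, 0L)
  # a trace that immediately decreases contributes nothing
  fits2 <- c(fits, list(mk_fit(c(0.6, 0.4), c(20, 20))))
  fs2 <- first_step_sizes(fits2)
  expect_equal(length(fs2$sizes), 2L)
  expect_equal(fs2$n_excluded, 1L)
  # flat traces are excluded and counted
  fs3 <- first_step_sizes(list(find_steps(rep(0.5, 40))))
  expect_equal(length(fs3$sizes), 0L)
  expect_equal(fs3$n_excluded, 1L)
  # mixed-size population: proportions recovered within the binomial CI
  set.seed(12)
  sizes <- ifelse(runif(300) < 0.7, 0.1, 0.2)
  fits4 <- lapply(sizes, function(s) mk_fit(c(0.3, 0.3 + s), c(20, 20)))
  fs4 <- first_step_sizes(fits4)
  p_hat <- mean(abs(fs4$sizes - 0.1) < 0.01)
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 300))
})

test_that("dwells below the dwell rule disqualify a first step", {
  y <- rep(c(0.3, 0.4, 0.5), c(3, 30, 30))   # first plateau only 3 frames
  fit <- find_steps(y)
  fs <- first_step_sizes(list(fit), min_dwell = 5)
  expect_equal(length(fs$sizes), 0L)
  expect_equal(fs$n_excluded, 1L)
})
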