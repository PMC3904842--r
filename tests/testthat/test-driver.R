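test_that("r_squared follows the definition", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  f <- c(1.1, 2.8, 2.2, 4.9, 4.1)
  expect_equal(r_squared(y, f),
               1 - sum((y - f)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(2, 5), f), "constant")
})

test_that("residual diagnostics expose whiteness and normality structure", {
  set.seed(16)
  r <- rnorm(144)
  d <- residual_diagnostics(r, max_lag = 20)
  expect_s3_class(d, "residual_diagnostics")
  expect_equal(nrow(d$acf), 20)
  expect_equal(d$band, 1.96 / sqrt(144))
  expect_equal(nrow(d$qq), 144)
  expect_equal(d$qq$sample, sort(r))
  # a pure sine at twice the sampling period is detected as non-white
  s <- sin(pi * seq_len(144))
  s <- sin(2 * pi * seq_len(144) / 8)
  ds <- residual_diagnostics(s, max_lag = 20)
  expect_gt(max(abs(ds$acf$autocorrelation)), ds$band)
  expect_error(residual_diagnostics(numeric(144)), "constant")
})

test_that("the nominal white-noise band holds in Monte Carlo", {
  set.seed(17)
  inside <- vapply(1:200, function(i) {
    d <- residual_diagnostics(rnorm(144), max_lag = 20)
    mean(abs(d$acf$autocorrelation) <= d$band)
  }, numeric(1))
  expect_gte(mean(inside), 0.9)
})

test_that("deconvolve validates its input series", {
  bad <- tibble::tibble(time_min = c(10, 20, 30), concentration = 1:3)
  expect_error(deconvolve(bad), "time-0")
  bad2 <- tibble::tibble(time_min = c(0, 10, 25), concentration = 1:3)
  expect_error(deconvolve(bad2), "uniform grid")
  expect_error(deconvolve(tibble::tibble(a = 1)), "time_min")
  short <- tibble::tibble(time_min = c(0, 10), concentration = c(1, 2))
  expect_error(deconvolve(short), "at least")
  nas <- tibble::tibble(time_min = c(0, 10, 20), concentration = c(1, NA, 2))
  expect_error(deconvolve(nas), "missing")
})

test_that("deconvolve warns and returns an empty train on constant data", {
  const <- tibble::tibble(time_min = seq(0, 100, by = 10),
                          concentration = rep(4, 11))
  expect_warning(fit <- deconvolve(const, n_starts = 1), "constant")
  expect_s3_class(fit, "decon_fit")
  expect_equal(fit$n_pulses, 0L)
  expect_equal(nrow(fit$pulses), 0)
  expect_true(is.na(fit$r_squared))
})

# A small problem (8 h, 4 events) keeps the full pipeline fast enough to run
# twice for the determinism check.
small_problem <- function() {
  th <- kinetic_params(0.0739, 0.0067)
  pt <- tibble::tibble(time_min = c(40L, 150L, 260L, 390L),
                       amplitude = c(8, 12, 6, 10))
  generate_dataset(th, pt, y0 = 5, sigma_nu = 0.3, seed = 99, n_obs = 48)
}

test_that("deconvolve is deterministic given the seed", {
  series <- small_problem()
  cfg <- solver_config(n_min = 3, n_max = 8)
  f1 <- deconvolve(series, cfg, n_starts = 2, seed = 5,
                   warmup_iters = 5, max_sweeps = 10)
  f2 <- deconvolve(series, cfg, n_starts = 2, seed = 5,
                   warmup_iters = 5, max_sweeps = 10)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$pulses, f2$pulses)
  expect_identical(f1$starts, f2$starts)
  f3 <- deconvolve(series, cfg, n_starts = 2, seed = 6,
                   warmup_iters = 5, max_sweeps = 10)
  expect_false(identical(f3$starts, f1$starts))
})

test_that("the fit object satisfies its invariants", {
  series <- small_problem()
  cfg <- solver_config(n_min = 3, n_max = 8)
  fit <- deconvolve(series, cfg, n_starts = 2, seed = 5,
                    warmup_iters = 5, max_sweeps = 10)
  expect_s3_class(fit, "decon_fit")
  expect_gte(fit$theta_hat$theta1, 4 * fit$theta_hat$theta2)
  expect_equal(fit$n_pulses, nrow(fit$pulses))
  expect_lte(fit$n_pulses, cfg$n_max)
  # fitted = A(theta) u + b(theta) y0
  refit <- forward_simulate(fit$theta_hat, fit$pulses, y0 = fit$y0,
                            n_obs = 48)$concentration
  expect_equal(fit$fitted, refit)
  expect_equal(fit$residuals, series$concentration[-1] - fit$fitted)
  expect_equal(fit$r_squared,
               r_squared(series$concentration[-1], fit$fitted))
  expect_equal(nrow(fit$starts), 2)
  expect_output(print(fit), "pulses")
})

test_that("tidiers and plots expose the fit in tidy form", {
  series <- small_problem()
  fit <- deconvolve(series, solver_config(n_min = 3, n_max = 8),
                    n_starts = 1, seed = 5, warmup_iters = 5, max_sweeps = 5)
  td <- tidy(fit)
  expect_named(td, c("time_min", "amplitude"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("theta1", "theta2", "n_pulses", "r_squared",
                     "final_lambda", "final_cost", "sparsity_in_range",
                     "n_starts_used", "seed"))
  aug <- augment(fit)
  expect_equal(nrow(aug), 48)
  expect_named(aug, c("time_min", "concentration", ".fitted", ".resid"))
  expect_equal(aug$.resid, aug$concentration - aug$.fitted)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  pd <- plot_residual_diagnostics(fit)
  expect_true(inherits(pd, "patchwork") || is.list(pd))
})
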