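test_that("decon_cost reproduces hand arithmetic", {
  th <- kinetic_params(0.08, 0.01)
  pt <- tibble::tibble(time_min = c(50L, 300L), amplitude = c(4, 9))
  y <- forward_simulate(th, pt, y0 = 2)$concentration
  # perfect fit, lambda = 0
  expect_equal(decon_cost(th, pt, y, y0 = 2, lambda = 0), 0)
  # empty input, y0 = 0: cost is the squared data norm
  empty <- pt[0, ]
  expect_equal(decon_cost(th, empty, y, y0 = 0, lambda = 3), sum(y^2))
  # random instance term by term
  y2 <- y + 0.1
  fit <- forward_simulate(th, pt, y0 = 2)$concentration
  expect_equal(decon_cost(th, pt, y2, y0 = 2, lambda = 0.7, p = 0.5),
               sum((y2 - fit)^2) + 0.7 * sum(pt$amplitude^0.5))
})

test_that("theta objective gradient matches finite differences", {
  set.seed(14)
  pt <- well_separated_train(3)
  th0 <- c(0.09, 0.012)
  y <- forward_simulate(kinetic_params(0.07, 0.008), pt, y0 = 5)$concentration
  obj <- pulsedecon:::theta_objective(pt$time_min, pt$amplitude, y, 5, 10)
  g <- obj$gr(th0)
  eps <- 1e-7
  fd <- c((obj$fn(th0 + c(eps, 0)) - obj$fn(th0 - c(eps, 0))) / (2 * eps),
          (obj$fn(th0 + c(0, eps)) - obj$fn(th0 - c(0, eps))) / (2 * eps))
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("fit_theta recovers the truth on noise-free data", {
  th_true <- kinetic_params(0.0739, 0.0067)
  pt <- well_separated_train(1)
  y <- forward_simulate(th_true, pt, y0 = 5)$concentration
  fit <- fit_theta(y, pt, y0 = 5, theta_init = kinetic_params(0.12, 0.02))
  expect_lt(abs(fit$theta1 - th_true$theta1) / th_true$theta1, 1e-4)
  expect_lt(abs(fit$theta2 - th_true$theta2) / th_true$theta2, 1e-4)
  expect_gte(fit$theta1, 4 * fit$theta2)
  expect_gt(fit$theta2, 0)
})

test_that("fit_theta projects infeasible starts with a warning and never
           worsens the residual", {
  th_true <- kinetic_params(0.08, 0.01)
  pt <- well_separated_train(2)
  y <- forward_simulate(th_true, pt, y0 = 5)$concentration
  expect_warning(fit <- fit_theta(y, pt, y0 = 5, theta_init = c(0.01, 0.02)),
                 "projected")
  expect_gte(fit$theta1, 4 * fit$theta2)
  # monotone improvement from a feasible start
  start <- kinetic_params(0.1, 0.02)
  fit2 <- fit_theta(y, pt, y0 = 5, theta_init = start)
  rss <- function(th) sum((y - forward_simulate(th, pt, y0 = 5)$concentration)^2)
  expect_lte(rss(fit2), rss(start))
})

test_that("fit_theta lands within one cell of a 50x50 log-grid scan", {
  th_true <- kinetic_params(0.0739, 0.0067)
  pt <- well_separated_train(1)
  y <- forward_simulate(th_true, pt, y0 = 5)$concentration
  rss <- function(t1, t2) {
    sum((y - forward_simulate(kinetic_params(t1, t2), pt, y0 = 5)$concentration)^2)
  }
  t2_grid <- exp(seq(log(0.001), log(0.05), length.out = 50))
  ratio_grid <- exp(seq(log(4), log(40), length.out = 50)) # theta1 / theta2
  costs <- outer(t2_grid, ratio_grid,
                 Vectorize(function(t2, r) rss(r * t2, t2)))
  idx <- which(costs == min(costs), arr.ind = TRUE)[1, ]
  fit <- fit_theta(y, pt, y0 = 5, theta_init = kinetic_params(0.1, 0.015))
  step2 <- diff(log(t2_grid))[1]
  stepr <- diff(log(ratio_grid))[1]
  expect_lte(abs(log(fit$theta2) - log(t2_grid[idx[1]])), step2)
  expect_lte(abs(log(fit$theta1 / fit$theta2) - log(ratio_grid[idx[2]])), stepr)
})

test_that("variable-projection fit recovers kinetics and amplitudes", {
  th_true <- kinetic_params(0.0739, 0.0067)
  pt <- well_separated_train(1)
  y <- forward_simulate(th_true, pt, y0 = 5)$concentration
  # a local method: started within the plausible kinetic range, as the
  # driver does after warm-up
  fit <- pulsedecon:::fit_theta_profile(y, pt$time_min, y0 = 5,
                                        theta_init = kinetic_params(0.08, 0.008))
  # gradient-free profiled objective: converges below 0.1% and is always
  # followed by a nonnegative amplitude refit in the driver
  expect_lt(abs(fit$theta$theta1 - th_true$theta1) / th_true$theta1, 1e-3)
  expect_lt(abs(fit$theta$theta2 - th_true$theta2) / th_true$theta2, 1e-3)
  expect_equal(fit$amplitudes, pt$amplitude, tolerance = 1e-2)
})

test_that("nnls_refit debiases amplitudes on a detected support", {
  set.seed(15)
  A <- matrix(runif(20 * 8), 20, 8)
  x_true <- c(2, 0, 1, 0, 0, 3, 0, 0)
  y <- drop(A %*% x_true) + rnorm(20, sd = 0.01)
  u0 <- x_true * 0.5 # shrunk amplitudes, right support
  u <- pulsedecon:::nnls_refit(A, y, u0)
  expect_true(all(u >= 0))
  expect_true(all(which(u > 0) %in% which(u0 > 0)))
  # matches Lawson-Hanson NNLS restricted to the same support
  S <- which(u0 > 0)
  ref <- pracma::lsqnonneg(A[, S, drop = FALSE], y)$x
  expect_equal(u[S], ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum((y - drop(A %*% u))^2), sum((y - drop(A %*% u0))^2))
})
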