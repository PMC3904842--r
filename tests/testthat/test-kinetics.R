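test_that("kinetic_params validates the feasibility cone", {
  th <- kinetic_params(0.0739, 0.0067)
  expect_s3_class(th, "kinetic_params")
  expect_equal(th$theta1, 0.0739)
  expect_equal(th$theta2, 0.0067)
  expect_error(kinetic_params(0.02, 0.0067), "at least 4")
  expect_error(kinetic_params(0.05, 0), "strictly positive")
  expect_error(kinetic_params(0.05, -0.01), "strictly positive")
  expect_error(kinetic_params(NA_real_, 0.01))
  expect_output(print(th), "theta1")
})

test_that("impulse response is zero at lag 0, positive, and decays", {
  th <- kinetic_params(0.0739, 0.0067)
  expect_identical(impulse_response(th, 0), 0)
  lags <- c(1, 5, 10, 60, 240, 1440)
  h <- impulse_response(th, lags)
  expect_true(all(h > 0))
  expect_lt(impulse_response(th, 1e6), 1e-12)
  expect_error(impulse_response(th, -1), "nonnegative")
})

test_that("closed-form impulse response matches RK4 integration of the ODE", {
  set.seed(101)
  for (i in 1:5) {
    t2 <- runif(1, 0.003, 0.02)
    t1 <- runif(1, 4 * t2, 0.15)
    lags <- sort(sample(1:300, 4))
    h_rk4 <- rk4_compartments(t1, t2, lags, pulse_times = 0,
                              pulse_amounts = 1, step = 0.01)
    h_cf <- impulse_response(kinetic_params(t1, t2), lags)
    expect_equal(h_rk4, h_cf, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("kernel derivatives match central finite differences", {
  th <- list(theta1 = 0.0739, theta2 = 0.0067)
  lag <- c(5, 50, 500)
  g <- pulsedecon:::impulse_response_grad(th, lag)
  eps <- 1e-7
  fd1 <- (impulse_response(kinetic_params(th$theta1 + eps, th$theta2), lag) -
          impulse_response(kinetic_params(th$theta1 - eps, th$theta2), lag)) / (2 * eps)
  fd2 <- (impulse_response(kinetic_params(th$theta1, th$theta2 + eps), lag) -
          impulse_response(kinetic_params(th$theta1, th$theta2 - eps), lag)) / (2 * eps)
  expect_equal(g$d1, fd1, tolerance = 1e-5)
  expect_equal(g$d2, fd2, tolerance = 1e-5)
})

test_that("forward operator has the causal Toeplitz structure", {
  th <- kinetic_params(0.0739, 0.0067)
  op <- forward_operator(th, n_obs = 144, n_input = 1440, dt = 10)
  expect_equal(dim(op$A), c(144, 1440))
  # first sample time is t = 10: nonzeros exactly at input minutes 0..9
  expect_true(all(op$A[1, 1:10] > 0))
  expect_true(all(op$A[1, 11:1440] == 0))
  expect_equal(op$A[1, 1], impulse_response(th, 10))
  # an impulse at the sample instant contributes nothing
  expect_equal(op$A[2, 21], 0)
  expect_true(all(op$A >= 0))
  expect_equal(op$b, exp(-th$theta2 * 10 * (1:144)))
  # Toeplitz along the lag
  expect_equal(op$A[3, 5], op$A[4, 15])
  # zero input leaves only the decaying initial condition
  expect_equal(drop(op$A %*% numeric(1440)) + op$b * 3, 3 * op$b)
})

test_that("forward_simulate superposes single-pulse responses", {
  th <- kinetic_params(0.08, 0.01)
  empty <- tibble::tibble(time_min = integer(), amplitude = numeric())
  expect_equal(forward_simulate(th, empty, y0 = 0)$concentration,
               numeric(144))
  p1 <- tibble::tibble(time_min = 100L, amplitude = 7)
  y1 <- forward_simulate(th, p1, y0 = 0)$concentration
  t_k <- 10 * (1:144)
  expect_equal(y1, ifelse(t_k > 100, 7 * impulse_response(th, pmax(t_k - 100, 0)), 0))
  p2 <- tibble::tibble(time_min = 700L, amplitude = 2)
  y2 <- forward_simulate(th, p2, y0 = 0)$concentration
  y12 <- forward_simulate(th, dplyr::bind_rows(p1, p2), y0 = 0)$concentration
  expect_equal(y12, y1 + y2)
})

test_that("forward_simulate matches RK4 integration with impulses and y0", {
  th <- kinetic_params(0.0739, 0.0067)
  pt <- well_separated_train(1)
  y_cf <- forward_simulate(th, pt, y0 = 5)$concentration
  y_rk4 <- rk4_compartments(th$theta1, th$theta2, 10 * (1:144),
                            pt$time_min, pt$amplitude, y0 = 5, step = 0.05)
  expect_equal(y_rk4, y_cf, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pulse-train validation enforces the contract", {
  v <- pulsedecon:::validate_pulse_train
  good <- tibble::tibble(time_min = c(10L, 400L), amplitude = c(1, 2))
  expect_equal(nrow(v(good)), 2)
  expect_error(v(data.frame(x = 1)), "data frame with columns")
  expect_error(v(tibble::tibble(time_min = 10.5, amplitude = 1)), "integer")
  expect_error(v(tibble::tibble(time_min = -1L, amplitude = 1)), "lie in")
  expect_error(v(tibble::tibble(time_min = 1440L, amplitude = 1)), "lie in")
  expect_error(v(tibble::tibble(time_min = c(5L, 5L), amplitude = c(1, 1))),
               "strictly increasing")
  expect_error(v(tibble::tibble(time_min = 5L, amplitude = 0)), "positive")
  expect_error(v(good[0, ]), "no events")
  expect_equal(nrow(v(good[0, ], allow_empty = TRUE)), 0)
})

test_that("dense and sparse pulse-train views round-trip", {
  pt <- tibble::tibble(time_min = c(0L, 7L, 1439L), amplitude = c(2, 5, 1))
  u <- pulsedecon:::dense_input(pt)
  expect_length(u, 1440)
  expect_equal(sum(u > 0), 3)
  expect_equal(u[1], 2)
  expect_equal(pulsedecon:::pulse_train_from_dense(u), pt)
})

test_that("adjacent-minute detections merge into single events", {
  m <- pulsedecon:::merge_adjacent_pulses
  pt <- tibble::tibble(time_min = c(100L, 101L, 300L), amplitude = c(3, 1, 2))
  out <- m(pt)
  expect_equal(nrow(out), 2)
  expect_equal(out$amplitude, c(4, 2))
  expect_equal(out$time_min[1], 100L) # weighted mean 100.25 rounds down
  # non-adjacent events untouched
  pt2 <- tibble::tibble(time_min = c(100L, 102L), amplitude = c(1, 1))
  expect_equal(m(pt2), pt2)
  # a chain of adjacent minutes collapses to one event
  pt3 <- tibble::tibble(time_min = 10:13, amplitude = rep(1, 4))
  expect_equal(nrow(m(pt3)), 1)
  expect_equal(m(pt3)$amplitude, 4)
})

test_that("sparsity_count ignores dust below the relative threshold", {
  u <- c(10, 1e-9, 0, 2e-5)
  expect_equal(pulsedecon:::sparsity_count(u, 1e-6), 2L)
  expect_equal(pulsedecon:::sparsity_count(numeric(5)), 0L)
})
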