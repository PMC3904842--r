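# Independent numerical oracles used across the test files. None of these
# call into the package's own forward model or solvers.

# Numerically integrate the two-compartment ODE
#   dx1/dt = -theta1 * x1,   dx2/dt = theta1 * x1 - theta2 * x2
# with fixed-step 4th-order Runge-Kutta (deSolve), delivering amount q_j into
# compartment 1 at time tau_j via add-events, and x2(0) = y0. Returns x2 at
# the requested output times.
rk4_compartments <- function(theta1, theta2, times_out, pulse_times = numeric(),
                             pulse_amounts = numeric(), y0 = 0, step = 0.01) {
  grid <- seq(0, max(times_out), by = step)
  grid <- sort(unique(c(grid, times_out, pulse_times)))
  deriv <- function(t, x, parms) {
    list(c(-theta1 * x[1], theta1 * x[1] - theta2 * x[2]))
  }
  events <- NULL
  if (length(pulse_times)) {
    events <- list(data = data.frame(var = "x1", time = pulse_times,
                                     value = pulse_amounts, method = "add"))
  }
  sol <- deSolve::ode(y = c(x1 = 0, x2 = y0), times = grid, func = deriv,
                      parms = NULL, method = "rk4", events = events)
  sol[match(times_out, sol[, "time"]), "x2"]
}

# Exhaustive best-subset nonnegative least squares: minimum residual sum of
# squares over every support of size <= k_max, each solved by Lawson-Hanson
# NNLS (pracma::lsqnonneg).
best_subset_nnls_rss <- function(A, y, k_max) {
  best <- sum(y^2)
  for (sz in seq_len(k_max)) {
    for (S in utils::combn(ncol(A), sz, simplify = FALSE)) {
      fit <- pracma::lsqnonneg(A[, S, drop = FALSE], y)
      best <- min(best, fit$resid.norm)
    }
  }
  best
}

# Direct influence-matrix evaluation of the GCV score for the ridge
# estimator with weighted operator B = A W^(1/2):
#   H = B (B'B + lambda I)^(-1) B',  G = L ||(I-H) y||^2 / tr(I-H)^2.
gcv_direct <- function(B, y, lambda) {
  L <- length(y)
  H <- B %*% solve(crossprod(B) + lambda * diag(ncol(B)), t(B))
  r <- y - H %*% y
  L * sum(r^2) / (L - sum(diag(H)))^2
}

# Exhaustive one-to-one matching oracle: over all injective assignments of
# estimated to true pulses within the window, maximize the number of matched
# pairs and, among those, minimize the total absolute timing error. Returns
# the same metric triple as match_pulses().
brute_force_match <- function(true_times, est_times, window) {
  n_t <- length(true_times); n_e <- length(est_times)
  best <- list(n = -1L, total = Inf, maxerr = NA_real_)
  recurse <- function(i, used_e, n, total, maxerr) {
    if (i > n_t) {
      if (n > best$n || (n == best$n && total < best$total)) {
        best <<- list(n = n, total = total, maxerr = maxerr)
      }
      return(invisible())
    }
    recurse(i + 1L, used_e, n, total, maxerr) # leave true pulse i unmatched
    for (j in seq_len(n_e)) {
      d <- abs(true_times[i] - est_times[j])
      if (!used_e[j] && d <= window) {
        used_e[j] <- TRUE
        recurse(i + 1L, used_e, n + 1L, total + d, max(maxerr, d, na.rm = TRUE))
        used_e[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n_e), 0L, 0, NA_real_)
  list(max_timing_error = if (best$n > 0) best$maxerr else NA_real_,
       n_undetected = n_t - best$n,
       n_extra = n_e - best$n)
}

# A deterministic, well-separated 18-event train with circadian-sized
# amplitudes, used by the noise-free recovery checks.
well_separated_train <- function(seed = 1) {
  cfg <- pulse_gen_config(n_pulses_range = c(18L, 18L))
  generate_pulse_train(cfg, seed = seed)
}

# Minimal hand-built decon_fit carrying only the fields the evaluation
# functions read; lets metric arithmetic be tested without running the solver.
fake_decon_fit <- function(theta, pulses, n_obs = 144, dt = 10) {
  structure(
    list(theta_hat = kinetic_params(theta[1], theta[2]),
         pulses = pulses, n_pulses = nrow(pulses),
         r_squared = NA_real_, fitted = numeric(n_obs),
         residuals = numeric(n_obs), dt = dt),
    class = "decon_fit"
  )
}
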