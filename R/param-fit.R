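#' Penalized deconvolution cost
#'
#' The objective the coordinate descent minimizes: squared residual of the
#' sampled forward model plus an lp quasi-norm penalty on the input,
#' `||y - A(theta) u - b(theta) y0||^2 + lambda * sum(|u_i|^p)`. With
#' `0 < p < 1` the penalty approximates a count of nonzeros while remaining
#' continuous.
#'
#' @param theta A [kinetic_params()] object.
#' @param pulses A pulse train data frame (`time_min`, `amplitude`); may be
#'   empty.
#' @param observed Length-M vector of observed samples at `dt, 2*dt, ...`.
#' @param y0 Initial serum concentration at time 0.
#' @param lambda Penalty weight, `>= 0`.
#' @param p Quasi-norm exponent.
#' @param dt Sampling interval, minutes.
#'
#' @return The scalar cost, nonnegative.
#' @export
decon_cost <- function(theta, pulses, observed, y0, lambda, p = 0.5, dt = 10) {
  theta <- as_kinetic_params(theta)
  pulses <- validate_pulse_train(pulses, allow_empty = TRUE)
  fit <- forward_samples(theta, pulses$time_min, pulses$amplitude, y0,
                         length(observed), dt)
  sum((observed - fit)^2) + lambda * sum(pulses$amplitude^p)
}

# Residual sum of squares and its analytic gradient in (theta1, theta2) for
# fixed pulses. The kernel derivatives are closed-form, so the gradient of
# the fitted samples is an exact sum over events plus the y0 decay term.
theta_objective <- function(times, amplitudes, observed, y0, dt) {
  n_obs <- length(observed)
  t_k <- dt * seq_len(n_obs)
  lag <- if (length(times)) outer(t_k, times, "-") else matrix(0, n_obs, 0)
  pos <- lag > 0
  fn <- function(par) {
    th <- list(theta1 = par[1], theta2 = par[2])
    fit <- y0 * exp(-th$theta2 * t_k)
    if (length(times)) {
      h <- matrix(0, n_obs, length(times))
      h[pos] <- th$theta1 / (th$theta1 - th$theta2) *
        (exp(-th$theta2 * lag[pos]) - exp(-th$theta1 * lag[pos]))
      fit <- fit + drop(h %*% amplitudes)
    }
    sum((observed - fit)^2)
  }
  gr <- function(par) {
    th <- list(theta1 = par[1], theta2 = par[2])
    fit <- y0 * exp(-th$theta2 * t_k)
    d1 <- numeric(n_obs)
    d2 <- -y0 * t_k * exp(-th$theta2 * t_k)
    if (length(times)) {
      h <- g1 <- g2 <- matrix(0, n_obs, length(times))
      h[pos] <- th$theta1 / (th$theta1 - th$theta2) *
        (exp(-th$theta2 * lag[pos]) - exp(-th$theta1 * lag[pos]))
      gd <- impulse_response_grad(th, lag[pos])
      g1[pos] <- gd$d1
      g2[pos] <- gd$d2
      fit <- fit + drop(h %*% amplitudes)
      d1 <- d1 + drop(g1 %*% amplitudes)
      d2 <- d2 + drop(g2 %*% amplitudes)
    }
    r <- observed - fit
    c(-2 * sum(r * d1), -2 * sum(r * d2))
  }
  list(fn = fn, gr = gr)
}

#' Fit the kinetic parameters for a fixed pulse train
#'
#' Minimizes the residual sum of squares of the sampled forward model over the
#' feasible cone `theta1 >= 4 * theta2 >= 0` (constrained smooth local
#' minimization with the analytic gradient; compact upper bounds
#' `theta2 <= 0.25`/min and infusion excess `theta1 - 4*theta2 <= 1`/min keep
#' the feasible set bounded, far above any plausible cortisol kinetics). The
#' cone is handled exactly by optimizing over `(theta2, theta1 - 4*theta2)`
#' with box constraints. An infeasible starting point is projected into the cone
#' with a warning. The returned parameters never have a larger residual than
#' the starting point.
#'
#' @param observed Length-M vector of observed samples at `dt, 2*dt, ...`.
#' @param pulses Pulse train data frame (`time_min`, `amplitude`), held fixed.
#' @param y0 Initial serum concentration at time 0, held fixed.
#' @param theta_init Starting [kinetic_params()] (or anything coercible; an
#'   infeasible pair is projected, not rejected).
#' @param dt Sampling interval, minutes.
#'
#' @return A [kinetic_params()] object at the constrained local minimum.
#' @export
fit_theta <- function(observed, pulses, y0, theta_init, dt = 10) {
  pulses <- validate_pulse_train(pulses, allow_empty = TRUE)
  init <- project_to_cone(theta_init)
  obj <- theta_objective(pulses$time_min, pulses$amplitude, observed, y0, dt)

  # reparameterize the cone as a box: theta1 = 4*theta2 + delta with
  # theta2 in [eps, 0.25] and delta in [0, 1], so the feasibility constraint
  # is exact at every iterate and boundary optima are handled natively
  eps <- 1e-6
  fn2 <- function(par) obj$fn(c(4 * par[1] + par[2], par[1]))
  gr2 <- function(par) {
    g <- obj$gr(c(4 * par[1] + par[2], par[1]))
    c(4 * g[1] + g[2], g[1])
  }
  start <- c(init$theta2, init$theta1 - 4 * init$theta2)
  start[1] <- min(max(start[1], eps), 0.25)
  start[2] <- min(max(start[2], 0), 1)

  res <- stats::optim(start, fn = fn2, gr = gr2, method = "L-BFGS-B",
                      lower = c(eps, 0), upper = c(0.25, 1),
                      control = list(maxit = 500, factr = 1e3))
  par <- res$par
  # monotone-improvement contract; the projected start is always feasible
  if (fn2(par) > fn2(start)) par <- start
  kinetic_params(4 * par[1] + par[2], par[1])
}

# Variable-projection kinetic fit: at a fixed event support, the amplitudes
# are profiled out by unconstrained LS inside the objective, and the residual
# is minimized over theta on the cone (same box reparameterization as
# fit_theta). Profiling removes the amplitude/kinetics degeneracy that makes
# the fixed-amplitude alternation crawl. Returns list(theta, amplitudes)
# where amplitudes are the profiled LS values (may contain nonpositive
# entries; callers debias with nonneg_refit()).
fit_theta_profile <- function(observed, times, y0, theta_init, dt = 10) {
  init <- project_to_cone(theta_init)
  n_obs <- length(observed)
  t_k <- dt * seq_len(n_obs)
  lag <- if (length(times)) outer(t_k, times, "-") else matrix(0, n_obs, 0)
  pos <- lag > 0
  kernel <- function(t1, t2) {
    H <- matrix(0, n_obs, length(times))
    H[pos] <- t1 / (t1 - t2) * (exp(-t2 * lag[pos]) - exp(-t1 * lag[pos]))
    H
  }
  fn <- function(par) {
    t2 <- par[1]; t1 <- 4 * par[1] + par[2]
    yd <- observed - y0 * exp(-t2 * t_k)
    if (!length(times)) return(sum(yd^2))
    H <- kernel(t1, t2)
    x <- qr.solve(H, yd)
    sum((yd - H %*% x)^2)
  }
  eps <- 1e-6
  start <- c(min(max(init$theta2, eps), 0.25),
             min(max(init$theta1 - 4 * init$theta2, 0), 1))
  res <- stats::optim(start, fn, method = "L-BFGS-B",
                      lower = c(eps, 0), upper = c(0.25, 1),
                      control = list(maxit = 500, factr = 1e3))
  par <- if (fn(res$par) <= fn(start)) res$par else start
  theta <- kinetic_params(4 * par[1] + par[2], par[1])
  yd <- observed - y0 * exp(-theta$theta2 * t_k)
  amp <- if (length(times)) {
    drop(qr.solve(kernel(theta$theta1, theta$theta2), yd))
  } else numeric(0)
  list(theta = theta, amplitudes = amp)
}

# Unregularized nonnegative LS refit of the amplitudes on a detected support:
# solve LS, drop nonpositive entries, repeat. Removes the shrinkage bias the
# lp penalty leaves on the amplitudes (standard FOCUSS debiasing).
nnls_refit <- function(A, y, u, dust_rel = 1e-6) {
  out <- numeric(length(u))
  S <- which(u > dust_rel * max(u, 0))
  while (length(S)) {
    x <- qr.solve(A[, S, drop = FALSE], y)
    if (all(x > 0)) { out[S] <- x; break }
    S <- S[x > 0]
  }
  out
}

# Projects an arbitrary (theta1, theta2) pair into the feasible cone,
# warning when it actually moves.
project_to_cone <- function(theta) {
  if (is.list(theta) && all(c("theta1", "theta2") %in% names(theta))) {
    t1 <- theta$theta1; t2 <- theta$theta2
  } else if (is.numeric(theta) && length(theta) == 2L) {
    t1 <- theta[[1]]; t2 <- theta[[2]]
  } else {
    stop("cannot interpret `theta_init`", call. = FALSE)
  }
  t2_new <- min(max(t2, 1e-6), 0.25)
  t1_new <- min(max(t1, 4 * t2_new), 1)
  if (t1_new < 4 * t2_new) t2_new <- t1_new / 4
  if (abs(t1_new - t1) > 1e-12 || abs(t2_new - t2) > 1e-12) {
    warning("infeasible starting parameters projected onto the cone theta1 >= 4*theta2")
  }
  kinetic_params(t1_new, t2_new)
}
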