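#' Two-compartment kinetic parameters
#'
#' Constructs and validates the pair of first-order rate constants of the
#' two-compartment secretion model: `theta1`, the infusion rate from the
#' secretory (adrenal) compartment into the blood, and `theta2`, the
#' clearance rate of the hormone from the blood (hepatic elimination).
#' Physiological plausibility requires the infusion rate to be at least four
#' times the clearance rate, which also keeps the bi-exponential impulse
#' response away from its `theta1 == theta2` degeneracy.
#'
#' @param theta1 Infusion rate, 1/min. Must satisfy `theta1 >= 4 * theta2`.
#' @param theta2 Clearance rate, 1/min. Must be strictly positive.
#'
#' @return An object of class `kinetic_params`: a named list with elements
#'   `theta1` and `theta2`.
#' @examples
#' kinetic_params(0.0739, 0.0067)
#' @export
kinetic_params <- function(theta1, theta2) {
  stopifnot(is.numeric(theta1), length(theta1) == 1L, is.finite(theta1),
            is.numeric(theta2), length(theta2) == 1L, is.finite(theta2))
  if (theta2 <= 0) {
    stop("`theta2` must be strictly positive, got ", theta2, call. = FALSE)
  }
  if (theta1 < 4 * theta2) {
    stop("infeasible kinetic parameters: `theta1` (", theta1,
         ") must be at least 4 * `theta2` (", 4 * theta2, ")", call. = FALSE)
  }
  structure(list(theta1 = theta1, theta2 = theta2), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> theta1 = %.4g /min (infusion), theta2 = %.4g /min (clearance)\n",
              x$theta1, x$theta2))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(kinetic_params(x[[1]], x[[2]]))
  if (is.list(x) && all(c("theta1", "theta2") %in% names(x))) {
    return(kinetic_params(x$theta1, x$theta2))
  }
  stop("cannot interpret `theta` as kinetic parameters", call. = FALSE)
}

#' Impulse response of the two-compartment model
#'
#' Closed-form response of the serum concentration to a unit amount delivered
#' into the secretory compartment `lag` minutes earlier, with no hormone
#' stored in that compartment initially. Solving the two coupled first-order
#' equations gives the bi-exponential kernel
#' \deqn{h(t) = \frac{\theta_1}{\theta_1-\theta_2}\left(e^{-\theta_2 t} - e^{-\theta_1 t}\right),}
#' which is zero at lag 0 (mass takes time to transit the first compartment),
#' positive for any positive lag, and decays to zero at the clearance rate.
#'
#' @param theta A [kinetic_params()] object (or coercible).
#' @param lag Nonnegative lag(s), minutes. Vectorised.
#'
#' @return Serum concentration per unit impulse amount, same length as `lag`.
#' @examples
#' th <- kinetic_params(0.0739, 0.0067)
#' impulse_response(th, c(0, 10, 60))
#' @export
impulse_response <- function(theta, lag) {
  theta <- as_kinetic_params(theta)
  if (any(lag < 0)) stop("`lag` must be nonnegative", call. = FALSE)
  theta$theta1 / (theta$theta1 - theta$theta2) *
    (exp(-theta$theta2 * lag) - exp(-theta$theta1 * lag))
}

# Partial derivatives of the kernel w.r.t. theta, used by the analytic
# gradient of the parameter-fit objective. Returns list(d1, d2).
impulse_response_grad <- function(theta, lag) {
  t1 <- theta$theta1; t2 <- theta$theta2
  d <- t1 - t2
  e2 <- exp(-t2 * lag); e1 <- exp(-t1 * lag)
  diff <- e2 - e1
  list(
    d1 = -t2 / d^2 * diff + t1 / d * lag * e1,
    d2 =  t1 / d^2 * diff - t1 / d * lag * e2
  )
}

#' Discrete forward operator of the sampled deconvolution problem
#'
#' Builds the linear system `y = A u + b * y0` linking the minute-resolution
#' input train `u` (length `n_input`) to the noise-free samples at times
#' `dt, 2*dt, ..., n_obs*dt`. Entry `A[k, i]` is the impulse response at lag
#' `t_k - tau_i` for input minute `tau_i = i - 1` (zero when the impulse has
#' not yet occurred), and `b[k] = exp(-theta2 * t_k)` carries the decay of the
#' initial serum concentration `y0`.
#'
#' @param theta A [kinetic_params()] object.
#' @param n_obs Number of observed samples M (default 144, a 24-h profile).
#' @param n_input Length N of the minute input grid (default 1440).
#' @param dt Sampling interval, minutes (default 10).
#'
#' @return A list of class `forward_operator` with elements `A` (M x N
#'   matrix), `b` (length-M vector), `theta`, `dt`.
#' @export
forward_operator <- function(theta, n_obs = 144, n_input = 1440, dt = 10) {
  theta <- as_kinetic_params(theta)
  stopifnot(n_obs >= 1, n_input >= 1, dt > 0)
  t_k <- dt * seq_len(n_obs)
  tau <- seq_len(n_input) - 1
  # Toeplitz along the lag: evaluate the kernel once per distinct lag
  lag <- outer(t_k, tau, "-")
  A <- matrix(0, n_obs, n_input)
  pos <- lag > 0
  A[pos] <- impulse_response(theta, lag[pos])
  structure(
    list(A = A, b = exp(-theta$theta2 * t_k), theta = theta, dt = dt),
    class = "forward_operator"
  )
}

# Noise-free sample vector for a sparse input given as (times, amplitudes):
# sum over events of q * h(t_k - tau), plus the decaying initial condition.
# Avoids building the full M x N matrix; used in the parameter-fit inner loop.
forward_samples <- function(theta, times, amplitudes, y0, n_obs, dt) {
  t_k <- dt * seq_len(n_obs)
  y <- y0 * exp(-theta$theta2 * t_k)
  if (length(times)) {
    lag <- outer(t_k, times, "-")
    h <- matrix(0, n_obs, length(times))
    pos <- lag > 0
    h[pos] <- impulse_response(theta, lag[pos])
    y <- y + drop(h %*% amplitudes)
  }
  y
}

#' Simulate noise-free serum samples from a pulse train
#'
#' Forward-simulates the two-compartment model: each secretory event of
#' amount `q` at minute `tau` contributes `q * h(t_k - tau)` to the sample at
#' time `t_k`, and the initial serum level `y0` decays exponentially at the
#' clearance rate. Superposition holds exactly because the model is linear.
#'
#' @param theta A [kinetic_params()] object.
#' @param pulses A pulse train: data frame with columns `time_min` (integer
#'   minutes, strictly increasing) and `amplitude` (positive amounts), e.g.
#'   from [generate_pulse_train()]. May have zero rows.
#' @param y0 Initial serum concentration at time 0 (default 0).
#' @param n_obs Number of samples (default 144).
#' @param dt Sampling interval, minutes (default 10).
#'
#' @return A tibble with columns `time_min` (`dt, 2*dt, ...`) and
#'   `concentration` (noise-free samples). The time-0 row is not included;
#'   `y0` is the caller's initial condition, not a model output.
#' @examples
#' th <- kinetic_params(0.0739, 0.0067)
#' pt <- tibble::tibble(time_min = c(30L, 300L), amplitude = c(8, 12))
#' forward_simulate(th, pt, y0 = 5)
#' @export
forward_simulate <- function(theta, pulses, y0 = 0, n_obs = 144, dt = 10) {
  theta <- as_kinetic_params(theta)
  pulses <- validate_pulse_train(pulses, allow_empty = TRUE)
  y <- forward_samples(theta, pulses$time_min, pulses$amplitude, y0, n_obs, dt)
  tibble::tibble(time_min = dt * seq_len(n_obs), concentration = y)
}

# Checks the pulse-train contract: integer minutes in [0, 1439] strictly
# increasing, positive amplitudes. Returns the train as a plain tibble.
validate_pulse_train <- function(pulses, allow_empty = FALSE, n_input = 1440) {
  if (!is.data.frame(pulses) ||
      !all(c("time_min", "amplitude") %in% names(pulses))) {
    stop("a pulse train is a data frame with columns `time_min` and `amplitude`",
         call. = FALSE)
  }
  pulses <- tibble::as_tibble(pulses)[c("time_min", "amplitude")]
  if (nrow(pulses) == 0L) {
    if (!allow_empty) stop("pulse train has no events", call. = FALSE)
    return(pulses)
  }
  if (any(pulses$time_min != round(pulses$time_min))) {
    stop("pulse times must be integer minutes", call. = FALSE)
  }
  if (any(pulses$time_min < 0) || any(pulses$time_min > n_input - 1)) {
    stop("pulse times must lie in [0, ", n_input - 1, "] minutes", call. = FALSE)
  }
  if (is.unsorted(pulses$time_min, strictly = TRUE)) {
    stop("pulse times must be strictly increasing", call. = FALSE)
  }
  if (any(pulses$amplitude <= 0)) {
    stop("stored pulse amplitudes must be strictly positive", call. = FALSE)
  }
  pulses
}

# Dense length-N input vector from a pulse train, and back. The dense view
# is what the sparse solver operates on; the tibble is the user-facing form.
dense_input <- function(pulses, n_input = 1440) {
  u <- numeric(n_input)
  if (nrow(pulses)) u[pulses$time_min + 1L] <- pulses$amplitude
  u
}

pulse_train_from_dense <- function(u, dust_rel = 1e-6) {
  keep <- which(u > dust_rel * max(u, 0))
  tibble::tibble(time_min = keep - 1L, amplitude = u[keep])
}

# Merges recovered events at immediately adjacent minutes (gap of 1) into a
# single event at the amplitude-weighted minute with the summed amount. A
# secretory event is not resolvable to better than a minute from 10-minute
# samples, so adjacent-minute detections are one event split by the grid.
merge_adjacent_pulses <- function(pulses) {
  if (nrow(pulses) < 2) return(pulses)
  grp <- cumsum(c(1L, as.integer(diff(pulses$time_min) > 1L)))
  out <- dplyr::summarise(
    dplyr::group_by(pulses, grp = grp),
    time_min = as.integer(round(stats::weighted.mean(.data$time_min,
                                                     .data$amplitude))),
    amplitude = sum(.data$amplitude),
    .groups = "drop"
  )
  tibble::tibble(time_min = out$time_min, amplitude = out$amplitude)
}

# Count of effective nonzeros under the relative dust threshold: clipping and
# finite solver tolerance leave entries many orders below the real events.
sparsity_count <- function(u, dust_rel = 1e-6) {
  m <- max(abs(u), 0)
  if (m == 0) return(0L)
  sum(abs(u) > dust_rel * m)
}
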