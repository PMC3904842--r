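#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`: the fraction of the sample variance of the
#' observations predicted by the fitted series.
#'
#' @param observed,fitted Equal-length numeric vectors, length `>= 2`.
#'
#' @return A scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R-squared is undefined for constant observations", call. = FALSE)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Whiteness and normality diagnostics of fit residuals
#'
#' A well-specified fit leaves residuals that look like the assay noise:
#' serially uncorrelated and Gaussian. Returns the sample autocorrelation at
#' lags `1..max_lag` with the approximate 95% white-noise band
#' `+/- 1.96/sqrt(M)`, and the sorted residuals paired with standard normal
#' quantiles for a quantile-quantile check.
#'
#' @param residuals Numeric vector, length at least `max_lag + 2`, not all zero.
#' @param max_lag Largest autocorrelation lag. Default 20.
#'
#' @return A list of class `residual_diagnostics`: `acf` (tibble `lag`,
#'   `autocorrelation`), `band` (scalar half-width), `qq` (tibble
#'   `theoretical`, `sample`), `n`.
#' @export
residual_diagnostics <- function(residuals, max_lag = 20) {
  n <- length(residuals)
  stopifnot(max_lag >= 1, n >= max_lag + 2)
  if (all(residuals == 0) || stats::var(residuals) == 0) {
    stop("autocorrelation is undefined for constant residuals", call. = FALSE)
  }
  rho <- drop(stats::acf(residuals, lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  structure(
    list(
      acf = tibble::tibble(lag = seq_len(max_lag), autocorrelation = rho),
      band = 1.96 / sqrt(n),
      qq = tibble::tibble(theoretical = stats::qnorm(stats::ppoints(n)),
                          sample = sort(residuals)),
      n = n
    ),
    class = "residual_diagnostics"
  )
}

# Validates an observed series data frame and returns its pieces:
# y0 (time 0), observed vector, dt, n_obs. The input grid spans the
# observation window at 1-minute resolution.
series_pieces <- function(data) {
  if (!is.data.frame(data) ||
      !all(c("time_min", "concentration") %in% names(data))) {
    stop("`data` must have columns `time_min` and `concentration`", call. = FALSE)
  }
  if (nrow(data) < 3) stop("need at least an initial sample and two observations",
                           call. = FALSE)
  tm <- data$time_min
  if (is.unsorted(tm, strictly = TRUE)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  if (tm[1] != 0) stop("the first row must be the time-0 initial sample",
                       call. = FALSE)
  dts <- diff(tm)
  if (max(dts) - min(dts) > 1e-9) {
    stop("observations must be on a uniform grid; interpolate gaps first ",
         "(see read_series())", call. = FALSE)
  }
  if (anyNA(data$concentration)) {
    stop("missing concentrations; interpolate at load time (see read_series())",
         call. = FALSE)
  }
  list(y0 = data$concentration[1],
       observed = data$concentration[-1],
       dt = dts[1],
       n_obs = nrow(data) - 1L)
}

# One multi-start replicate of the estimation algorithm: random feasible
# initialization; 30 warm-up alternations of FOCUSS+ (all-ones init each
# pass) and the kinetic fit, keeping the penalized-cost-minimizing iterate;
# then coordinate descent alternating GCV-FOCUSS+ (all-ones init), a
# nonnegative LS debias of the amplitudes on the detected support, and a
# variable-projection kinetic fit, to joint convergence. Adjacent-minute
# detections are merged into single events at exit and the fit is polished
# once on the merged support.
run_single_start <- function(observed, y0, dt, n_obs, n_input, config,
                             warmup_iters = 30, max_sweeps = 100,
                             outer_tol = 1e-6) {
  # initialization brackets published cortisol kinetics:
  # theta2 ~ U(0.001, 0.02), theta1 ~ U(4*theta2, 0.15)
  t2 <- stats::runif(1, 0.001, 0.02)
  t1 <- stats::runif(1, 4 * t2, 0.15)
  theta <- kinetic_params(t1, t2)

  best <- list(cost = Inf)
  for (j in seq_len(warmup_iters)) {
    op <- forward_operator(theta, n_obs, n_input, dt)
    sol <- focuss_plus(op$A, observed - op$b * y0, config)
    support <- which(sol$u > config$dust_rel * max(sol$u, 0)) - 1L
    theta <- fit_theta_profile(observed, support, y0, theta, dt)$theta
    pulses <- pulse_train_from_dense(sol$u, config$dust_rel)
    cost_j <- decon_cost(theta, pulses, observed, y0, sol$lambda, config$p, dt)
    if (cost_j < best$cost) {
      best <- list(theta = theta, u = sol$u, lambda = sol$lambda, cost = cost_j)
    }
  }

  theta <- best$theta
  u <- best$u
  lambda <- best$lambda
  sweeps_used <- 0L
  for (sweep in seq_len(max_sweeps)) {
    sweeps_used <- sweep
    op <- forward_operator(theta, n_obs, n_input, dt)
    yd <- observed - op$b * y0
    sol <- gcv_focuss_plus(op$A, yd, config)
    lambda <- sol$lambda
    u_new <- nnls_refit(op$A, yd, sol$u, config$dust_rel)
    support <- which(u_new > 0) - 1L
    theta_new <- fit_theta_profile(observed, support, y0, theta, dt)$theta

    du <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)), .Machine$double.eps)
    dth <- sqrt((theta_new$theta1 - theta$theta1)^2 +
                (theta_new$theta2 - theta$theta2)^2) /
      sqrt(theta$theta1^2 + theta$theta2^2)
    u <- u_new
    theta <- theta_new
    if (max(du, dth) < outer_tol) break
  }

  # merge 1-minute split detections, then polish kinetics and amplitudes on
  # the merged support
  pulses <- merge_adjacent_pulses(pulse_train_from_dense(u, config$dust_rel))
  if (nrow(pulses)) {
    pol <- fit_theta_profile(observed, pulses$time_min, y0, theta, dt)
    theta <- pol$theta
    op <- forward_operator(theta, n_obs, n_input, dt)
    u <- numeric(n_input)
    u[pulses$time_min + 1L] <- pmax(pol$amplitudes, 0)
    u <- nnls_refit(op$A, observed - op$b * y0, u, config$dust_rel)
    pulses <- pulse_train_from_dense(u, config$dust_rel)
  }

  fitted <- forward_samples(theta, pulses$time_min, pulses$amplitude, y0,
                            n_obs, dt)
  rss <- sum((observed - fitted)^2)
  list(theta = theta, u = u, pulses = pulses, lambda = lambda,
       cost = rss + lambda * sum(pulses$amplitude^config$p),
       rss = rss, sparsity = nrow(pulses), sweeps = sweeps_used,
       fitted = fitted)
}

#' Deconvolve a sampled hormone series into sparse secretory events
#'
#' The full blind-deconvolution estimator. For each random start it draws
#' feasible kinetic parameters, alternates FOCUSS+ sparse recovery (input
#' initialized at all ones on every pass) with constrained kinetic fitting for
#' 30 warm-up iterations keeping the penalized-cost-minimizing iterate, then
#' runs coordinate descent: GCV-FOCUSS+ support detection, an unregularized
#' nonnegative amplitude refit on the detected support, and a
#' variable-projection kinetic fit, until the joint relative change of the
#' input and parameters falls below `1e-6` (at most 100 sweeps). Detections at
#' immediately adjacent minutes are merged into single events at exit (the
#' 10-minute samples cannot resolve events to better than a minute). Across
#' starts, the result whose final sparsity lies in the plausible range
#' `[n_min, n_max]` with the smallest residual sum of squares is returned;
#' if no start lands in the range, the smallest penalized cost wins
#' (penalized costs at different regularizations are not comparable, so the
#' residual is preferred whenever the sparsity constraint disambiguates).
#' Deterministic given `seed`.
#'
#' @param data A data frame with columns `time_min` and `concentration` on a
#'   uniform grid whose first row is the time-0 initial sample, e.g. from
#'   [read_series()] or [generate_dataset()].
#' @param config A [solver_config()].
#' @param n_starts Number of random initializations. Default 10.
#' @param seed Integer seed controlling the initializations.
#' @param n_input Length of the minute input grid; defaults to `dt * M` so the
#'   grid spans the observation window at 1-minute resolution.
#' @param warmup_iters Warm-up alternations per start. Default 30.
#' @param max_sweeps Cap on coordinate-descent sweeps. Default 100.
#'
#' @return An object of class `decon_fit`: a list with `theta_hat`
#'   ([kinetic_params()]), `pulses` (tibble `time_min`, `amplitude`),
#'   `fitted`, `residuals`, `observed` (the input data), `r_squared`,
#'   `final_lambda`, `final_cost`, `n_pulses`, `sparsity_in_range`,
#'   `n_starts_used`, `seed`, `config`, `starts` (per-start summary tibble).
#'   Supports [tidy()], [glance()], [augment()], and [ggplot2::autoplot()].
#' @export
deconvolve <- function(data, config = solver_config(), n_starts = 10,
                       seed = 1, n_input = NULL,
                       warmup_iters = 30, max_sweeps = 100) {
  stopifnot(n_starts >= 1)
  pieces <- series_pieces(data)
  if (is.null(n_input)) n_input <- as.integer(pieces$dt * pieces$n_obs)
  if (stats::var(pieces$observed) == 0) {
    warning("constant observations: returning an empty pulse train")
    empty <- tibble::tibble(time_min = integer(), amplitude = numeric())
    theta <- fit_theta(pieces$observed, empty, pieces$y0,
                       kinetic_params(0.08, 0.008), pieces$dt)
    fitted <- forward_samples(theta, integer(), numeric(), pieces$y0,
                              pieces$n_obs, pieces$dt)
    return(structure(
      list(theta_hat = theta, pulses = empty, fitted = fitted,
           residuals = pieces$observed - fitted,
           observed = tibble::as_tibble(data[c("time_min", "concentration")]),
           y0 = pieces$y0, dt = pieces$dt, r_squared = NA_real_,
           final_lambda = config$lambda_floor,
           final_cost = sum((pieces$observed - fitted)^2),
           n_pulses = 0L, sparsity_in_range = FALSE,
           n_starts_used = as.integer(n_starts), seed = as.integer(seed),
           config = config,
           starts = tibble::tibble(start = integer(), theta1 = numeric(),
                                   theta2 = numeric(), n_pulses = integer(),
                                   rss = numeric(), cost = numeric(),
                                   lambda = numeric(), sweeps = integer())),
      class = "decon_fit"))
  }

  set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max, n_starts)
  runs <- purrr::map(seq_len(n_starts), function(s) {
    set.seed(start_seeds[s])
    run_single_start(pieces$observed, pieces$y0, pieces$dt, pieces$n_obs,
                     n_input, config, warmup_iters, max_sweeps)
  })

  starts <- tibble::tibble(
    start = seq_len(n_starts),
    theta1 = purrr::map_dbl(runs, ~ .x$theta$theta1),
    theta2 = purrr::map_dbl(runs, ~ .x$theta$theta2),
    n_pulses = purrr::map_int(runs, ~ as.integer(.x$sparsity)),
    rss = purrr::map_dbl(runs, "rss"),
    cost = purrr::map_dbl(runs, "cost"),
    lambda = purrr::map_dbl(runs, "lambda"),
    sweeps = purrr::map_int(runs, ~ as.integer(.x$sweeps))
  )

  in_range <- starts$n_pulses >= config$n_min & starts$n_pulses <= config$n_max
  pick <- if (any(in_range)) {
    which(in_range)[which.min(starts$rss[in_range])]
  } else {
    which.min(starts$cost)
  }
  bestrun <- runs[[pick]]

  structure(
    list(
      theta_hat = bestrun$theta,
      pulses = bestrun$pulses,
      fitted = bestrun$fitted,
      residuals = pieces$observed - bestrun$fitted,
      observed = tibble::as_tibble(data[c("time_min", "concentration")]),
      y0 = pieces$y0,
      dt = pieces$dt,
      r_squared = r_squared(pieces$observed, bestrun$fitted),
      final_lambda = bestrun$lambda,
      final_cost = bestrun$cost,
      n_pulses = as.integer(bestrun$sparsity),
      sparsity_in_range = in_range[pick],
      n_starts_used = as.integer(n_starts),
      seed = as.integer(seed),
      config = config,
      starts = starts
    ),
    class = "decon_fit"
  )
}

#' @export
print.decon_fit <- function(x, ...) {
  cat("<decon_fit> sparse deconvolution of a sampled hormone series\n")
  cat(sprintf("  observations : %d samples every %g min (+ y0 = %.3g)\n",
              length(x$fitted), x$dt, x$y0))
  cat(sprintf("  theta1 (infusion)  : %.4f /min\n", x$theta_hat$theta1))
  cat(sprintf("  theta2 (clearance) : %.4f /min\n", x$theta_hat$theta2))
  cat(sprintf("  pulses : %d%s   R-squared : %.4f\n", x$n_pulses,
              if (x$sparsity_in_range) "" else " (outside plausible range)",
              x$r_squared))
  cat(sprintf("  lambda : %.4g   cost : %.4g   starts : %d   seed : %d\n",
              x$final_lambda, x$final_cost, x$n_starts_used, x$seed))
  invisible(x)
}
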