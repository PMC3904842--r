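#' Read a sampled hormone series from CSV
#'
#' Expects two columns, `time_min` and `concentration`, with the first row at
#' time 0 (the initial sample). The remaining rows must lie on a uniform grid;
#' rows missing from the interior of the grid, or present with an empty
#' concentration, are filled by linear interpolation. A missing first or last
#' value cannot be interpolated and is an error, as are unsorted or duplicated
#' times.
#'
#' @param path CSV file path.
#' @param dt Expected sampling interval, minutes. Default 10.
#'
#' @return A tibble with columns `time_min`, `concentration` on the complete
#'   grid, ready for [deconvolve()].
#' @export
read_series <- function(path, dt = 10) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_min", "concentration") %in% names(raw))) {
    stop("expected columns `time_min` and `concentration` in ", path,
         call. = FALSE)
  }
  tm <- raw$time_min
  if (anyNA(tm)) stop("missing times in ", path, call. = FALSE)
  dup <- anyDuplicated(tm)
  if (dup) stop("duplicate time at line ", dup + 1L, " of ", path, call. = FALSE)
  bad <- which(diff(tm) <= 0)
  if (length(bad)) {
    stop("times not increasing at line ", bad[1] + 2L, " of ", path,
         call. = FALSE)
  }
  if (tm[1] != 0) stop("first row must be the time-0 sample in ", path,
                       call. = FALSE)
  if (any(tm %% dt != 0)) {
    off <- which(tm %% dt != 0)[1]
    stop("time off the ", dt, "-minute grid at line ", off + 1L, " of ", path,
         call. = FALSE)
  }
  grid <- seq(0, max(tm), by = dt)
  conc <- raw$concentration[match(grid, tm)]
  if (is.na(conc[1]) || is.na(conc[length(conc)])) {
    stop("leading or trailing value missing in ", path,
         "; only interior gaps can be interpolated", call. = FALSE)
  }
  if (anyNA(conc)) {
    conc <- stats::approx(grid[!is.na(conc)], conc[!is.na(conc)],
                          xout = grid)$y
  }
  tibble::tibble(time_min = grid, concentration = conc)
}

#' Write / read a pulse train as CSV
#'
#' Two columns, `time_min` (ascending integer minutes) and `amplitude`.
#'
#' @param pulses Pulse-train data frame.
#' @param path CSV file path.
#' @return `write_pulses()` returns `path` invisibly; `read_pulses()` a tibble.
#' @export
write_pulses <- function(pulses, path) {
  pulses <- validate_pulse_train(pulses, allow_empty = TRUE)
  readr::write_csv(pulses, path)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  raw$time_min <- as.integer(raw$time_min)
  validate_pulse_train(raw, allow_empty = TRUE)
}

#' Write a deconvolution result to JSON
#'
#' Serializes every field of a `decon_fit` (including the seed and the full
#' solver configuration, so any result file identifies the run that produced
#' it) to a JSON file that [read_result()] restores losslessly.
#'
#' @param result A `decon_fit` from [deconvolve()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "decon_fit"))
  payload <- list(
    theta_hat = list(theta1 = result$theta_hat$theta1,
                     theta2 = result$theta_hat$theta2),
    pulses = as.list(result$pulses),
    fitted = result$fitted,
    residuals = result$residuals,
    observed = as.list(result$observed),
    y0 = result$y0,
    dt = result$dt,
    r_squared = result$r_squared,
    final_lambda = result$final_lambda,
    final_cost = result$final_cost,
    n_pulses = result$n_pulses,
    sparsity_in_range = result$sparsity_in_range,
    n_starts_used = result$n_starts_used,
    seed = result$seed,
    config = unclass(result$config),
    starts = as.list(result$starts)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# JSON text carries ~15 significant digits, so parameters that sit exactly on
# the cone boundary theta1 = 4*theta2 can re-read as infeasible by one part
# in 1e15; snap such round-off back onto the boundary before validating.
theta_from_json <- function(theta1, theta2) {
  if (theta1 < 4 * theta2 &&
      4 * theta2 - theta1 <= 1e-9 * max(theta1, 4 * theta2)) {
    theta1 <- 4 * theta2
  }
  kinetic_params(theta1, theta2)
}

#' Read a deconvolution result written by [write_result()]
#'
#' @param path JSON path.
#' @return A `decon_fit` object.
#' @export
read_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(solver_config, p$config[setdiff(names(p$config), character())])
  structure(
    list(
      theta_hat = theta_from_json(p$theta_hat$theta1, p$theta_hat$theta2),
      pulses = tibble::tibble(time_min = as.integer(p$pulses$time_min %||% integer()),
                              amplitude = as.numeric(p$pulses$amplitude %||% numeric())),
      fitted = as.numeric(p$fitted),
      residuals = as.numeric(p$residuals),
      observed = tibble::tibble(time_min = as.numeric(p$observed$time_min),
                                concentration = as.numeric(p$observed$concentration)),
      y0 = p$y0, dt = p$dt, r_squared = p$r_squared,
      final_lambda = p$final_lambda, final_cost = p$final_cost,
      n_pulses = as.integer(p$n_pulses),
      sparsity_in_range = p$sparsity_in_range,
      n_starts_used = as.integer(p$n_starts_used),
      seed = as.integer(p$seed),
      config = cfg,
      starts = tibble::as_tibble(p$starts)
    ),
    class = "decon_fit"
  )
}

#' Write / read simulation ground truth as JSON
#'
#' Stores the true kinetic parameters, pulse train, initial level, noise
#' standard deviation and seed of a synthetic dataset.
#'
#' @param theta True [kinetic_params()].
#' @param pulses True pulse train.
#' @param y0,sigma_nu,seed Simulation settings.
#' @param path JSON path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a list
#'   with elements `theta`, `pulses`, `y0`, `sigma_nu`, `seed`.
#' @export
write_truth <- function(theta, pulses, y0, sigma_nu, seed, path) {
  theta <- as_kinetic_params(theta)
  pulses <- validate_pulse_train(pulses)
  jsonlite::write_json(
    list(theta = list(theta1 = theta$theta1, theta2 = theta$theta2),
         pulses = as.list(pulses), y0 = y0, sigma_nu = sigma_nu, seed = seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    theta = theta_from_json(p$theta$theta1, p$theta$theta2),
    pulses = tibble::tibble(time_min = as.integer(p$pulses$time_min),
                            amplitude = as.numeric(p$pulses$amplitude)),
    y0 = p$y0, sigma_nu = p$sigma_nu, seed = as.integer(p$seed)
  )
}

#' Write a sampled series as CSV
#'
#' @param series Tibble with `time_min`, `concentration`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(all(c("time_min", "concentration") %in% names(series)))
  readr::write_csv(series[c("time_min", "concentration")], path)
  invisible(path)
}
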