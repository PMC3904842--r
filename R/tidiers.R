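#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a deconvolution fit into its estimated pulse train
#'
#' @param x A `decon_fit` from [deconvolve()].
#' @param ... Unused.
#' @return A tibble with one row per recovered secretory event: `time_min`,
#'   `amplitude`.
#' @export
tidy.decon_fit <- function(x, ...) {
  x$pulses
}

#' One-row summary of a deconvolution fit
#'
#' @param x A `decon_fit` from [deconvolve()].
#' @param ... Unused.
#' @return A one-row tibble: `theta1`, `theta2`, `n_pulses`, `r_squared`,
#'   `final_lambda`, `final_cost`, `sparsity_in_range`, `n_starts_used`,
#'   `seed`.
#' @export
glance.decon_fit <- function(x, ...) {
  tibble::tibble(
    theta1 = x$theta_hat$theta1,
    theta2 = x$theta_hat$theta2,
    n_pulses = x$n_pulses,
    r_squared = x$r_squared,
    final_lambda = x$final_lambda,
    final_cost = x$final_cost,
    sparsity_in_range = x$sparsity_in_range,
    n_starts_used = x$n_starts_used,
    seed = x$seed
  )
}

#' Observations with fitted values and residuals
#'
#' @param x A `decon_fit` from [deconvolve()].
#' @param ... Unused.
#' @return A tibble with one row per observed sample (the time-0 initial
#'   sample excluded): `time_min`, `concentration`, `.fitted`, `.resid`.
#' @export
augment.decon_fit <- function(x, ...) {
  tibble::tibble(
    time_min = x$observed$time_min[-1],
    concentration = x$observed$concentration[-1],
    .fitted = x$fitted,
    .resid = x$residuals
  )
}
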