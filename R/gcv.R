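#' Workspace for generalized cross-validation of a ridge-regularized solve
#'
#' Precomputes the pieces of the GCV function that do not depend on the
#' regularization parameter: the singular values of the (already weighted)
#' operator and the projection of the data onto its left singular basis.
#' For the reweighted solve `u = W A' (A W A' + lambda I)^{-1} y` the
#' influence matrix has eigenvalues `s_i^2 / (s_i^2 + lambda)` in that basis,
#' where `s_i` are the singular values of `A W^{1/2}`, so the GCV score can be
#' evaluated for any `lambda` in O(rank) time.
#'
#' @param A_weighted The column-weighted operator `A W^{1/2}` (L x r).
#' @param y Length-L data vector.
#'
#' @return A list of class `gcv_workspace`: `s` (singular values, descending),
#'   `beta` (coefficients of `y` in the left singular basis), `y_perp_sq`
#'   (squared norm of the part of `y` outside the column space), `L`.
#' @export
gcv_workspace <- function(A_weighted, y) {
  stopifnot(is.matrix(A_weighted), length(y) == nrow(A_weighted))
  L <- length(y)
  if (ncol(A_weighted) == 0L) {
    return(structure(list(s = numeric(0), beta = numeric(0),
                          y_perp_sq = sum(y^2), L = L),
                     class = "gcv_workspace"))
  }
  dec <- svd(A_weighted, nu = min(dim(A_weighted)), nv = 0)
  beta <- drop(crossprod(dec$u, y))
  structure(
    list(s = dec$d, beta = beta,
         y_perp_sq = max(0, sum(y^2) - sum(beta^2)), L = L),
    class = "gcv_workspace"
  )
}

#' Generalized cross-validation score
#'
#' Evaluates `G(lambda) = L * ||(I - H_lambda) y||^2 / tr(I - H_lambda)^2`
#' from a precomputed [gcv_workspace()]. In the left singular basis the
#' residual operator `I - H_lambda` acts as `lambda / (s_i^2 + lambda)` on
#' each component (and as the identity on the orthogonal complement), so
#' \deqn{\|(I-H_\lambda)y\|^2 = \sum_i \Big(\frac{\lambda}{s_i^2+\lambda}\Big)^2 \beta_i^2 + \|y_\perp\|^2,
#'   \quad \mathrm{tr}(I-H_\lambda) = L - \sum_i \frac{s_i^2}{s_i^2+\lambda}.}
#' Minimizing `G` over `lambda` balances residual error against the effective
#' degrees of freedom spent on fitting it, and is the criterion used to pick
#' the regularization (hence the recovered sparsity) at each solver iteration.
#'
#' @param workspace A [gcv_workspace()].
#' @param lambda Regularization parameter(s), nonnegative. Vectorised.
#'
#' @return The score(s), nonnegative.
#' @export
gcv_score <- function(workspace, lambda) {
  stopifnot(inherits(workspace, "gcv_workspace"), all(lambda >= 0))
  vapply(lambda, function(l) {
    shrink <- l / (workspace$s^2 + l)           # residual factor per component
    tr <- workspace$L - sum(1 - shrink)          # trace(I - H_lambda)
    if (abs(tr) < sqrt(.Machine$double.eps) * workspace$L) {
      stop("GCV score undefined: trace(I - H) is zero; use lambda above the search floor",
           call. = FALSE)
    }
    num <- sum((shrink * workspace$beta)^2) + workspace$y_perp_sq
    workspace$L * num / tr^2
  }, numeric(1))
}

#' Golden-section minimization of a unimodal scalar function
#'
#' Classic derivative-free bracketing search. For a unimodal `f` on
#' `[lower, upper]` it returns the minimizer to within `tol`; for a monotone
#' `f` it converges to the appropriate boundary. Used to minimize the GCV
#' score over the regularization range, where unimodality makes the search
#' reliable without derivatives.
#'
#' @param f Scalar function of one variable.
#' @param lower,upper Search interval, `lower < upper`.
#' @param tol Absolute tolerance on the minimizer location (default 1e-6).
#'
#' @return The approximate minimizer (scalar).
#' @examples
#' golden_section_min(function(x) (x - 3)^2, 0, 10)
#' @export
golden_section_min <- function(f, lower, upper, tol = 1e-6) {
  stopifnot(lower < upper, tol > 0)
  invphi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c <- b - invphi * (b - a)
  d <- a + invphi * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc <= fd) {
      b <- d; d <- c; fd <- fc
      c <- b - invphi * (b - a)
      fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + invphi * (b - a)
      fd <- f(d)
    }
  }
  (a + b) / 2
}
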