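#' Sparse-solver configuration
#'
#' Collects the tuning constants of the nonnegative sparse recovery. The
#' quasi-norm exponent `p` controls how aggressively the reweighting
#' concentrates energy (`p = 0.5` trades convexity for faster convergence to
#' genuinely sparse solutions); `n_max` caps the number of recovered events at
#' the physiological upper bound of secretory events per 24 h, and `n_min` is
#' the lower end of that plausible range (used when ranking candidate
#' solutions, not enforced during the iteration).
#'
#' @param p Quasi-norm exponent in (0, 2). Default 0.5.
#' @param n_max Maximum sparsity enforced by late-iteration pruning. Default 22.
#' @param n_min Lower end of the plausible sparsity range. Default 15.
#' @param lambda_floor Lower end of the regularization search range; strictly
#'   positive so the ridge solve and the GCV trace stay well-posed in double
#'   precision. Default 1e-8.
#' @param lambda_max Upper end of the regularization search range. Default 10.
#' @param max_iters Maximum reweighting iterations. Default 50 (the iteration
#'   typically converges in 10 to 50 steps).
#' @param tol Relative-change convergence tolerance on the iterate. Default 1e-6.
#' @param lambda_max_heuristic Scale of the heuristic regularization schedule
#'   used by [focuss_plus()]: `lambda = lambda_max_heuristic * max(0, 1 -
#'   ||y - A u|| / ||y||)`, so regularization grows towards its maximum as the
#'   residual shrinks. Default 1.
#' @param dust_rel Relative threshold below which an entry counts as zero:
#'   an entry is a nonzero of `u` iff it exceeds `dust_rel * max(u)`. Default 1e-6.
#'
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(p = 0.5, n_max = 22, n_min = 15,
                          lambda_floor = 1e-8, lambda_max = 10,
                          max_iters = 50, tol = 1e-6,
                          lambda_max_heuristic = 1, dust_rel = 1e-6) {
  stopifnot(p > 0, p < 2,
            lambda_floor > 0, lambda_floor < lambda_max,
            n_min <= n_max, n_min >= 1,
            max_iters >= 1, tol > 0, dust_rel > 0,
            lambda_max_heuristic >= 0)
  structure(
    list(p = p, n_max = as.integer(n_max), n_min = as.integer(n_min),
         lambda_floor = lambda_floor, lambda_max = lambda_max,
         max_iters = as.integer(max_iters), tol = tol,
         lambda_max_heuristic = lambda_max_heuristic, dust_rel = dust_rel),
    class = "solver_config"
  )
}

#' One FOCUSS reweighting step
#'
#' The focal underdetermined system solver refines an iterate by solving a
#' weighted minimum-norm problem: with `Pi = diag(|u_i|^(2-p))`, the update is
#' `u' = Pi A' (A Pi A' + lambda I)^{-1} y`, whose fixed points are stationary
#' points of the lp-penalized least-squares objective. Entries that are
#' exactly zero have zero weight and stay zero — the support can only shrink.
#'
#' @param A Forward matrix (L x N).
#' @param y Length-L data vector.
#' @param u Current iterate, length N.
#' @param p Quasi-norm exponent in (0, 2).
#' @param lambda Ridge regularization, `>= 0`. With `lambda = 0` the system
#'   `A Pi A'` must be numerically nonsingular.
#'
#' @return The updated iterate, length N.
#' @export
focuss_step <- function(A, y, u, p, lambda) {
  stopifnot(is.matrix(A), length(y) == nrow(A), length(u) == ncol(A),
            p > 0, p < 2, lambda >= 0, all(is.finite(u)))
  w <- abs(u)^(2 - p)
  active <- which(w > 0)
  out <- numeric(length(u))
  if (!length(active)) return(out)
  As <- A[, active, drop = FALSE]
  ws <- w[active]
  K <- tcrossprod(sweep(As, 2L, ws, `*`), As)
  diag(K) <- diag(K) + lambda
  x <- tryCatch(solve(K, y), error = function(e) {
    stop("reweighted system is numerically singular; use lambda at or above the search floor",
         call. = FALSE)
  })
  out[active] <- ws * drop(crossprod(As, x))
  out
}

# Shared iteration driving both focuss_plus() and gcv_focuss_plus().
# `lambda_rule(iter, u, active, A_active, w_active)` returns the
# regularization for this iteration; nonnegativity is enforced by clipping,
# the sparsity cap by pruning strictly after ceiling(max_iters / 2).
focuss_engine <- function(A, y, cfg, lambda_rule, u0 = NULL) {
  N <- ncol(A)
  if (all(y == 0)) {
    warning("all-zero observations: returning the zero input")
    return(list(u = numeric(N), lambda = cfg$lambda_floor, iterations = 0L,
                converged = TRUE,
                path = tibble::tibble(iteration = integer(), lambda = numeric(),
                                      sparsity = integer(), residual = numeric())))
  }
  u <- if (is.null(u0)) rep(1, N) else u0
  stopifnot(length(u) == N)
  u <- pmax(u, 0)
  prune_from <- ceiling(cfg$max_iters / 2)
  lambda <- cfg$lambda_floor
  converged <- FALSE
  it <- 0L
  path_lambda <- path_sparsity <- path_resid <- numeric(cfg$max_iters)
  for (it in seq_len(cfg$max_iters)) {
    # dust removal keeps the weighted system small and makes zeros absorbing
    m <- max(u)
    if (m == 0) { converged <- TRUE; it <- it - 1L; break }
    u[u <= cfg$dust_rel * m] <- 0
    active <- which(u > 0)
    As <- A[, active, drop = FALSE]
    w <- u[active]^(2 - cfg$p)

    lambda <- lambda_rule(it, u, active, As, w)

    K <- tcrossprod(sweep(As, 2L, w, `*`), As)
    dK <- diag(K)
    # if the ridge is below the numerical rank of A Pi A', raise it just
    # enough to keep the solve well-posed (the floor exists for this reason)
    x <- NULL
    lam_eff <- lambda
    repeat {
      diag(K) <- dK + lam_eff
      x <- tryCatch(solve(K, y), error = function(e) NULL)
      if (!is.null(x)) break
      lam_eff <- max(lam_eff * 100, mean(dK) * 1e-12)
    }
    lambda <- lam_eff
    u_new <- numeric(N)
    u_new[active] <- w * drop(crossprod(As, x))
    u_new <- pmax(u_new, 0)                        # nonnegativity

    if (it > prune_from && sparsity_count(u_new, cfg$dust_rel) > cfg$n_max) {
      # keep the n_max largest entries; ties broken by earlier time index
      ord <- order(-u_new, seq_along(u_new))
      u_new[ord[-seq_len(cfg$n_max)]] <- 0
    }

    nrm <- sqrt(sum(u^2))
    delta <- sqrt(sum((u_new - u)^2)) / max(nrm, .Machine$double.eps)
    resid <- y - drop(As %*% u_new[active])
    path_lambda[it] <- lambda
    path_sparsity[it] <- sparsity_count(u_new, cfg$dust_rel)
    path_resid[it] <- sqrt(sum(resid^2))
    u <- u_new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  # the cap is a contract at exit: if convergence preceded the pruning phase,
  # prune now and refit the surviving amplitudes at the last regularization
  if (sparsity_count(u, cfg$dust_rel) > cfg$n_max) {
    ord <- order(-u, seq_along(u))
    u[ord[-seq_len(cfg$n_max)]] <- 0
    u <- pmax(focuss_step(A, y, u, cfg$p, lambda), 0)
  }
  list(u = u, lambda = lambda, iterations = it, converged = converged,
       path = tibble::tibble(iteration = seq_len(it),
                             lambda = path_lambda[seq_len(it)],
                             sparsity = as.integer(path_sparsity[seq_len(it)]),
                             residual = path_resid[seq_len(it)]))
}

#' Nonnegative sparse recovery with a sparsity cap (FOCUSS+)
#'
#' Iterates the FOCUSS reweighting with three modifications that suit
#' nonnegative impulse trains: negative entries are clipped to zero after each
#' solve, the regularization follows a heuristic schedule that grows towards
#' `lambda_max_heuristic` as the relative residual shrinks, and strictly after
#' half the iteration budget any iterate with more than `n_max` nonzeros is
#' pruned to its `n_max` largest entries. The returned input is elementwise
#' nonnegative with at most `n_max` effective nonzeros.
#'
#' @inheritParams focuss_step
#' @param config A [solver_config()].
#' @param u0 Optional starting iterate (default: all ones, so every input
#'   minute starts with equal weight).
#'
#' @return A list: `u` (dense recovered input, length `ncol(A)`), `lambda`
#'   (last regularization used), `iterations`, `converged`, and `path` (a
#'   tibble tracing lambda, sparsity and residual norm per iteration).
#' @export
focuss_plus <- function(A, y, config = solver_config(), u0 = NULL) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  rule <- function(it, u, active, As, w) {
    resid <- sqrt(sum((y - drop(As %*% u[active]))^2))
    max(config$lambda_floor,
        config$lambda_max_heuristic * max(0, 1 - resid / sqrt(sum(y^2))))
  }
  focuss_engine(A, y, config, rule, u0)
}

#' Sparse recovery with GCV-selected regularization (GCV-FOCUSS+)
#'
#' The same iteration as [focuss_plus()], but at every reweighting step the
#' regularization parameter is chosen by minimizing the generalized
#' cross-validation score of the current weighted operator `A W^{1/2}` over
#' `[lambda_floor, lambda_max]` with a golden-section search. GCV balances
#' residual error against effective degrees of freedom, so the recovered
#' sparsity adapts to the noise level instead of being fixed in advance.
#'
#' @inheritParams focuss_plus
#'
#' @return As [focuss_plus()]; `lambda` is the GCV choice at the final
#'   iteration.
#' @export
gcv_focuss_plus <- function(A, y, config = solver_config(), u0 = NULL) {
  stopifnot(is.matrix(A), length(y) == nrow(A))
  rule <- function(it, u, active, As, w) {
    ws <- gcv_workspace(sweep(As, 2L, sqrt(w), `*`), y)
    golden_section_min(function(l) gcv_score(ws, l),
                       config$lambda_floor, config$lambda_max, tol = 1e-6)
  }
  focuss_engine(A, y, config, rule, u0)
}
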