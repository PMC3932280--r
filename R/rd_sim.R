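#' One-dimensional node-centered grid
#'
#' Uniform grid on `[0, length]` with `n` nodes including both endpoints,
#' spacing `dx = length/(n-1)`. Used for the no-flux interval domain.
#'
#' @param length domain size (length units), > 0.
#' @param n node count, >= 16.
#' @return An object of class `grid1d` with fields `length`, `n`, `dx`, `x`.
#' @export
grid1d <- function(length, n) {
  if (!is.finite(length) || length <= 0) stop("'length' must be positive", call. = FALSE)
  n <- as.integer(n)
  if (n < 16L) stop("'n' must be at least 16", call. = FALSE)
  dx <- length / (n - 1L)
  structure(list(length = length, n = n, dx = dx,
                 x = seq(0, length, length.out = n)),
            class = "grid1d")
}

#' Discrete Laplacian with no-flux (Neumann) boundaries
#'
#' Second-order central difference on a node-centered grid with mirrored
#' ghost nodes: the ghost value at index -1 equals the value at index 1 and
#' symmetrically at the right end, so the discrete normal derivative vanishes
#' at both boundaries. Constant fields map to zero exactly.
#'
#' @param values numeric vector, one value per grid node.
#' @param grid a [grid1d()].
#' @return Numeric vector of the same length.
#' @export
laplacian_neumann <- function(values, grid) {
  n <- grid$n
  if (length(values) != n)
    stop("'values' length must match the grid node count", call. = FALSE)
  if (n < 3L) stop("grid too coarse for a Laplacian stencil", call. = FALSE)
  out <- numeric(n)
  out[2:(n - 1L)] <- values[1:(n - 2L)] - 2 * values[2:(n - 1L)] + values[3:n]
  out[1L] <- 2 * (values[2L] - values[1L])
  out[n] <- 2 * (values[n - 1L] - values[n])
  out / grid$dx^2
}

#' Simulate the reaction-diffusion predator-prey system
#'
#' Method of lines: [laplacian_neumann()] in space, stiff adaptive time
#' integration of the resulting 2n-dimensional system with
#' [deSolve::ode.1D()] (banded Jacobian). Snapshots are recorded every
#' `save_every` time units. At each saved time, values in `[-1e-10, 0)` are
#' clamped to zero (solver round-off below the nonnegativity boundary);
#' anything below `-1e-10` aborts with a tolerance hint, since the continuous
#' system preserves nonnegativity and larger undershoots signal an unresolved
#' integration.
#'
#' @param params a [model_params()] (supplies `D1`, `D2`).
#' @param spec a [response_spec()].
#' @param grid a [grid1d()].
#' @param init list with numeric vectors `N` and `P` (one value per node),
#'   nonnegative.
#' @param t_end final time, > 0.
#' @param save_every snapshot spacing (time units), default 1.
#' @param rtol,atol solver tolerances.
#' @param seed optional integer recorded in the trajectory header (the
#'   simulator itself is deterministic; the seed documents how `init` was
#'   drawn).
#' @return An object of class `pp_trajectory`: `times`, `x`, matrices `N` and
#'   `P` (node x time), a per-time `summary` data.frame (min/max/mean/variance
#'   of each field), and the inputs.
#' @export
simulate_rd <- function(params, spec, grid, init, t_end,
                        save_every = 1, rtol = 1e-8, atol = 1e-11,
                        seed = NA_integer_) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "response_spec"),
            inherits(grid, "grid1d"))
  n <- grid$n
  if (length(init$N) != n || length(init$P) != n)
    stop("initial fields must have one value per grid node", call. = FALSE)
  if (any(init$N < 0) || any(init$P < 0))
    stop("initial fields must be nonnegative", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)

  idx2 <- 1:(n - 2L); dx2 <- grid$dx^2
  eps <- params$eps; K <- params$K; a <- params$a; b <- params$b
  gamma <- params$gamma; delta <- params$delta
  D1 <- params$D1; D2 <- params$D2
  phi <- spec$phi

  rhs <- function(t, y, p) {
    N <- y[1:n]; P <- y[(n + 1L):(2L * n)]
    Nc <- pmax(N, 0); Pc <- pmax(P, 0)
    lapN <- c(2 * (N[2L] - N[1L]),
              N[idx2] - 2 * N[idx2 + 1L] + N[idx2 + 2L],
              2 * (N[n - 1L] - N[n])) / dx2
    lapP <- c(2 * (P[2L] - P[1L]),
              P[idx2] - 2 * P[idx2 + 1L] + P[idx2 + 2L],
              2 * (P[n - 1L] - P[n])) / dx2
    pN <- phi(Nc)
    M <- (gamma + delta * Pc) / (1 + Pc)
    list(c(D1 * lapN + eps * (1 - Nc / K) * Nc - a * pN * Pc,
           D2 * lapP - M * Pc + b * pN * Pc))
  }

  times <- seq(0, t_end, by = save_every)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode.1D(y = c(init$N, init$P), times = times, func = rhs,
                         parms = NULL, nspec = 2L, dimens = n,
                         method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times))
    stop("PDE solver failed at t = ", sol[nrow(sol), 1],
         "; consider tightening rtol/atol", call. = FALSE)
  Nmat <- t(unname(sol[, 2:(n + 1L), drop = FALSE]))
  Pmat <- t(unname(sol[, (n + 2L):(2L * n + 1L), drop = FALSE]))
  if (any(!is.finite(Nmat)) || any(!is.finite(Pmat)))
    stop("non-finite field values produced by the solver", call. = FALSE)
  floor_val <- min(Nmat, Pmat)
  if (floor_val < -1e-10)
    stop(sprintf(paste0("negative density %.3e exceeds the clamping band; ",
                        "tighten solver tolerances"), floor_val), call. = FALSE)
  Nmat[Nmat < 0] <- 0
  Pmat[Pmat < 0] <- 0

  summ <- data.frame(
    t = times,
    minN = apply(Nmat, 2L, min), maxN = apply(Nmat, 2L, max),
    minP = apply(Pmat, 2L, min), maxP = apply(Pmat, 2L, max),
    meanN = colMeans(Nmat), meanP = colMeans(Pmat),
    varN = apply(Nmat, 2L, stats::var), varP = apply(Pmat, 2L, stats::var))

  structure(list(times = times, x = grid$x, N = Nmat, P = Pmat,
                 summary = summ, params = params, spec = spec, grid = grid,
                 seed = seed, energy = NULL),
            class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("Reaction-diffusion trajectory: %d nodes x %d saved times (t in [%g, %g])\n",
              x$grid$n, nt, x$times[1], x$times[nt]))
  cat(sprintf("  terminal: N in [%.6g, %.6g], P in [%.6g, %.6g]\n",
              x$summary$minN[nt], x$summary$maxN[nt],
              x$summary$minP[nt], x$summary$maxP[nt]))
  if (!is.na(x$seed)) cat("  init seed:", x$seed, "\n")
  invisible(x)
}

## indices of the tail window: last `window` fraction of saved times after a
## burn-in of max(10, 0.1 t_end) time units
tail_indices <- function(traj, window = 0.2) {
  t_end <- traj$times[length(traj$times)]
  burn <- max(10, 0.1 * t_end)
  keep <- which(traj$times >= burn)
  if (length(keep) < 2L)
    stop("trajectory too short for a tail window", call. = FALSE)
  keep[traj$times[keep] >= (1 - window) * t_end]
}

#' Verify the dissipativity bounds on a trajectory tail
#'
#' The system is dissipative: every solution eventually satisfies
#' \eqn{\max_x N \le K} and \eqn{\max_x P \le M_0} with
#' \eqn{M_0 = \varepsilon(K+1)/(a\phi(K+1))}. This diagnostic computes
#' \eqn{M_0} and checks both bounds (up to `tol`) over the tail window of a
#' simulated trajectory.
#'
#' @param traj a [simulate_rd()] trajectory.
#' @param tol slack added to both bounds (default 1e-3).
#' @param window tail-window fraction.
#' @return An object of class `dissipativity_verdict`.
#' @export
dissipativity_check <- function(traj, tol = 1e-3, window = 0.2) {
  params <- traj$params; spec <- traj$spec
  M0 <- params$eps * (params$K + 1) / (params$a * spec$phi(params$K + 1))
  idx <- tail_indices(traj, window)
  tail_max_N <- max(traj$summary$maxN[idx])
  tail_max_P <- max(traj$summary$maxP[idx])
  structure(list(M0 = M0,
                 tail_max_N = tail_max_N, tail_max_P = tail_max_P,
                 holds_N = tail_max_N <= params$K + tol,
                 holds_P = tail_max_P <= M0 + tol,
                 tol = tol, K = params$K),
            class = "dissipativity_verdict")
}

#' @export
print.dissipativity_verdict <- function(x, ...) {
  cat("Dissipativity (absorbing-set) check:\n")
  cat(sprintf("  tail max N = %.6g vs K = %g: %s\n", x$tail_max_N, x$K,
              if (x$holds_N) "within bound" else "EXCEEDS"))
  cat(sprintf("  tail max P = %.6g vs M0 = %.6g: %s\n", x$tail_max_P, x$M0,
              if (x$holds_P) "within bound" else "EXCEEDS"))
  invisible(x)
}

#' Empirical persistence margins from a trajectory tail
#'
#' Under permanence there exist positive constants \eqn{q \le N \le Q} and
#' \eqn{w \le P \le W} holding for all large times and all locations. This
#' returns the empirical surrogates: extrema of each field over all nodes and
#' the tail window.
#'
#' @param traj a [simulate_rd()] trajectory.
#' @param window tail-window fraction in (0, 1).
#' @return Named numeric vector `c(q, Q, w, W)`.
#' @export
persistence_margins <- function(traj, window = 0.2) {
  if (window <= 0 || window >= 1) stop("'window' must be in (0,1)", call. = FALSE)
  idx <- tail_indices(traj, window)
  c(q = min(traj$summary$minN[idx]), Q = max(traj$summary$maxN[idx]),
    w = min(traj$summary$minP[idx]), W = max(traj$summary$maxP[idx]))
}

#' Permanence/extinction regime from the parameters alone
#'
#' The system is permanent if and only if \eqn{-\gamma + b\phi(K) > 0}; when
#' the margin is \eqn{\le 0} the predator goes extinct and (K, 0) is globally
#' asymptotically stable. The verdict is independent of the diffusion
#' coefficients.
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @return An object of class `regime_verdict` with fields `regime`
#'   (`"permanent"` or `"extinction"`) and `margin` (\eqn{b\phi(K) - \gamma}).
#' @export
regime_check <- function(params, spec) {
  margin <- -params$gamma + params$b * spec$phi(params$K)
  structure(list(regime = if (margin > 0) "permanent" else "extinction",
                 margin = margin,
                 note = "verdict independent of D1, D2"),
            class = "regime_verdict")
}

#' @export
print.regime_verdict <- function(x, ...) {
  cat(sprintf("Regime: %s (margin b*phi(K) - gamma = %.6g; %s)\n",
              x$regime, x$margin, x$note))
  invisible(x)
}
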