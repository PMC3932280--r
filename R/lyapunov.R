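#' Lyapunov energy of a field pair relative to an interior equilibrium
#'
#' The energy functional
#' \deqn{E = \int_\Omega \left[ N - N_0 - N_0 \ln(N/N_0)
#'   + P - P_0 - P_0 \ln(P/P_0) \right] dx}
#' is nonnegative and vanishes exactly at the homogeneous state
#' \eqn{(N_0, P_0)}; it decreases along trajectories when the coexistence
#' state is globally stable. Computed by trapezoidal quadrature on the grid.
#'
#' @param N,P strictly positive field vectors (one value per node).
#' @param eq an interior `pp_equilibrium`.
#' @param grid a [grid1d()].
#' @return Nonnegative scalar.
#' @export
energy_E <- function(N, P, eq, grid) {
  if (any(N <= 0) || any(P <= 0))
    stop("energy undefined: fields must be strictly positive", call. = FALSE)
  N0 <- eq$N0; P0 <- eq$P0
  if (N0 <= 0 || P0 <= 0)
    stop("'eq' must be an interior equilibrium", call. = FALSE)
  f <- N - N0 - N0 * log(N / N0) + P - P0 - P0 * log(P / P0)
  n <- grid$n
  ## the integrand is pointwise >= 0; clamp quadrature round-off near zero
  max(sum((f[-1L] + f[-n]) / 2) * grid$dx, 0)
}

#' Lyapunov energy along a trajectory
#'
#' Evaluates [energy_E()] at every saved time of a trajectory, estimates
#' slopes by finite differences, and reports the fraction of steps on which
#' the energy is nonincreasing (within a slope tolerance
#' `1e-8 * max(E)` absorbing quadrature noise near zero). If a field drops to
#' the positivity floor at some saved time (e.g. predator extinction), the
#' series is truncated there with a warning: the logarithmic term is
#' meaningless as the field collapses to zero.
#'
#' @param traj a [simulate_rd()] trajectory.
#' @param eq an interior `pp_equilibrium`.
#' @param floor positivity floor below which a field counts as collapsed
#'   (default 1e-12).
#' @return An object of class `lyapunov_series`: `times`, `E_values`,
#'   `dE_estimates`, `monotone_fraction`, `truncated`.
#' @export
energy_series <- function(traj, eq, floor = 1e-12) {
  nt <- length(traj$times)
  pos <- which(apply(traj$N > floor, 2L, all) & apply(traj$P > floor, 2L, all))
  truncated <- FALSE
  last <- nt
  if (length(pos) == 0L)
    stop("no saved time has strictly positive fields", call. = FALSE)
  if (pos[length(pos)] != nt || length(pos) != nt) {
    ## keep the leading run of positive times only
    last <- if (any(diff(pos) > 1L)) pos[which(diff(pos) > 1L)[1L]] else pos[length(pos)]
    truncated <- last < nt
    if (truncated)
      warning("energy series truncated at t = ", traj$times[last],
              ": a field reached the positivity floor", call. = FALSE)
  }
  idx <- seq_len(last)
  E <- vapply(idx, function(i)
    energy_E(traj$N[, i], traj$P[, i], eq, traj$grid), numeric(1))
  dE <- diff(E) / diff(traj$times[idx])
  tol <- 1e-8 * max(E)
  structure(list(times = traj$times[idx], E_values = E, dE_estimates = dE,
                 monotone_fraction = mean(dE <= tol),
                 truncated = truncated),
            class = "lyapunov_series")
}

#' @export
print.lyapunov_series <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("Lyapunov energy series (%d times%s):\n", nt,
              if (x$truncated) ", truncated" else ""))
  cat(sprintf("  E(0) = %.6g -> E(%g) = %.6g; nonincreasing on %.1f%% of steps\n",
              x$E_values[1], x$times[nt], x$E_values[nt],
              100 * x$monotone_fraction))
  invisible(x)
}

#' Sufficient condition for global stability (symbolic branch)
#'
#' Evaluates the two left-hand sides of the sufficient condition for global
#' asymptotic stability of the coexistence state, given persistence bounds
#' \eqn{q \le N \le Q}, \eqn{w \le P \le W}. Under the default reading
#' (parse "A") of the collapsed fractions:
#' \deqn{c_1 = \frac{(q+N_0)\varepsilon}{KQ} - \varepsilon q
#'   - \frac{a\tilde M}{2} - \frac{b P_0 H}{2w},}
#' \deqn{c_2 = \frac{\gamma}{W} - bLw - \frac{b P_0 H}{2w}
#'   - \frac{a\tilde M}{2}.}
#' Parse "B" replaces the first term of \eqn{c_1} by
#' \eqn{(q+N_0)\varepsilon Q / K}. Both are recorded in the verdict; the
#' empirical energy-descent diagnostic ([energy_series()]) is the
#' authoritative check.
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @param eq an interior `pp_equilibrium`.
#' @param bounds named numeric `c(q, Q, w, W)`, all positive with `q <= Q`,
#'   `w <= W`.
#' @param parse which reading of the condition to use ("A" default, or "B").
#' @return An object of class `global_stability_verdict` (symbolic fields
#'   filled; empirical fields `NA` until combined by
#'   [global_stability_verdict()]).
#' @export
condition60_check <- function(params, spec, eq, bounds, parse = c("A", "B")) {
  parse <- match.arg(parse)
  q <- bounds[["q"]]; Q <- bounds[["Q"]]; w <- bounds[["w"]]; W <- bounds[["W"]]
  if (any(c(q, Q, w, W) <= 0) || Q < q || W < w)
    stop("'bounds' must be positive with q <= Q and w <= W", call. = FALSE)
  if (eq$label != "E3")
    stop("'eq' must be an interior equilibrium", call. = FALSE)
  N0 <- eq$N0; P0 <- eq$P0
  first <- switch(parse,
                  A = (q + N0) * params$eps / (params$K * Q),
                  B = (q + N0) * params$eps * Q / params$K)
  cond1 <- first - params$eps * q - params$a * spec$Mtilde / 2 -
    params$b * P0 * spec$H / (2 * w)
  cond2 <- params$gamma / W - params$b * spec$L * w -
    params$b * P0 * spec$H / (2 * w) - params$a * spec$Mtilde / 2
  structure(list(bounds = c(q = q, Q = Q, w = w, W = W),
                 condition_parse = parse,
                 cond1_value = cond1, cond2_value = cond2,
                 symbolic_holds = cond1 > 0 && cond2 > 0,
                 empirical_holds = NA, combined = NA_character_,
                 eq = c(N0 = N0, P0 = P0)),
            class = "global_stability_verdict")
}

#' Combined global-stability verdict
#'
#' Combines the symbolic sufficient condition ([condition60_check()], with
#' bounds taken from [persistence_margins()] deflated/inflated by a 0.9/1.1
#' safety factor) with the empirical Lyapunov diagnostic: `empirical_holds`
#' requires an energy monotone fraction >= 0.99, terminal spatial variance of
#' both fields < 1e-8, and a terminal state within 1e-2 of the equilibrium.
#' Requires a permanent regime and a unique interior equilibrium (the
#' symbolic condition presumes uniqueness; with several coexistence states it
#' is refused and only the empirical branch is reported).
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @param eq an interior `pp_equilibrium`, or `NULL` to locate it.
#' @param traj a [simulate_rd()] trajectory in the permanent regime.
#' @param parse condition parse label, see [condition60_check()].
#' @param bounds optional user override of the `(q, Q, w, W)` bounds.
#' @return A `global_stability_verdict` with both branches filled.
#' @export
global_stability_verdict <- function(params, spec, eq = NULL, traj,
                                     parse = "A", bounds = NULL) {
  reg <- regime_check(params, spec)
  if (reg$regime != "permanent")
    stop("global stability of a coexistence state requires the permanent ",
         "regime (b*phi(K) > gamma)", call. = FALSE)
  eqs <- find_equilibria(params, spec, warn_hypotheses = FALSE)
  interior <- Filter(function(e) e$label == "E3", eqs)
  multiple <- length(interior) > 1L
  if (is.null(eq)) {
    if (length(interior) == 0L) stop("no interior equilibrium found", call. = FALSE)
    eq <- interior[[1L]]
  }

  if (is.null(bounds)) {
    m <- persistence_margins(traj)
    bounds <- c(q = 0.9 * m[["q"]], Q = 1.1 * m[["Q"]],
                w = 0.9 * m[["w"]], W = 1.1 * m[["W"]])
  }
  symbolic <- if (multiple) NULL else
    condition60_check(params, spec, eq, bounds, parse = parse)

  es <- energy_series(traj, eq)
  nt <- length(traj$times)
  term_var <- max(traj$summary$varN[nt], traj$summary$varP[nt])
  term_dist <- max(abs(traj$N[, nt] - eq$N0), abs(traj$P[, nt] - eq$P0))
  empirical <- es$monotone_fraction >= 0.99 && term_var < 1e-8 &&
    term_dist < 1e-2

  out <- if (is.null(symbolic)) {
    structure(list(bounds = bounds, condition_parse = NA_character_,
                   cond1_value = NA_real_, cond2_value = NA_real_,
                   symbolic_holds = NA,
                   empirical_holds = empirical, combined = NA_character_,
                   eq = c(N0 = eq$N0, P0 = eq$P0)),
              class = "global_stability_verdict")
  } else symbolic
  out$empirical_holds <- empirical
  out$energy <- es
  out$terminal_variance <- term_var
  out$terminal_distance <- term_dist
  out$multiple_interior <- multiple
  out$combined <- if (multiple)
    "symbolic branch refused (multiple coexistence states); empirical branch only"
  else if (isTRUE(out$symbolic_holds) && empirical)
    "globally stable (symbolic condition holds; energy descends)"
  else if (empirical)
    "empirically convergent (energy descends); symbolic condition not verified"
  else "no evidence of global stability"
  out
}

#' @export
print.global_stability_verdict <- function(x, ...) {
  cat("Global stability verdict for (N0, P0) = (",
      sprintf("%.6g, %.6g", x$eq[["N0"]], x$eq[["P0"]]), "):\n", sep = "")
  if (!is.na(x$condition_parse))
    cat(sprintf("  symbolic (parse %s): cond1 = %.6g, cond2 = %.6g -> %s\n",
                x$condition_parse, x$cond1_value, x$cond2_value,
                if (isTRUE(x$symbolic_holds)) "holds" else "does not hold"))
  if (!is.na(x$empirical_holds))
    cat("  empirical energy descent:",
        if (isTRUE(x$empirical_holds)) "holds" else "not observed", "\n")
  if (!is.na(x$combined)) cat(" ", x$combined, "\n")
  invisible(x)
}
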