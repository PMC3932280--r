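#' Model parameters
#'
#' The eight scalar coefficients of the diffusive predator-prey model
#' \deqn{N_t = D_1 \Delta N + \varepsilon(1 - N/K)N - a\phi(N)P,}
#' \deqn{P_t = D_2 \Delta P - M(P)P + b\phi(N)P,}
#' with predator mortality \eqn{M(P) = (\gamma + \delta P)/(1 + P)} rising
#' from \eqn{\gamma} at low predator density toward \eqn{\delta} at high
#' density (standing assumption \eqn{0 < \gamma < \delta}).
#'
#' @param eps prey intrinsic growth rate (per time), > 0.
#' @param K prey carrying capacity (density), > 0.
#' @param a predation coefficient, > 0.
#' @param b conversion coefficient, > 0.
#' @param gamma low-density predator mortality (per time).
#' @param delta maximal predator mortality (per time), > gamma.
#' @param D1,D2 diffusion coefficients (length^2/time), >= 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(eps, K, a, b, gamma, delta, D1 = 0, D2 = 0) {
  vals <- c(eps = eps, K = K, a = a, b = b, gamma = gamma, delta = delta,
            D1 = D1, D2 = D2)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite numbers", call. = FALSE)
  if (any(vals[c("eps", "K", "a", "b")] <= 0))
    stop("'eps', 'K', 'a', 'b' must be positive", call. = FALSE)
  if (D1 < 0 || D2 < 0) stop("diffusion coefficients must be >= 0", call. = FALSE)
  if (!(gamma > 0 && gamma < delta))
    stop("mortality parameters must satisfy 0 < gamma < delta", call. = FALSE)
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Predator-prey model parameters:\n")
  cat(sprintf("  eps = %g, K = %g, a = %g, b = %g\n", x$eps, x$K, x$a, x$b))
  cat(sprintf("  mortality: gamma = %g -> delta = %g\n", x$gamma, x$delta))
  cat(sprintf("  diffusion: D1 = %g, D2 = %g\n", x$D1, x$D2))
  invisible(x)
}

#' Density-dependent predator mortality
#'
#' \eqn{M(P) = (\gamma + \delta P)/(1 + P)}, increasing from \eqn{\gamma} at
#' \eqn{P = 0} toward \eqn{\delta} as \eqn{P \to \infty}.
#'
#' @param P predator density (vectorized), >= 0.
#' @param params a [model_params()].
#' @return Mortality rate(s) in `[gamma, delta)`.
#' @export
mortality <- function(P, params) {
  if (any(P < 0)) stop("'P' must be nonnegative", call. = FALSE)
  (params$gamma + params$delta * P) / (1 + P)
}

## derivative M'(P) = (delta - gamma)/(1+P)^2, used in Jacobians
mortality_deriv <- function(P, params) (params$delta - params$gamma) / (1 + P)^2

#' Prey nullcline
#'
#' The nontrivial prey nullcline \eqn{P = f(N)} with
#' \eqn{f(N) = \varepsilon(1 - N/K)N / (a\phi(N))}. At \eqn{N = 0} the
#' singularity is removable and the limit \eqn{\varepsilon/(a\phi'(0))} is
#' returned (provided \eqn{\phi'(0) > 0}).
#'
#' @param N prey density (vectorized), in `[0, K]`.
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @return Nullcline value(s) \eqn{f(N)}.
#' @export
prey_nullcline_f <- function(N, params, spec) {
  if (any(N < 0) || any(N > params$K))
    stop("'N' must lie in [0, K]", call. = FALSE)
  out <- numeric(length(N))
  zero <- N == 0
  if (any(zero)) {
    d0 <- spec$dphi(0)
    if (d0 <= 0)
      stop("singular limit at N = 0: phi'(0) must be positive", call. = FALSE)
    out[zero] <- params$eps / (params$a * d0)
  }
  if (any(!zero)) {
    Np <- N[!zero]
    pN <- spec$phi(Np)
    if (any(pN <= 0))
      stop("phi(N) must be positive for N > 0 on the nullcline", call. = FALSE)
    out[!zero] <- params$eps * (1 - Np / params$K) * Np / (params$a * pN)
  }
  out
}

## derivative of the prey nullcline f(N) = g(N)/(a phi(N)) with
## g(N) = eps (1 - N/K) N, by the quotient rule (not the garbled printed form):
## f'(N) = (g'(N) phi(N) - g(N) phi'(N)) / (a phi(N)^2)
prey_nullcline_df <- function(N, params, spec) {
  g  <- params$eps * (1 - N / params$K) * N
  dg <- params$eps * (1 - 2 * N / params$K)
  p  <- spec$phi(N)
  (dg * p - g * spec$dphi(N)) / (params$a * p^2)
}

#' Reaction right-hand side of the reduced ODE system
#'
#' \eqn{dN/dt = \varepsilon(1 - N/K)N - a\phi(N)P},
#' \eqn{dP/dt = -M(P)P + b\phi(N)P}. Vectorized over states.
#'
#' @param N,P densities, >= 0.
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @return A list with components `dN` and `dP`.
#' @export
ode_rhs <- function(N, P, params, spec) {
  if (any(N < 0) || any(P < 0))
    stop("densities must be nonnegative", call. = FALSE)
  pN <- spec$phi(N)
  list(dN = params$eps * (1 - N / params$K) * N - params$a * pN * P,
       dP = -mortality(P, params) * P + params$b * pN * P)
}

#' Locate all equilibria of the reduced ODE system
#'
#' The boundary equilibria E1 = (0, 0) and E2 = (K, 0) are always present.
#' Interior equilibria are the roots \eqn{N_0 \in (0, K)} of
#' \eqn{g(N) = b\phi(N) - M(f(N))} with \eqn{P_0 = f(N_0) > 0}, located by a
#' uniform sign-change scan followed by bisection ([stats::uniroot()]).
#' When \eqn{-\gamma + b\phi(K) \le 0} no interior equilibrium exists (the
#' extinction regime) and only E1, E2 are returned. Hump-shaped responses
#' (Holling type IV) can yield several interior equilibria; all are returned,
#' sorted by prey coordinate.
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @param scan_n points in the sign-change scan (default 1e4).
#' @param classify logical: classify each equilibrium (default TRUE).
#' @param warn_hypotheses warn when [verify_hypotheses()] fails for
#'   `(spec, K)` (default TRUE).
#' @return A list of `pp_equilibrium` objects, class `pp_equilibria`.
#' @examples
#' par <- model_params(eps = 1, K = 2, a = 1, b = 1, gamma = 0.4, delta = 0.6)
#' find_equilibria(par, holling2(1))  # E3 = (1, 1)
#' @export
find_equilibria <- function(params, spec, scan_n = 1e4, classify = TRUE,
                            warn_hypotheses = TRUE) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "response_spec"))
  if (warn_hypotheses) {
    rep <- verify_hypotheses(spec, params$K)
    if (!rep$all_satisfied)
      warning("response hypotheses not all satisfied for this (phi, K); ",
              "equilibrium theory may not apply", call. = FALSE)
  }
  eqs <- list(
    new_equilibrium(0, 0, "E1", params, spec),
    new_equilibrium(params$K, 0, "E2", params, spec))

  margin <- -params$gamma + params$b * spec$phi(params$K)
  if (margin > 0) {
    epsN <- 1e-9 * params$K
    Ngrid <- seq(epsN, params$K - epsN, length.out = scan_n)
    g <- params$b * spec$phi(Ngrid) -
      mortality(pmax(prey_nullcline_f(Ngrid, params, spec), 0), params)
    sgn <- sign(g)
    flip <- which(sgn[-1] * sgn[-scan_n] < 0)
    gfun <- function(N)
      params$b * spec$phi(N) -
        mortality(max(prey_nullcline_f(N, params, spec), 0), params)
    roots <- vapply(flip, function(i) {
      stats::uniroot(gfun, c(Ngrid[i], Ngrid[i + 1L]),
                     tol = 1e-12 * params$K)$root
    }, numeric(1))
    ## exact zeros on the grid (rare ties)
    roots <- sort(unique(c(roots, Ngrid[g == 0])))
    for (N0 in roots) {
      P0 <- prey_nullcline_f(N0, params, spec)
      if (P0 > 0)
        eqs[[length(eqs) + 1L]] <- new_equilibrium(N0, P0, "E3", params, spec)
    }
  }
  if (classify) eqs <- lapply(eqs, classify_equilibrium, params = params)
  structure(eqs, class = "pp_equilibria")
}

## construct an equilibrium record with Jacobian, spectrum and residual
new_equilibrium <- function(N0, P0, label, params, spec) {
  rhs <- ode_rhs(N0, P0, params, spec)
  J <- jacobian(c(N0, P0), params, spec, warn = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    list(N0 = N0, P0 = P0, label = label, jac = J,
         trace = J[1, 1] + J[2, 2],
         det = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
         eigenvalues = ev,
         residual = max(abs(c(rhs$dN, rhs$dP))),
         classification = NA_character_,
         prop1_certificate = label == "E3" &&
           N0 >= params$K / 2 && N0 <= params$K),
    class = "pp_equilibrium")
}

#' Jacobian of the reduced ODE system at a point
#'
#' At E1 = (0,0) the Jacobian is \eqn{diag(\varepsilon, -\gamma)}; at
#' E2 = (K,0) it is upper triangular with diagonal
#' \eqn{(-\varepsilon, -\gamma + b\phi(K))}. At interior equilibria the
#' entries are \eqn{J_{11} = a\phi(N_0)f'(N_0)}, \eqn{J_{12} = -a\phi(N_0)},
#' \eqn{J_{21} = bP_0\phi'(N_0)}, \eqn{J_{22} = -P_0 M'(P_0)}, with \eqn{f'}
#' the analytic derivative of the prey nullcline.
#'
#' @param point numeric length-2 vector `(N, P)`.
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @param warn warn when the point is not an equilibrium (residual > 1e-8).
#' @return A 2x2 numeric matrix.
#' @export
jacobian <- function(point, params, spec, warn = TRUE) {
  N0 <- point[1]; P0 <- point[2]
  if (warn) {
    rhs <- ode_rhs(N0, P0, params, spec)
    if (max(abs(c(rhs$dN, rhs$dP))) > 1e-8)
      warning("point is not an equilibrium (residual > 1e-8); ",
              "the closed-form interior Jacobian assumes P0 = f(N0)",
              call. = FALSE)
  }
  if (N0 == 0 && P0 == 0)
    return(matrix(c(params$eps, 0, 0, -params$gamma), 2, 2))
  if (P0 == 0 && isTRUE(all.equal(N0, params$K)))
    return(matrix(c(-params$eps, 0,
                    -params$a * spec$phi(params$K),
                    -params$gamma + params$b * spec$phi(params$K)), 2, 2))
  pN <- spec$phi(N0)
  matrix(c(params$a * pN * prey_nullcline_df(N0, params, spec),
           params$b * P0 * spec$dphi(N0),
           -params$a * pN,
           -P0 * mortality_deriv(P0, params)), 2, 2)
}

#' Classify an equilibrium by its Jacobian spectrum
#'
#' Standard planar classification: saddle when det < 0; otherwise by sign of
#' the trace and the discriminant \eqn{trace^2 - 4 det} (node vs spiral).
#' `|trace|` or `|det|` below 1e-12 yields "nonhyperbolic" (no stability
#' claim). For interior equilibria with \eqn{N_0 \in [K/2, K]} the certificate
#' `prop1_certificate` is set: in that range \eqn{f'(N_0) \le 0} and
#' \eqn{M'(P_0) > 0} force trace < 0 and det > 0, so local asymptotic
#' stability is guaranteed analytically; the numeric classification is checked
#' for agreement.
#'
#' @param eq a `pp_equilibrium`.
#' @param params a [model_params()].
#' @return The equilibrium with `classification` filled.
#' @export
classify_equilibrium <- function(eq, params) {
  tol <- 1e-12
  tr <- eq$trace; dt <- eq$det
  cls <-
    if (abs(dt) < tol || (dt > 0 && abs(tr) < tol)) "nonhyperbolic"
    else if (dt < 0) "saddle"
    else {
      disc <- tr^2 - 4 * dt
      if (tr < 0) { if (disc >= 0) "stable-node" else "stable-spiral" }
      else        { if (disc >= 0) "unstable-node" else "unstable-spiral" }
    }
  eq$classification <- cls
  if (isTRUE(eq$prop1_certificate) &&
      !(cls %in% c("stable-node", "stable-spiral")))
    warning("interior equilibrium with N0 in [K/2, K] not classified stable; ",
            "numerical classification disagrees with the analytic guarantee",
            call. = FALSE)
  eq
}

#' @export
print.pp_equilibrium <- function(x, ...) {
  cat(sprintf("%s = (%.10g, %.10g): %s\n", x$label, x$N0, x$P0,
              x$classification))
  cat(sprintf("  trace = %.6g, det = %.6g, eigenvalues = %s\n",
              x$trace, x$det,
              paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  if (isTRUE(x$prop1_certificate))
    cat("  analytic stability certificate: N0 in [K/2, K]\n")
  invisible(x)
}

#' @export
print.pp_equilibria <- function(x, ...) {
  cat("Equilibria of the reduced ODE system:\n")
  for (eq in x) print(eq)
  invisible(x)
}

#' Integrate the reduced ODE system
#'
#' Adaptive stiff integration ([deSolve::ode()], `lsoda`) of the reaction
#' system from a strictly positive initial state. Defaults (`rtol = 1e-9`,
#' `atol = 1e-12`) are tight so that downstream Lyapunov diagnostics see a
#' smooth energy decay.
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()].
#' @param init numeric length-2, initial `(N, P)`, nonnegative.
#' @param t_end final time, > 0.
#' @param dt output sampling interval.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `t`, `N`, `P`.
#' @export
integrate_ode <- function(params, spec, init, t_end, dt = t_end / 500,
                          rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "response_spec"))
  if (length(init) != 2L || any(init < 0))
    stop("'init' must be a nonnegative (N, P) pair", call. = FALSE)
  if (t_end <= 0) stop("'t_end' must be positive", call. = FALSE)
  f <- function(t, y, p) {
    y <- pmax(y, 0)
    r <- ode_rhs(y[1], y[2], params, spec)
    list(c(r$dN, r$dP))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(N = init[1], P = init[2]), times = times,
                      func = f, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("t", "N", "P")
  out$N <- pmax(out$N, 0); out$P <- pmax(out$P, 0)
  out
}
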