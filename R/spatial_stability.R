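#' Neumann eigenvalues of the interval Laplacian
#'
#' Eigenvalues of \eqn{-\Delta} on an interval of the given length with
#' no-flux boundaries: \eqn{\lambda_j = (j\pi/\ell)^2}, \eqn{j = 0, 1, \dots},
#' with \eqn{\lambda_0 = 0} and the spectrum strictly increasing.
#'
#' @param length domain size, > 0.
#' @param j_max largest mode index, >= 1.
#' @return Numeric vector of `j_max + 1` eigenvalues starting at 0.
#' @export
neumann_spectrum <- function(length, j_max) {
  if (length <= 0) stop("'length' must be positive", call. = FALSE)
  if (j_max < 1) stop("'j_max' must be at least 1", call. = FALSE)
  ((0:j_max) * pi / length)^2
}

#' Mode-wise linearization matrix
#'
#' For the linearization about a homogeneous steady state with reaction
#' Jacobian `A`, the spatial mode with Laplacian eigenvalue \eqn{\lambda_j}
#' evolves by \eqn{B_j = A - \lambda_j \, diag(D_1, D_2)}. The mode is stable
#' when both eigenvalues of \eqn{B_j} have negative real parts.
#'
#' @param A 2x2 reaction Jacobian.
#' @param lambda_j Laplacian eigenvalue, >= 0.
#' @param D1,D2 diffusion coefficients.
#' @param j optional mode index for the report.
#' @return An object of class `mode_report` with `Bj`, `trace`, `det`,
#'   `eigenvalues`, `stable`.
#' @export
linearized_matrix <- function(A, lambda_j, D1, D2, j = NA_integer_) {
  if (lambda_j < 0) stop("'lambda_j' must be >= 0", call. = FALSE)
  Bj <- A - lambda_j * diag(c(D1, D2))
  ev <- eigen(Bj, only.values = TRUE)$values
  structure(list(j = j, lambda_j = lambda_j, Bj = Bj,
                 trace = Bj[1, 1] + Bj[2, 2],
                 det = Bj[1, 1] * Bj[2, 2] - Bj[1, 2] * Bj[2, 1],
                 eigenvalues = ev,
                 stable = all(Re(ev) < 0)),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat(sprintf("Mode %s (lambda = %.6g): trace = %.6g, det = %.6g -> %s\n",
              if (is.na(x$j)) "?" else x$j, x$lambda_j, x$trace, x$det,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

## analytic cutoff lambda* beyond which every mode of (A, D) is stable:
## trace(B_lambda) = trace(A) - lambda (D1+D2) is negative beyond its root,
## and det(B_lambda) = D1 D2 lambda^2 - (A11 D2 + A22 D1) lambda + det(A) is
## an upward parabola (D1 D2 > 0) positive beyond its largest real root.
mode_cutoff <- function(A, D1, D2) {
  trA <- A[1, 1] + A[2, 2]
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  cut_tr <- if (D1 + D2 > 0) max(0, trA / (D1 + D2)) else 0
  cut_det <- 0
  if (D1 * D2 > 0) {
    bq <- A[1, 1] * D2 + A[2, 2] * D1
    disc <- bq^2 - 4 * D1 * D2 * detA
    if (disc >= 0) cut_det <- max(0, (bq + sqrt(disc)) / (2 * D1 * D2))
  }
  1.1 * max(cut_tr, cut_det)
}

#' Linearized stability of a homogeneous steady state over all Neumann modes
#'
#' Scans the mode matrices \eqn{B_j = A - \lambda_j D} for all \eqn{j} with
#' \eqn{\lambda_j \le \lambda^*}, where the analytic cutoff \eqn{\lambda^*}
#' guarantees stability of every higher mode (the trace is eventually negative
#' and, when \eqn{D_1 D_2 > 0}, the determinant is an upward parabola in
#' \eqn{\lambda}; with a degenerate diffusion pair the scan falls back to a
#' fixed range \eqn{\lambda \le 10^4/\ell^2}). The steady state is linearly
#' stable for the PDE iff every mode is stable. When the interior equilibrium
#' satisfies \eqn{N_0 \in [K/2, K]}, stability over all modes is guaranteed
#' analytically (the sign pattern \eqn{A_{11}, A_{22}, A_{12} < 0},
#' \eqn{A_{21} > 0} makes every trace negative and every determinant
#' positive); the scan is cross-checked against that certificate.
#'
#' @param params a [model_params()] (supplies `D1`, `D2`).
#' @param spec a [response_spec()].
#' @param eq an interior `pp_equilibrium` (label "E3").
#' @param length domain size.
#' @return An object of class `homogeneous_stability` with the per-mode
#'   reports, overall `stable` flag, `certificate` (the analytic guarantee)
#'   and the cutoff used.
#' @export
homogeneous_stability <- function(params, spec, eq, length) {
  stopifnot(inherits(eq, "pp_equilibrium"))
  if (eq$label != "E3")
    stop("'eq' must be an interior equilibrium (E3)", call. = FALSE)
  A <- eq$jac; D1 <- params$D1; D2 <- params$D2
  if (D1 == 0 && D2 == 0) {
    modes <- list(linearized_matrix(A, 0, 0, 0, j = 0L))
    cutoff <- 0
  } else {
    cutoff <- mode_cutoff(A, D1, D2)
    if (D1 * D2 == 0) cutoff <- max(cutoff, 1e4 / length^2)
    j_max <- max(1L, ceiling(length * sqrt(cutoff) / pi))
    lam <- neumann_spectrum(length, j_max)
    modes <- lapply(seq_along(lam), function(i)
      linearized_matrix(A, lam[i], D1, D2, j = i - 1L))
  }
  inconclusive <- any(vapply(modes, function(m) abs(m$det) < 1e-12, logical(1)))
  stable <- all(vapply(modes, function(m) m$stable, logical(1)))
  cert <- isTRUE(eq$prop1_certificate)
  if (cert && !stable)
    warning("mode scan disagrees with the analytic stability certificate ",
            "(N0 in [K/2, K]); check the equilibrium residual", call. = FALSE)
  structure(list(modes = modes, stable = stable,
                 inconclusive = inconclusive, certificate = cert,
                 cutoff = cutoff, length = length, eq = eq),
            class = "homogeneous_stability")
}

#' @export
print.homogeneous_stability <- function(x, ...) {
  cat(sprintf("Homogeneous steady state (N0, P0) = (%.6g, %.6g):\n",
              x$eq$N0, x$eq$P0))
  cat(sprintf("  %d modes scanned up to lambda* = %.6g\n",
              length(x$modes), x$cutoff))
  cat("  verdict:", if (x$inconclusive) "inconclusive (near-nonhyperbolic mode)"
      else if (x$stable) "linearly stable for the PDE" else "UNSTABLE", "\n")
  if (x$certificate)
    cat("  analytic certificate: N0 in [K/2, K] => stable for all D1, D2\n")
  invisible(x)
}

#' Scan for a diffusion-driven (Turing) instability window
#'
#' For an ODE-stable Jacobian `A`, diffusion destabilizes a mode exactly when
#' \eqn{det(A - \lambda D) < 0} for some \eqn{\lambda > 0} (the trace only
#' decreases with \eqn{\lambda}). Scans a logarithmic \eqn{\lambda} grid and
#' refines the window endpoints by root bisection on the determinant. Under
#' the sign pattern of a prey nullcline falling at the coexistence state
#' (\eqn{A_{11}, A_{22}, A_{12} < 0}, \eqn{A_{21} > 0}) the determinant is
#' positive for every \eqn{\lambda}, so no window exists.
#'
#' @param A 2x2 ODE-stable Jacobian (a warning is issued otherwise).
#' @param D1,D2 diffusion coefficients, >= 0.
#' @param lambda_max right end of the scan (default 1e3).
#' @param grid_n number of scan points.
#' @return `NULL` when no instability window exists, else a numeric
#'   `c(lower, upper)` interval of unstable \eqn{\lambda}.
#' @export
turing_scan <- function(A, D1, D2, lambda_max = 1e3, grid_n = 1e4) {
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    warning("'A' is not ODE-stable; a Turing window presumes ODE stability",
            call. = FALSE)
  if (D1 == 0 && D2 == 0) return(NULL)
  detB <- function(lam)
    (A[1, 1] - lam * D1) * (A[2, 2] - lam * D2) - A[1, 2] * A[2, 1]
  lam <- c(0, exp(seq(log(1e-6), log(lambda_max), length.out = grid_n)))
  d <- detB(lam)
  neg <- which(d < 0)
  if (length(neg) == 0L) return(NULL)
  i0 <- neg[1L]; i1 <- neg[length(neg)]
  lower <- if (i0 == 1L) 0 else
    stats::uniroot(detB, c(lam[i0 - 1L], lam[i0]), tol = 1e-12)$root
  upper <- if (i1 == length(lam)) lambda_max else
    stats::uniroot(detB, c(lam[i1], lam[i1 + 1L]), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

#' Certificate excluding nonconstant positive steady states
#'
#' When \eqn{\gamma < b\phi(K) < \delta}, every positive classical steady
#' state obeys the a-priori bounds \eqn{\max N \le K} and
#' \eqn{\max P \le K_0 = (b\phi(K) - \gamma)/(\delta - b\phi(K))}. If in
#' addition
#' \deqn{\mu_1 D_1 > \varepsilon + aL/2 + (a + b/2) K_0 H,}
#' \deqn{\mu_1 D_2 > -\gamma + bL + aL/2 + (b/2) K_0 H,}
#' with \eqn{\mu_1 = (\pi/\ell)^2} the smallest positive Neumann eigenvalue,
#' then no nonconstant positive steady state exists: diffusion this strong
#' flattens any would-be pattern.
#'
#' @param params a [model_params()].
#' @param spec a [response_spec()] (supplies `L` and `H`).
#' @param length domain size \eqn{\ell}.
#' @return An object of class `nonexistence_verdict` with `K0`, `mu1`, the two
#'   thresholds, `applicable` (\eqn{\gamma < b\phi(K) < \delta}), `holds`, and
#'   the a-priori bounds `bound_N = K`, `bound_P = K0`.
#' @export
nonexistence_check <- function(params, spec, length) {
  bphiK <- params$b * spec$phi(params$K)
  applicable <- params$gamma < bphiK && bphiK < params$delta
  K0 <- if (applicable) (bphiK - params$gamma) / (params$delta - bphiK) else NA_real_
  mu1 <- (pi / length)^2
  L <- spec$L; H <- spec$H
  thr1 <- if (applicable)
    params$eps + params$a * L / 2 + (params$a + params$b / 2) * K0 * H else NA_real_
  thr2 <- if (applicable)
    -params$gamma + params$b * L + params$a * L / 2 + (params$b / 2) * K0 * H else NA_real_
  holds <- applicable && mu1 * params$D1 > thr1 && mu1 * params$D2 > thr2
  structure(list(K0 = K0, mu1 = mu1,
                 threshold_D1 = thr1, threshold_D2 = thr2,
                 applicable = applicable, holds = holds,
                 bound_N = params$K, bound_P = K0,
                 D1 = params$D1, D2 = params$D2),
            class = "nonexistence_verdict")
}

#' @export
print.nonexistence_verdict <- function(x, ...) {
  cat("Nonconstant-steady-state exclusion certificate:\n")
  if (!x$applicable) {
    cat("  not applicable: requires gamma < b*phi(K) < delta\n")
  } else {
    cat(sprintf("  a-priori bounds: max N <= %g, max P <= K0 = %.6g\n",
                x$bound_N, x$K0))
    cat(sprintf("  mu1*D1 = %.6g vs threshold %.6g; mu1*D2 = %.6g vs %.6g\n",
                x$mu1 * x$D1, x$threshold_D1, x$mu1 * x$D2, x$threshold_D2))
    cat("  certificate", if (x$holds) "HOLDS: no spatial patterns exist\n"
        else "does not hold (no conclusion)\n")
  }
  invisible(x)
}
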