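#' Functional response specifications
#'
#' A `response_spec` bundles a functional response \eqn{\phi(N)} (per-predator
#' prey consumption rate as a function of prey density) with its derivative and
#' the four constants used throughout the stability and permanence theory:
#' \describe{
#'   \item{Mtilde}{supremum of \eqn{\phi(N)/N} over \eqn{N > 0};}
#'   \item{L}{supremum of \eqn{\phi} (saturation bound);}
#'   \item{H}{supremum of \eqn{|\phi'(N)|};}
#'   \item{l}{right end of the interval on which \eqn{\phi} is nondecreasing
#'     (\code{Inf} for monotone responses such as Holling type II).}
#' }
#' The standing hypotheses on \eqn{\phi} are: (i) \eqn{\phi} is \eqn{C^1} with
#' \eqn{\phi(0)=0}; (ii) \eqn{\phi(N)/N} is decreasing and bounded by Mtilde;
#' (iii) \eqn{0 \le \phi \le L}; (iv) \eqn{|\phi'| \le H}; (v) \eqn{\phi} is
#' increasing on \eqn{[0, l]} with the carrying capacity \eqn{K < l}.
#'
#' @param name text label.
#' @param phi,dphi vectorized functions of density \eqn{N \ge 0}.
#' @param Mtilde,L,H,l the hypothesis constants (see Description).
#' @param closed_form logical; `TRUE` when the constants are analytic rather
#'   than grid-estimated.
#' @param notes optional character notes (e.g. recorded nonsmooth points).
#' @return An object of class `response_spec`.
#' @seealso [holling2()], [holling4()], [generic_response()],
#'   [verify_hypotheses()]
#' @export
response_spec <- function(name, phi, dphi, Mtilde, L, H, l,
                          closed_form = FALSE, notes = character()) {
  stopifnot(is.function(phi), is.function(dphi))
  if (!is.finite(Mtilde) || Mtilde <= 0)
    stop("'Mtilde' must be a positive finite number", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be a positive finite number", call. = FALSE)
  if (!is.finite(H) || H <= 0) stop("'H' must be a positive finite number", call. = FALSE)
  if (is.na(l) || l <= 0) stop("'l' must be positive (possibly Inf)", call. = FALSE)
  structure(
    list(name = as.character(name), phi = phi, dphi = dphi,
         Mtilde = Mtilde, L = L, H = H, l = l,
         closed_form = isTRUE(closed_form), notes = notes),
    class = "response_spec")
}

#' @export
print.response_spec <- function(x, ...) {
  cat("Functional response:", x$name, "\n")
  cat(sprintf("  constants: Mtilde = %g, L = %g, H = %g, l = %s\n",
              x$Mtilde, x$L, x$H, if (is.finite(x$l)) format(x$l) else "Inf"))
  cat("  constants are", if (x$closed_form) "closed form" else "grid estimates", "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Holling type II (Michaelis-Menten) functional response
#'
#' \eqn{\phi(N) = N/(\beta + N)}: saturating and monotone increasing, so the
#' hypothesis constants are exact: \eqn{\tilde M = 1/\beta}, \eqn{L = 1},
#' \eqn{H = 1/\beta} and \eqn{l = \infty}.
#'
#' @param beta positive half-saturation constant (density units).
#' @return A [response_spec()].
#' @examples
#' h2 <- holling2(1)
#' h2$phi(1)  # 0.5
#' @export
holling2 <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  force(beta)
  response_spec(
    name = sprintf("holling2(beta=%g)", beta),
    phi  = function(N) N / (beta + N),
    dphi = function(N) beta / (beta + N)^2,
    Mtilde = 1 / beta, L = 1, H = 1 / beta, l = Inf,
    closed_form = TRUE)
}

#' Simplified Holling type IV (Sokol-Howell) functional response
#'
#' \eqn{\phi(N) = N/(\beta + N^2)}: hump-shaped (inhibition at high prey
#' density), increasing on \eqn{[0, \sqrt\beta]} and decreasing beyond. Exact
#' constants: \eqn{\tilde M = 1/\beta}, \eqn{L = 1/(2\sqrt\beta)} (attained at
#' \eqn{N = \sqrt\beta}), \eqn{H = 1/\beta} (attained at 0) and
#' \eqn{l = \sqrt\beta}.
#'
#' @param beta positive shape constant (density-squared units).
#' @return A [response_spec()].
#' @examples
#' h4 <- holling4(4)
#' h4$phi(2)  # maximum value 0.25 at N = sqrt(4)
#' @export
holling4 <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  force(beta)
  response_spec(
    name = sprintf("holling4(beta=%g)", beta),
    phi  = function(N) N / (beta + N^2),
    dphi = function(N) (beta - N^2) / (beta + N^2)^2,
    Mtilde = 1 / beta, L = 1 / (2 * sqrt(beta)), H = 1 / beta, l = sqrt(beta),
    closed_form = TRUE)
}

#' Build a response specification from user-supplied functions
#'
#' Estimates the hypothesis constants numerically: Mtilde, L and H are grid
#' suprema over `[0, N_max]` inflated by a 1.01 safety factor (global suprema
#' of a smooth function sampled on a finite grid can only be undershot), and
#' `l` is the largest grid point up to which `phi` is nondecreasing (`Inf` if
#' it never decreases on the grid). Smoothness of `phi` is probed by comparing
#' `dphi` with central finite differences; grid points where they disagree by
#' more than a relative 1e-4 are recorded in `notes` as suspected nonsmooth
#' points (e.g. the kink of a piecewise-linear Holling type I response).
#'
#' @param phi,dphi vectorized functions of density, with `phi(0) == 0`.
#' @param N_max right end of the estimation interval.
#' @param grid_n number of grid points (at least 1000).
#' @param name optional label.
#' @return A [response_spec()] with `closed_form = FALSE`.
#' @export
generic_response <- function(phi, dphi, N_max = 1e3, grid_n = 1e5,
                             name = "generic") {
  stopifnot(is.function(phi), is.function(dphi))
  if (grid_n < 1e3) stop("'grid_n' must be at least 1000", call. = FALSE)
  if (!is.finite(N_max) || N_max <= 0) stop("'N_max' must be positive", call. = FALSE)
  if (abs(phi(0)) > 1e-12)
    stop("hypothesis violation: phi(0) must be 0", call. = FALSE)
  N <- seq(0, N_max, length.out = grid_n)
  pN <- phi(N); dN <- dphi(N)
  if (any(!is.finite(pN)) || any(!is.finite(dN)))
    stop("non-finite response values on the estimation grid", call. = FALSE)
  safety <- 1.01
  L <- max(pN) * safety
  ratio <- pN[-1] / N[-1]
  Mt <- max(ratio) * safety
  H <- max(abs(dN)) * safety
  if (max(pN) <= 0)
    stop("degenerate response: phi is not positive anywhere on the grid",
         call. = FALSE)
  ## largest prefix of the grid on which phi is nondecreasing
  dec <- which(diff(pN) < -1e-14 * max(pN))
  l <- if (length(dec) == 0L) Inf else N[dec[1L]]
  ## C^1 probe: central differences vs dphi at interior points
  h <- N[2L] - N[1L]
  fd <- (pN[-c(1L, 2L)] - pN[-c(grid_n - 1L, grid_n)]) / (2 * h)
  mid <- dN[-c(1L, grid_n)]
  scale <- pmax(abs(mid), H / safety)
  bad <- which(abs(fd - mid) / scale > 1e-4)
  notes <- character()
  if (length(bad))
    notes <- sprintf("suspected nonsmooth points near N = %s",
                     paste(signif(N[bad[seq_len(min(3L, length(bad)))] + 1L], 4),
                           collapse = ", "))
  response_spec(name = name, phi = phi, dphi = dphi,
                Mtilde = Mt, L = L, H = H, l = l,
                closed_form = FALSE, notes = notes)
}

#' Certify the standing hypotheses for a response and carrying capacity
#'
#' Checks hypotheses (i)-(v) (see [response_spec()]) numerically on a uniform
#' grid over `[0, max(10 K, 10 l)]` (the `l` term only when finite). Violations
#' are reported with a witness point, never raised as errors.
#'
#' @param spec a [response_spec()].
#' @param K carrying capacity against which hypothesis (v) (`K < l`) is tested.
#' @param grid_n grid resolution.
#' @return An object of class `hypothesis_report`: logical flags `i` to `v`,
#'   `all_satisfied`, witness points of violations, the constants tested and
#'   `K_tested`.
#' @export
verify_hypotheses <- function(spec, K, grid_n = 1e4) {
  stopifnot(inherits(spec, "response_spec"))
  if (!is.finite(K) || K <= 0) stop("'K' must be positive", call. = FALSE)
  upper <- max(10 * K, if (is.finite(spec$l)) 10 * spec$l else 0)
  N <- seq(0, upper, length.out = grid_n)
  pN <- spec$phi(N); dN <- spec$dphi(N)
  witness <- list()
  tol <- 1e-9

  ## (i) C^1 with phi(0) = 0: finite-difference agreement + value at 0
  ok_i <- abs(pN[1L]) <= 1e-12
  if (!ok_i) witness$i <- 0
  if (ok_i) {
    h <- N[2L] - N[1L]
    fd <- (pN[-c(1L, 2L)] - pN[-c(grid_n - 1L, grid_n)]) / (2 * h)
    mid <- dN[-c(1L, grid_n)]
    rel <- abs(fd - mid) / pmax(abs(mid), spec$H)
    ## central differences on a smooth function carry O(h^2) truncation error;
    ## scale the acceptance band accordingly and flag only gross jumps
    band <- pmax(1e-4, h^2 * spec$H * 100)
    bad <- which(rel > band)
    if (length(bad)) { ok_i <- FALSE; witness$i <- N[bad[1L] + 1L] }
  }

  ## (ii) phi/N <= Mtilde and nonincreasing
  ratio <- pN[-1L] / N[-1L]
  ok_ii <- all(ratio <= spec$Mtilde * (1 + tol)) &&
    all(diff(ratio) <= tol * max(ratio))
  if (!ok_ii) {
    j <- which(ratio > spec$Mtilde * (1 + tol))[1L]
    if (is.na(j)) j <- which(diff(ratio) > tol * max(ratio))[1L] + 1L
    witness$ii <- N[-1L][j]
  }

  ## (iii) 0 <= phi <= L
  ok_iii <- all(pN >= -tol) && all(pN <= spec$L * (1 + tol))
  if (!ok_iii) witness$iii <- N[which(pN < -tol | pN > spec$L * (1 + tol))[1L]]

  ## (iv) |phi'| <= H
  ok_iv <- all(abs(dN) <= spec$H * (1 + tol))
  if (!ok_iv) witness$iv <- N[which(abs(dN) > spec$H * (1 + tol))[1L]]

  ## (v) phi nondecreasing on [0, l] with K < l (strict)
  ok_v <- K < spec$l
  if (ok_v && is.finite(spec$l)) {
    idx <- which(N <= spec$l)
    inc <- diff(pN[idx])
    if (any(inc < -tol * max(pN))) {
      ok_v <- FALSE
      witness$v <- N[idx][which(inc < -tol * max(pN))[1L]]
    }
  }
  if (!ok_v && is.null(witness$v)) witness$v <- K

  flags <- c(i = ok_i, ii = ok_ii, iii = ok_iii, iv = ok_iv, v = ok_v)
  structure(
    list(flags = flags, all_satisfied = all(flags), witness = witness,
         constants_used = c(Mtilde = spec$Mtilde, L = spec$L, H = spec$H,
                            l = spec$l),
         K_tested = K, response = spec$name),
    class = "hypothesis_report")
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Hypothesis certification for", x$response,
      sprintf("(K = %g)\n", x$K_tested))
  for (nm in names(x$flags)) {
    cat(sprintf("  (%s): %s", nm, if (x$flags[[nm]]) "satisfied" else "VIOLATED"))
    if (!x$flags[[nm]] && !is.null(x$witness[[nm]]))
      cat(sprintf(" (witness N = %g)", x$witness[[nm]]))
    cat("\n")
  }
  cat(if (x$all_satisfied) "All hypotheses satisfied.\n"
      else "Not all hypotheses satisfied.\n")
  invisible(x)
}
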