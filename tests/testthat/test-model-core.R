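test_that("parameter validation enforces sign constraints", {
  expect_error(model_params(1, 2, 1, 1, 0.6, 0.4), "gamma < delta")
  expect_error(model_params(1, 2, 1, 1, 0.4, 0.4), "gamma < delta")
  expect_error(model_params(-1, 2, 1, 1, 0.4, 0.6), "positive")
  expect_error(model_params(1, 2, 1, 1, 0.4, 0.6, D1 = -0.1), ">= 0")
})

test_that("mortality saturates from gamma toward delta", {
  par <- clean_params()
  expect_equal(mortality(0, par), 0.4)
  expect_equal(mortality(1, par), 0.5)          # midpoint (gamma+delta)/2
  expect_lt(mortality(1e6, par), 0.6)           # approaches delta from below
  expect_gt(mortality(1e6, par), 0.6 - 1e-5)
  expect_error(mortality(-0.1, par), "nonnegative")
})

test_that("prey nullcline takes the removable-singularity limit at N = 0", {
  par <- clean_params(); sp <- holling2(1)
  expect_equal(prey_nullcline_f(1, par, sp), 1)    # (1-1/2)*1 / 0.5
  expect_equal(prey_nullcline_f(2, par, sp), 0)    # vanishes at K
  expect_equal(prey_nullcline_f(0, par, sp), 1)    # eps/(a*phi'(0))
  expect_error(prey_nullcline_f(3, par, sp), "\\[0, K\\]")
})

test_that("reaction right-hand side vanishes exactly at all three equilibria", {
  par <- clean_params(); sp <- holling2(1)
  r <- ode_rhs(1, 1, par, sp)
  expect_equal(c(r$dN, r$dP), c(0, 0))
  r0 <- ode_rhs(0, 0, par, sp)
  expect_identical(c(r0$dN, r0$dP), c(0, 0))
  rK <- ode_rhs(2, 0, par, sp)
  expect_identical(c(rK$dN, rK$dP), c(0, 0))
  expect_error(ode_rhs(-1, 0, par, sp), "nonnegative")
})

test_that("equilibria of the clean set are E1, E2 and E3 = (1, 1)", {
  eqs <- find_equilibria(clean_params(), holling2(1))
  expect_length(eqs, 3L)
  expect_equal(sapply(eqs, function(e) e$label), c("E1", "E2", "E3"))
  expect_equal(c(eqs[[1]]$N0, eqs[[1]]$P0), c(0, 0))
  expect_equal(c(eqs[[2]]$N0, eqs[[2]]$P0), c(2, 0))
  expect_equal(c(eqs[[3]]$N0, eqs[[3]]$P0), c(1, 1), tolerance = 1e-10)
  expect_true(all(sapply(eqs, function(e) e$residual) < 1e-10))
})

test_that("no interior equilibrium exists in the extinction regime", {
  eqs <- find_equilibria(extinct_params(), holling2(1))
  expect_length(eqs, 2L)
  expect_equal(sapply(eqs, function(e) e$label), c("E1", "E2"))
})

test_that("boundary Jacobians have the closed-form spectra", {
  par <- clean_params(); sp <- holling2(1)
  eqs <- find_equilibria(par, sp)
  expect_equal(sort(Re(eqs[[1]]$eigenvalues)), c(-0.4, 1))        # E1
  expect_equal(sort(Re(eqs[[2]]$eigenvalues)), c(-1, -0.4 + 2/3)) # E2
  expect_equal(eqs[[1]]$classification, "saddle")
  expect_equal(eqs[[2]]$classification, "saddle")
})

test_that("the interior Jacobian of the clean set matches hand arithmetic", {
  par <- clean_params(); sp <- holling2(1)
  e3 <- find_equilibria(par, sp)[[3]]
  expect_equal(e3$jac, matrix(c(-0.25, 0.25, -0.5, -0.05), 2, 2),
               tolerance = 1e-9)
  expect_equal(e3$trace, -0.3, tolerance = 1e-9)
  expect_equal(e3$det, 0.1375, tolerance = 1e-9)
  expect_equal(e3$classification, "stable-spiral")
  expect_true(e3$prop1_certificate)                 # N0 = 1 in [K/2, K]
  # trace/det consistent with the eigenvalues
  expect_equal(sum(e3$eigenvalues), complex(real = e3$trace), tolerance = 1e-10)
  expect_equal(prod(e3$eigenvalues), complex(real = e3$det), tolerance = 1e-10)
})

test_that("the nullcline derivative matches finite differences", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_model(sample(c("holling2", "holling4"), 1))
    N <- runif(5, 0.1 * m$params$K, 0.9 * m$params$K)
    h <- 1e-6
    fd <- (prey_nullcline_f(N + h, m$params, m$spec) -
           prey_nullcline_f(N - h, m$params, m$spec)) / (2 * h)
    an <- ppdiffusion:::prey_nullcline_df(N, m$params, m$spec)
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("equilibrium residuals stay below 1e-10 across random models", {
  set.seed(22)
  for (i in 1:40) {
    m <- random_model(if (i %% 2) "holling2" else "holling4")
    eqs <- find_equilibria(m$params, m$spec)
    expect_true(all(sapply(eqs, function(e) e$residual) < 1e-10))
    # E1 spectrum is exactly (eps, -gamma)
    expect_equal(sort(Re(eqs[[1]]$eigenvalues)),
                 sort(c(m$params$eps, -m$params$gamma)))
  }
})

test_that("E2 stability flips exactly where b*phi(K) crosses gamma", {
  sp <- holling2(1); bphiK <- 2 / 3
  for (gamma in c(0.5, 0.6, bphiK - 1e-3)) {   # margin > 0: saddle
    par <- model_params(1, 2, 1, 1, gamma, gamma + 0.5)
    e2 <- find_equilibria(par, sp)[[2]]
    expect_equal(e2$classification, "saddle", label = paste("gamma =", gamma))
  }
  for (gamma in c(bphiK + 1e-3, 0.7, 0.9)) {   # margin < 0: stable
    par <- model_params(1, 2, 1, 1, gamma, gamma + 0.5)
    e2 <- find_equilibria(par, sp)[[2]]
    expect_equal(e2$classification, "stable-node",
                 label = paste("gamma =", gamma))
  }
})

test_that("analytic stability certificate implies a stable classification", {
  set.seed(23)
  found <- 0
  for (i in 1:60) {
    m <- random_model("holling2")
    for (e in interior_of(find_equilibria(m$params, m$spec))) {
      if (isTRUE(e$prop1_certificate)) {
        found <- found + 1
        expect_true(e$classification %in% c("stable-node", "stable-spiral"))
      }
    }
  }
  expect_gt(found, 5)  # the sweep must actually exercise the certificate
})

test_that("constant-mortality limit: N0 solves b*phi(N) = gamma as delta -> gamma", {
  sp <- holling2(1)
  par <- model_params(1, 2, 1, 1, 0.4, 0.4 + 1e-8)
  e3 <- interior_of(find_equilibria(par, sp))[[1]]
  # b*phi(N) = gamma: N/(1+N) = 0.4 -> N = 2/3
  expect_equal(e3$N0, 2 / 3, tolerance = 1e-6)
})

test_that("ODE integration converges to the predicted attractor", {
  sp <- holling2(1)
  ts <- integrate_ode(clean_params(), sp, c(0.5, 0.5), 500)
  expect_equal(unlist(ts[nrow(ts), c("N", "P")]), c(N = 1, P = 1),
               tolerance = 1e-3)
  tx <- integrate_ode(extinct_params(), sp, c(0.5, 0.5), 500)
  expect_lt(tx$P[nrow(tx)], 1e-6)
  expect_equal(tx$N[nrow(tx)], 2, tolerance = 1e-3)
  # prey axis is invariant: P stays 0, N -> K
  ta <- integrate_ode(clean_params(), sp, c(0.3, 0), 200)
  expect_true(all(ta$P == 0))
  expect_equal(ta$N[nrow(ta)], 2, tolerance = 1e-4)
})
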