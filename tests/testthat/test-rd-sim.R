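test_that("Neumann Laplacian is exact on constants and second order on cosines", {
  g <- grid1d(pi, 201L)
  expect_identical(laplacian_neumann(rep(3.7, g$n), g), rep(0, g$n))
  # Neumann eigenfunction: -lap cos(jx) = j^2 cos(jx) on length pi
  for (j in c(1, 3)) {
    v <- cos(j * g$x)
    err <- max(abs(laplacian_neumann(v, g) + j^2 * v))
    expect_lt(err, 10 * j^4 * g$dx^2)   # O(dx^2) with curvature constant
  }
  # linear field: zero second derivative in the interior, flux enforced at ends
  lin <- g$x
  lap <- laplacian_neumann(lin, g)
  expect_equal(lap[2:(g$n - 1)], rep(0, g$n - 2))
  expect_true(lap[1] != 0 && lap[g$n] != 0)
  expect_error(grid1d(pi, 8L), "at least 16")
  expect_error(laplacian_neumann(1:5, g), "match")
})

test_that("the clean coexistence run flattens onto (1, 1)", {
  par <- clean_params(); sp <- holling2(1); g <- grid1d(pi, 201L)
  traj <- simulate_rd(par, sp, g, random_init(g, 1L, c(1, 1), 0.5), 500,
                      seed = 1L)
  nt <- length(traj$times)
  expect_lt(max(traj$N[, nt]) - min(traj$N[, nt]), 1e-3)  # spatially uniform
  expect_lt(max(traj$P[, nt]) - min(traj$P[, nt]), 1e-3)
  expect_equal(mean(traj$N[, nt]), 1, tolerance = 1e-2)
  expect_equal(mean(traj$P[, nt]), 1, tolerance = 1e-2)
  # summaries consistent with snapshots
  expect_equal(traj$summary$maxN, apply(traj$N, 2, max))
  expect_equal(traj$summary$varP, apply(traj$P, 2, var))
  expect_true(all(traj$N >= 0) && all(traj$P >= 0))
})

test_that("invariant faces: predator-free and prey-free dynamics", {
  par <- clean_params(); sp <- holling2(1); g <- grid1d(pi, 101L)
  # P identically 0: prey follows the logistic PDE, N -> K uniformly
  init <- list(N = 1 + 0.4 * cos(g$x), P = rep(0, g$n))
  tr <- simulate_rd(par, sp, g, init, 300)
  nt <- length(tr$times)
  expect_true(all(tr$P == 0))
  expect_equal(unname(tr$N[, nt]), rep(2, g$n), tolerance = 1e-4)
  # N identically 0: predator decays (mortality >= gamma)
  init2 <- list(N = rep(0, g$n), P = 1 + 0.4 * cos(g$x))
  tr2 <- simulate_rd(par, sp, g, init2, 300)
  expect_true(all(tr2$N == 0))
  expect_lt(max(tr2$P[, length(tr2$times)]), 1e-6)
})

test_that("diffusion-free spatially constant runs match the ODE integrator", {
  par <- clean_params(D1 = 0, D2 = 0); sp <- holling2(1)
  g <- grid1d(pi, 33L)
  init <- list(N = rep(0.5, g$n), P = rep(0.5, g$n))
  tr <- simulate_rd(par, sp, g, init, 50, rtol = 1e-9, atol = 1e-12)
  od <- integrate_ode(par, sp, c(0.5, 0.5), 50, dt = 1)
  i <- match(od$t, tr$times)
  expect_lt(max(abs(tr$N[17, i] - od$N)), 1e-6)
  expect_lt(max(abs(tr$P[17, i] - od$P)), 1e-6)
})

test_that("with predation off the prey relaxes to carrying capacity", {
  par <- clean_params()
  par$a <- 0   # predation switched off for this limit check only
  sp <- holling2(1); g <- grid1d(pi, 101L)
  init <- random_init(g, 5L, c(0.5, 0.5), 0.5)
  tr <- simulate_rd(par, sp, g, init, 300)
  expect_equal(unname(tr$N[, length(tr$times)]), rep(2, g$n),
               tolerance = 1e-4)
})

test_that("dissipativity: tails enter the absorbing set from far outside", {
  par <- clean_params(); sp <- holling2(1); g <- grid1d(pi, 201L)
  # start an order of magnitude above the absorbing set
  init <- random_init(g, 3L, c(10 * par$K, 8), 0.3)
  traj <- simulate_rd(par, sp, g, init, 500)
  v <- dissipativity_check(traj)
  expect_equal(v$M0, 4)    # eps (K+1) / (a phi(K+1)) = 3 / 0.75
  expect_true(v$holds_N)
  expect_true(v$holds_P)
  expect_lte(v$tail_max_N, par$K + 1e-3)
  expect_lte(v$tail_max_P, 4 + 1e-3)
})

test_that("persistence margins are positive under permanence, zero under extinction", {
  sp <- holling2(1); g <- grid1d(pi, 201L)
  for (s in 1:3) {
    tr <- simulate_rd(clean_params(), sp, g, random_init(g, s, c(1, 1), 0.5),
                      500)
    m <- persistence_margins(tr)
    expect_gt(m[["q"]], 0); expect_gt(m[["w"]], 0)
    expect_lte(m[["q"]], m[["Q"]]); expect_lte(m[["w"]], m[["W"]])
  }
  trx <- simulate_rd(extinct_params(), sp, g,
                     random_init(g, 1L, c(1, 0.5), 0.5), 500)
  mx <- persistence_margins(trx)
  expect_lt(mx[["W"]], 1e-6)                       # predator extinct
  # equilibrium initial data stays put: margins collapse to the point
  tre <- simulate_rd(clean_params(), sp, g,
                     list(N = rep(1, g$n), P = rep(1, g$n)), 100)
  me <- persistence_margins(tre)
  expect_equal(unname(me), c(1, 1, 1, 1), tolerance = 1e-6)
})

test_that("regime verdict is the sign of b*phi(K) - gamma, diffusion-independent", {
  sp <- holling2(1)
  r1 <- regime_check(clean_params(), sp)
  expect_equal(r1$regime, "permanent")
  expect_equal(r1$margin, -0.4 + 2 / 3)
  r2 <- regime_check(extinct_params(), sp)
  expect_equal(r2$regime, "extinction")
  expect_equal(r2$margin, -0.9 + 2 / 3)
  # boundary case belongs to the extinction branch
  par_b <- model_params(1, 2, 1, 1, 2 / 3, 1)
  expect_equal(regime_check(par_b, sp)$regime, "extinction")
  # verdict does not involve D1, D2
  expect_equal(regime_check(clean_params(0, 0), sp)$margin, r1$margin)
  expect_equal(regime_check(clean_params(9, 7), sp)$regime, r1$regime)
})

test_that("Holling II assembly reproduces the saturating-ratio system term by term", {
  # independent rewrite of the reaction terms with an explicit N/(beta+N) ratio
  set.seed(31)
  beta <- 1.7
  par <- model_params(1.2, 3, 0.8, 0.9, 0.3, 0.7)
  sp <- holling2(beta)
  N <- runif(200, 0, 10); P <- runif(200, 0, 10)
  r <- ode_rhs(N, P, par, sp)
  expect_equal(r$dN, 1.2 * (1 - N / 3) * N - 0.8 * P * N / (beta + N))
  expect_equal(r$dP, -(0.3 + 0.7 * P) / (1 + P) * P + 0.9 * N * P / (beta + N))
})
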