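#' Preset study scenarios
#'
#' Named parameter sets realizing each dynamical regime the toolkit
#' diagnoses:
#' \describe{
#'   \item{clean_stable}{eps = 1, K = 2, a = b = 1, gamma = 0.4, delta = 0.6,
#'     Holling II (beta = 1), D1 = D2 = 0.1, domain length pi. Permanent, with
#'     coexistence state (1, 1) inside the analytic stability range
#'     `[K/2, K]`.}
#'   \item{extinction}{as above with gamma = 0.9, delta = 1.2: the predator
#'     margin b*phi(K) - gamma = 2/3 - 0.9 is negative, so (K, 0) is globally
#'     attracting.}
#'   \item{permanent_h2}{a second permanent Holling II configuration
#'     (beta = 2, gamma = 0.3, delta = 0.5, D1 = 0.5, D2 = 0.2).}
#'   \item{permanent_h4}{Holling IV (beta = 9, so l = 3 > K = 2), b = 2,
#'     gamma = 0.2, delta = 0.4: permanent with a hump-shaped response.}
#'   \item{nonexistence_cert}{gamma = 0.4, delta = 0.8, D1 = 5, D2 = 3 on
#'     length pi: the pattern-exclusion certificate holds (thresholds 4.5 and
#'     2.1 with K0 = 2, mu1 = 1).}
#'   \item{hypothesis_fail_h4}{Holling IV with beta = 4 and K = 3 > l = 2:
#'     hypothesis (v) deliberately violated; flagged.}
#' }
#'
#' @param name one of the preset names above.
#' @return An object of class `pp_scenario`: `name`, `params`, `spec`,
#'   `grid`, `init` descriptor (`kind`, `seed`, `amplitude`, `base`), `t_end`,
#'   `expected_regime`, `hypothesis_violation` flag.
#' @export
preset <- function(name) {
  presets <- c("clean_stable", "extinction", "permanent_h2", "permanent_h4",
               "nonexistence_cert", "hypothesis_fail_h4")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  sc <- switch(
    name,
    clean_stable = list(
      params = model_params(1, 2, 1, 1, 0.4, 0.6, 0.1, 0.1),
      spec = holling2(1), expected_regime = "permanent"),
    extinction = list(
      params = model_params(1, 2, 1, 1, 0.9, 1.2, 0.1, 0.1),
      spec = holling2(1), expected_regime = "extinction"),
    permanent_h2 = list(
      params = model_params(1, 2, 1, 1, 0.3, 0.5, 0.5, 0.2),
      spec = holling2(2), expected_regime = "permanent"),
    permanent_h4 = list(
      params = model_params(1, 2, 1, 2, 0.2, 0.4, 0.1, 0.1),
      spec = holling4(9), expected_regime = "permanent"),
    nonexistence_cert = list(
      params = model_params(1, 2, 1, 1, 0.4, 0.8, 5, 3),
      spec = holling2(1), expected_regime = "permanent"),
    hypothesis_fail_h4 = list(
      params = model_params(1, 3, 1, 1, 0.2, 0.4, 0.1, 0.1),
      spec = holling4(4), expected_regime = "permanent"))
  hyp <- verify_hypotheses(sc$spec, sc$params$K)
  structure(list(name = name, params = sc$params, spec = sc$spec,
                 grid = grid1d(pi, 201L),
                 init = list(kind = "perturbed", seed = 1L, amplitude = 0.2,
                             base = NULL),
                 t_end = 500,
                 expected_regime = sc$expected_regime,
                 hypothesis_violation = !hyp$all_satisfied),
            class = "pp_scenario")
}

#' @export
print.pp_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  print(x$params)
  cat("  response:", x$spec$name, "\n")
  cat(sprintf("  domain: length %.4g, %d nodes; t_end = %g\n",
              x$grid$length, x$grid$n, x$t_end))
  cat("  expected regime:", x$expected_regime, "\n")
  if (x$hypothesis_violation)
    cat("  NOTE: response hypotheses deliberately violated for this preset\n")
  invisible(x)
}

#' Smooth positive initial fields compatible with no-flux boundaries
#'
#' Builds seeded perturbations of constant base densities from cosine modes
#' 1-5 (each has zero slope at both boundaries, so the initial data satisfy
#' the Neumann condition exactly). Coefficients are drawn once per seed and
#' rescaled so the relative perturbation is bounded by `amplitude`
#' deterministically; fields are therefore strictly positive for
#' `amplitude < 1` and bit-reproducible per seed.
#'
#' @param grid a [grid1d()].
#' @param seed integer seed for the coefficient draw.
#' @param base strictly positive `(N, P)` base densities.
#' @param amplitude relative perturbation bound in `[0, 1)`.
#' @return A list with vectors `N` and `P`.
#' @export
random_init <- function(grid, seed, base, amplitude = 0.2) {
  if (any(base <= 0)) stop("'base' must be strictly positive", call. = FALSE)
  if (amplitude < 0 || amplitude >= 1)
    stop("'amplitude' must be in [0, 1) to keep the fields positive",
         call. = FALSE)
  modes <- 1:5
  pert <- function(coefs) {
    if (amplitude == 0) return(rep(0, grid$n))
    s <- sum(abs(coefs))
    basis <- vapply(modes, function(j) cos(j * pi * grid$x / grid$length),
                    numeric(grid$n))
    amplitude * as.vector(basis %*% coefs) / s
  }
  coefs <- with_preserved_seed(seed, stats::runif(2L * length(modes), -1, 1))
  list(N = base[1] * (1 + pert(coefs[modes])),
       P = base[2] * (1 + pert(coefs[modes + length(modes)])))
}

## evaluate `expr` under set.seed(seed) without disturbing the global RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run a scenario end to end
#'
#' Convenience pipeline: resolve initial data, simulate, and attach the
#' standard diagnostics (regime, equilibria, dissipativity, persistence
#' margins; mode-wise stability, energy series and global-stability verdict
#' when an interior equilibrium exists and the regime is permanent;
#' nonexistence certificate).
#'
#' @param scenario a [preset()] scenario (fields may be modified first).
#' @param seed overrides the scenario's init seed when not `NULL`.
#' @param t_end overrides the scenario's horizon when not `NULL`.
#' @return A list with the trajectory and all diagnostic records.
#' @export
run_scenario <- function(scenario, seed = NULL, t_end = NULL) {
  stopifnot(inherits(scenario, "pp_scenario"))
  if (!is.null(seed)) scenario$init$seed <- as.integer(seed)
  if (!is.null(t_end)) scenario$t_end <- t_end
  params <- scenario$params; spec <- scenario$spec; grid <- scenario$grid

  eqs <- find_equilibria(params, spec,
                         warn_hypotheses = !scenario$hypothesis_violation)
  interior <- Filter(function(e) e$label == "E3", eqs)
  base <- scenario$init$base
  if (is.null(base)) {
    base <- if (length(interior)) c(interior[[1L]]$N0, interior[[1L]]$P0)
            else c(params$K, 0.5)
  }
  init <- switch(scenario$init$kind,
                 constant = list(N = rep(base[1], grid$n),
                                 P = rep(base[2], grid$n)),
                 perturbed = random_init(grid, scenario$init$seed, base,
                                         scenario$init$amplitude),
                 stop("unknown init kind '", scenario$init$kind, "'",
                      call. = FALSE))
  traj <- simulate_rd(params, spec, grid, init, scenario$t_end,
                      seed = scenario$init$seed)

  out <- list(scenario = scenario, trajectory = traj,
              regime = regime_check(params, spec),
              equilibria = eqs,
              dissipativity = dissipativity_check(traj),
              margins = persistence_margins(traj),
              nonexistence = nonexistence_check(params, spec, grid$length))
  if (length(interior) && out$regime$regime == "permanent") {
    out$mode_stability <- homogeneous_stability(params, spec, interior[[1L]],
                                                grid$length)
    gs <- tryCatch(global_stability_verdict(params, spec, interior[[1L]], traj),
                   error = function(e) e, warning = function(w) w)
    if (inherits(gs, "global_stability_verdict")) out$global_stability <- gs
  }
  out
}

#' Run a YAML configuration file
#'
#' Executes the full pipeline described by a structured config (sections
#' `model`, `response`, `domain`, `init`, `solver`, `output`) and writes all
#' outputs under a run directory: the resolved config (with the seed echoed),
#' the trajectory summary and snapshots as columnar text, the equilibrium and
#' stability reports, and the energy series when available.
#'
#' @param path path to a YAML config file.
#' @param out_dir run directory (created if missing); defaults to
#'   `output.dir` in the config or a `"run"` directory beside the config.
#' @return (Invisibly) the [run_scenario()] result list, with `out_dir`
#'   attached.
#' @export
run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  problems <- character()
  need <- function(sect, keys) {
    missing <- setdiff(keys, names(cfg[[sect]]))
    if (is.null(cfg[[sect]]))
      problems <<- c(problems, sprintf("missing section '%s'", sect))
    else if (length(missing))
      problems <<- c(problems, sprintf("section '%s' missing keys: %s", sect,
                                       paste(missing, collapse = ", ")))
  }
  need("model", c("eps", "K", "a", "b", "gamma", "delta"))
  need("response", "name")
  if (length(problems))
    stop("config validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  m <- cfg$model
  params <- tryCatch(
    model_params(m$eps, m$K, m$a, m$b, m$gamma, m$delta,
                 D1 = m$D1 %||% 0, D2 = m$D2 %||% 0),
    error = function(e) stop("config validation failed: model: ",
                             conditionMessage(e), call. = FALSE))
  spec <- switch(
    cfg$response$name,
    holling2 = holling2(cfg$response$beta %||% 1),
    holling4 = holling4(cfg$response$beta %||% 1),
    generic = {
      ex <- parse_response_expr(cfg$response$phi, cfg$response$dphi)
      generic_response(ex$phi, ex$dphi,
                       N_max = cfg$response$N_max %||% 1e3,
                       name = "generic(config)")
    },
    stop("unknown response name '", cfg$response$name,
         "'; valid: holling2, holling4, generic", call. = FALSE))

  dom <- cfg$domain %||% list()
  grid <- grid1d(dom$length %||% pi, dom$n %||% 201L)
  initc <- cfg$init %||% list()
  scenario <- structure(
    list(name = cfg$name %||% "config", params = params, spec = spec,
         grid = grid,
         init = list(kind = initc$kind %||% "perturbed",
                     seed = as.integer(initc$seed %||% 1L),
                     amplitude = initc$amplitude %||% 0.2,
                     base = initc$base),
         t_end = cfg$t_end %||% 500,
         expected_regime = regime_check(params, spec)$regime,
         hypothesis_violation =
           !verify_hypotheses(spec, params$K)$all_satisfied),
    class = "pp_scenario")

  res <- run_scenario(scenario)

  if (is.null(out_dir))
    out_dir <- cfg$output$dir %||% file.path(dirname(path), "run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$resolved_seed <- scenario$init$seed
  yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
  write_trajectory(res$trajectory, out_dir)
  rep <- file.path(out_dir, "reports.txt")
  sink(rep); on.exit(sink(), add = TRUE)
  print(res$regime); print(res$equilibria); print(res$dissipativity)
  cat(sprintf("persistence margins: q = %.6g, Q = %.6g, w = %.6g, W = %.6g\n",
              res$margins[["q"]], res$margins[["Q"]],
              res$margins[["w"]], res$margins[["W"]]))
  print(res$nonexistence)
  if (!is.null(res$mode_stability)) print(res$mode_stability)
  if (!is.null(res$global_stability)) print(res$global_stability)
  sink(); on.exit()
  if (!is.null(res$global_stability) && !is.null(res$global_stability$energy)) {
    es <- res$global_stability$energy
    utils::write.table(
      data.frame(t = es$times, E = es$E_values),
      file.path(out_dir, "energy.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res$out_dir <- out_dir
  invisible(res)
}

#' Write trajectory summary and snapshots as columnar text
#'
#' @param traj a [simulate_rd()] trajectory.
#' @param dir output directory.
#' @return (Invisibly) the paths written.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "summary.tsv")
  utils::write.table(traj$summary, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  p2 <- file.path(dir, "snapshots.tsv")
  nt <- length(traj$times)
  snap <- data.frame(
    t = rep(traj$times, each = traj$grid$n),
    x = rep(traj$x, nt),
    N = as.vector(traj$N), P = as.vector(traj$P))
  utils::write.table(snap, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(summary = p1, snapshots = p2))
}

## restricted arithmetic evaluator for user response expressions in configs:
## only arithmetic operators, parentheses, selected math functions and the
## variable N are allowed
parse_response_expr <- function(phi_str, dphi_str) {
  if (is.null(phi_str) || is.null(dphi_str))
    stop("generic response requires 'phi' and 'dphi' expression strings",
         call. = FALSE)
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "abs",
               "sin", "cos", "tanh", "pmin", "pmax", "N")
  check <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!fn %in% allowed)
        stop("disallowed function '", fn, "' in response expression",
             call. = FALSE)
      for (i in seq_along(e)[-1L]) check(e[[i]])
    } else if (is.name(e)) {
      if (!as.character(e) %in% allowed)
        stop("disallowed symbol '", as.character(e),
             "' in response expression", call. = FALSE)
    } else if (!is.numeric(e)) {
      stop("disallowed token in response expression", call. = FALSE)
    }
  }
  build <- function(s) {
    e <- str2lang(s)
    check(e)
    env <- new.env(parent = baseenv())
    function(N) eval(e, list(N = N), env)
  }
  list(phi = build(phi_str), dphi = build(dphi_str))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
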