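# shared fixtures: the "clean" coexistence parameter set used throughout
# (interior equilibrium exactly (1, 1)), its extinction twin, and a random
# generator of valid parameter/response pairs

clean_params <- function(D1 = 0.1, D2 = 0.1)
  model_params(eps = 1, K = 2, a = 1, b = 1, gamma = 0.4, delta = 0.6,
               D1 = D1, D2 = D2)

extinct_params <- function(D1 = 0.1, D2 = 0.1)
  model_params(eps = 1, K = 2, a = 1, b = 1, gamma = 0.9, delta = 1.2,
               D1 = D1, D2 = D2)

# random valid parameter set + response satisfying hypotheses (i)-(v);
# Holling IV draws beta > K^2 so that K < l = sqrt(beta)
random_model <- function(type = c("holling2", "holling4")) {
  type <- match.arg(type)
  K <- runif(1, 1, 5)
  spec <- if (type == "holling2") holling2(runif(1, 0.3, 3))
          else holling4(K^2 * runif(1, 1.2, 3))
  gamma <- runif(1, 0.05, 1)
  list(params = model_params(eps = runif(1, 0.5, 2), K = K,
                             a = runif(1, 0.5, 2), b = runif(1, 0.5, 2),
                             gamma = gamma, delta = gamma + runif(1, 0.1, 1),
                             D1 = runif(1, 0, 1), D2 = runif(1, 0, 1)),
       spec = spec)
}

interior_of <- function(eqs) Filter(function(e) e$label == "E3", eqs)
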