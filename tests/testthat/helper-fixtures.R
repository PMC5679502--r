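# shared fixtures: built once per test run

toy_net <- make_toy_network()
toy_S <- stoichiometric_matrix(toy_net)

# short, coarse run used where only qualitative behaviour matters
fast_config <- function(...) {
  args <- modifyList(list(dt = 0.1, duration = 96), list(...))
  do.call(simulation_config, args)
}

# randomized LP bound sets on the toy network (seeded by the caller)
random_bound_set <- function(n, force_lower = FALSE) {
  l <- rep(0, n)
  u <- runif(n, 0.01, 5)
  if (force_lower) {
    j <- sample(n, 2)
    l[j] <- u[j] * runif(2, 0.5, 3)
    l <- pmin(l, u)
  }
  k <- sample(1:3, 1)
  cvec <- numeric(n)
  cvec[sample(n, k)] <- runif(k, 0.5, 2)
  list(l = l, u = u, c = cvec)
}

# independent formulation of the proton-release curve: average charge of
# the equilibrium speciation computed from cumulative dissociation
# products (distinct algebra from the packaged closed form)
eq10_oracle <- function(pKas, H_e) {
  K <- 10^(-pKas[!is.na(pKas)])
  denom_terms <- c(1, cumprod(K) / H_e^seq_along(K))
  alphas <- denom_terms / sum(denom_terms)
  sum((seq_along(denom_terms) - 1) * alphas)
}
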