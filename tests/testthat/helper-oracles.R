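# Shared fixtures and independent oracles for the test suite.

toy_tree <- function() read_newick(text = "((A:1,B:1):1,C:2);")

# Dense-matrix Gaussian log-likelihood with the root state profiled by GLS:
# the brute-force counterpart of the linear-time kernel.
dense_profiled_lnL <- function(phy, trait, model, se = NULL) {
  ord <- phy$tip.label
  V <- model_covariance(phy, model)[ord, ord, drop = FALSE]
  y <- trait[ord]
  if (!is.null(se)) V <- V + diag(se[ord]^2, length(y))
  iV <- solve(V)
  z0 <- sum(iV %*% y) / sum(iV)
  q <- drop(t(y - z0) %*% iV %*% (y - z0))
  list(lnL = -0.5 * (length(y) * log(2 * pi) +
                       as.numeric(determinant(V)$modulus) + q),
       z0 = z0)
}

# Simulate Brownian motion edge by edge, recording internal-node states.
# Independent of the package's covariance-based simulator.
sim_bm_with_nodes <- function(phy, sigma2, z0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  states <- rep(NA_real_, N)
  states[n + 1] <- z0
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; chi <- pre$edge[e, 2]
    states[chi] <- states[par] + rnorm(1, 0, sqrt(sigma2 * pre$edge.length[e]))
  }
  list(tips = stats::setNames(states[1:n], phy$tip.label),
       nodes = states[(n + 1):N])
}

# A quick random model spec for oracle sweeps.
random_model <- function(name) {
  switch(name,
    BM = evo_model("BM", sigma2 = runif(1, 0.3, 2)),
    OU = evo_model("OU", sigma2 = runif(1, 0.3, 2), alpha = runif(1, 0.1, 3)),
    lambda = evo_model("lambda", sigma2 = runif(1, 0.3, 2), lambda = runif(1)),
    delta = evo_model("delta", sigma2 = runif(1, 0.3, 2), delta = runif(1, 0.2, 2.8)),
    kappa = evo_model("kappa", sigma2 = runif(1, 0.3, 2), kappa = runif(1)),
    white = evo_model("white", sigma2 = runif(1, 0.3, 2)),
    trend = evo_model("trend", sigma2 = runif(1, 0.3, 2), trend_b = runif(1, -0.25, 1.5)))
}

sorted_trait <- function(phy, values) {
  stats::setNames(values, sort(phy$tip.label))
}
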