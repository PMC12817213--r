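test_that("model specifications enforce parameter ownership and bounds", {
  expect_error(evo_model("BM", sigma2 = -1), "sigma2")
  expect_error(evo_model("BM", lambda = 0.5), "do not belong")
  expect_error(evo_model("lambda", lambda = 1.2), "out of bounds")
  expect_error(evo_model("delta", delta = 0), "out of bounds")
  expect_error(evo_model("kappa", kappa = -0.1), "out of bounds")
  m <- evo_model("OU", sigma2 = 2, alpha = 0.5)
  expect_equal(m$shape, 0.5)
})

test_that("model covariances match their defining transformations", {
  tr <- toy_tree()
  C <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))

  expect_equal(unname(model_covariance(tr, evo_model("BM", 1.7))), 1.7 * C)
  expect_equal(unname(model_covariance(tr, evo_model("white", 0.3))),
               0.3 * diag(3))

  # kappa = 0 equalises all branch lengths
  expect_equal(unname(model_covariance(tr, evo_model("kappa", 2, kappa = 0))),
               2 * rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 1)))

  # lambda scales only the off-diagonal
  Vl <- model_covariance(tr, evo_model("lambda", 1, lambda = 0.5))
  expect_equal(unname(Vl), rbind(c(2, 0.5, 0), c(0.5, 2, 0), c(0, 0, 2)))

  # strong OU pull decouples the tips: closed form at alpha = 10, depth 2
  Vou <- model_covariance(tr, evo_model("OU", 1, alpha = 10))
  expect_equal(Vou["A", "B"],
               (1 / 20) * exp(-2 * 10 * (2 - 1)) * (1 - exp(-2 * 10 * 1)))
  expect_lt(Vou["A", "B"], 1e-8)
  expect_equal(Vou["A", "A"], (1 / 20) * (1 - exp(-2 * 10 * 2)))
})

test_that("OU and delta refuse non-ultrametric trees", {
  tr <- read_newick(text = "((A:1,B:2):1,C:2);")
  expect_error(model_covariance(tr, evo_model("OU", 1, alpha = 1)),
               "ultrametric")
  expect_error(model_covariance(tr, evo_model("delta", 1, delta = 2)),
               "ultrametric")
  # lambda, kappa, trend and white remain defined
  expect_silent(model_covariance(tr, evo_model("kappa", 1, kappa = 0.5)))
  expect_silent(model_covariance(tr, evo_model("trend", 1, trend_b = -0.9)))
})

test_that("every model reproduces Brownian motion at its nest point", {
  for (i in 1:10) {
    tr <- simulate_tree(sample(4:25, 1), seed = 400 + i)
    Vbm <- model_covariance(tr, evo_model("BM", 1.3))
    nests <- list(evo_model("lambda", 1.3, lambda = 1),
                  evo_model("delta", 1.3, delta = 1),
                  evo_model("kappa", 1.3, kappa = 1),
                  evo_model("OU", 1.3, alpha = 1e-9),
                  evo_model("trend", 1.3, trend_b = 0))
    for (m in nests)
      expect_equal(model_covariance(tr, m), Vbm, tolerance = 1e-8)
  }
})

test_that("covariances scale linearly in sigma2", {
  tr <- simulate_tree(12, seed = 9)
  for (nm in c("BM", "OU", "lambda", "delta", "kappa", "white", "trend")) {
    set.seed(50)
    m1 <- random_model(nm); m3 <- m1; m3$sigma2 <- 3 * m1$sigma2
    expect_equal(model_covariance(tr, m3), 3 * model_covariance(tr, m1),
                 tolerance = 1e-12)
  }
})

test_that("trait simulation is deterministic and degenerate at sigma2 = 0", {
  tr <- simulate_tree(10, seed = 2)
  m <- evo_model("BM", 1, z0 = 3)
  expect_identical(simulate_trait(tr, m, seed = 7), simulate_trait(tr, m, seed = 7))
  z <- simulate_trait(tr, evo_model("BM", 0, z0 = 5), seed = 1)
  expect_true(all(z == 5))
  expect_identical(names(z), sort(tr$tip.label))
})

test_that("simulated traits reproduce the model covariance empirically", {
  tr <- simulate_tree(5, seed = 21)
  m <- evo_model("lambda", 0.8, z0 = 1, lambda = 0.6)
  V <- model_covariance(tr, m)
  nrep <- 4000
  X <- t(vapply(seq_len(nrep),
                function(i) simulate_trait(tr, m, seed = 70000 + i),
                numeric(5)))
  Vhat <- stats::cov(X)
  mc_se <- sqrt((outer(diag(V), diag(V)) + V^2) / nrep)
  expect_true(all(abs(Vhat - V) <= 3.5 * mc_se))
  expect_true(all(abs(colMeans(X) - 1) <= 3.5 * sqrt(diag(V) / nrep)))
})

test_that("lambda = 0 draws are mutually uncorrelated across tips", {
  tr <- simulate_tree(5, seed = 22)
  m <- evo_model("lambda", 1, lambda = 0)
  X <- t(vapply(1:4000, function(i) simulate_trait(tr, m, seed = 90000 + i),
                numeric(5)))
  R <- stats::cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 3.5 / sqrt(4000))
})

test_that("profiled log-likelihood matches closed forms on tiny trees", {
  # single tip: univariate normal density at the profiled mean
  single <- read_newick(text = "(A:1.5);")
  out <- log_likelihood(c(A = 0.7), single, evo_model("BM", 2))
  expect_equal(out$lnL, -0.5 * log(2 * pi * 2 * 1.5))
  expect_equal(out$z0_hat, 0.7)

  # three tips, x = 0: lnL = -(1/2) [3 log(2 pi) + log |C|], |C| = 6
  out3 <- log_likelihood(c(A = 0, B = 0, C = 0), toy_tree(), evo_model("BM", 1))
  expect_equal(out3$lnL, -0.5 * (3 * log(2 * pi) + log(6)))
  expect_equal(out3$z0_hat, 0)
})

test_that("linear-time likelihood equals the dense multivariate-normal oracle", {
  set.seed(77)
  nms <- c("BM", "OU", "lambda", "delta", "kappa", "white", "trend")
  for (i in 1:100) {
    tr <- simulate_tree(sample(4:8, 1), seed = 500 + i)
    m <- random_model(sample(nms, 1))
    n <- length(tr$tip.label)
    y <- sorted_trait(tr, rnorm(n, sd = 2))
    se <- if (i %% 2) sorted_trait(tr, runif(n, 0.05, 0.4)) else NULL
    got <- log_likelihood(y, tr, m, se = se)
    want <- dense_profiled_lnL(tr, y, m, se = se)
    expect_equal(got$lnL, want$lnL, tolerance = 1e-8)
    expect_equal(got$z0_hat, want$z0, tolerance = 1e-8)
  }
})

test_that("the clamped trend regime stays finite and PSD-consistent", {
  # a steep negative rate slope drives the late-time rate onto its floor,
  # leaving tips that diverged after the clamp almost perfectly correlated;
  # the kernel and the dense route must still agree to the conditioning limit
  tr <- simulate_tree(6, seed = 518)
  m <- evo_model("trend", 1, trend_b = -1.2)
  y <- sorted_trait(tr, rnorm(6))
  got <- log_likelihood(y, tr, m)$lnL
  want <- dense_profiled_lnL(tr, y, m)$lnL
  expect_true(is.finite(got))
  expect_equal(got, want, tolerance = 1e-6)
  V <- model_covariance(tr, m)
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("log-likelihood is invariant to tip reordering", {
  set.seed(8)
  for (i in 1:10) {
    tr <- simulate_tree(sample(5:20, 1), seed = 600 + i)
    m <- random_model(sample(c("BM", "lambda", "OU"), 1))
    y <- sorted_trait(tr, rnorm(length(tr$tip.label)))
    perm <- sample(names(y))
    expect_equal(log_likelihood(y[perm], tr, m)$lnL,
                 log_likelihood(y, tr, m)$lnL, tolerance = 1e-12)
  }
})
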