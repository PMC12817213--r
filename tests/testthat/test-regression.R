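make_records <- function(species, n_records, n_event, extra = NULL) {
  d <- data.frame(species = species, n_records = n_records, n_event = n_event)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

test_that("prevalence standard errors use the shrunk proportion", {
  out <- prevalence_se(c(0, 5), c(10, 10))
  expect_equal(out$prevalence, c(0, 0.5))
  expect_equal(out$se[1], sqrt((0.5 / 11) * (10.5 / 11) / 10), tolerance = 1e-10)
  expect_equal(out$se[1], 0.0659, tolerance = 1e-3)
  expect_equal(out$se[2], sqrt(0.25 / 10), tolerance = 1e-10)
  expect_equal(out$se[2], 0.1581, tolerance = 1e-4)
  expect_true(all(out$se > 0))
  # se vanishes as records accumulate at fixed prevalence
  ns <- 10^(1:6)
  expect_true(all(diff(prevalence_se(0.3 * ns, ns)$se) < 0))
  expect_error(prevalence_se(1, 0), "n_records")
  expect_error(prevalence_se(11, 10), "n_event")
})

star_data <- function(n = 30, seed = 1, sd_y = 0.1, slope = 0.5) {
  set.seed(seed)
  sp <- paste0("s", 1:n)
  star <- ape::stree(n, "star")
  star$tip.label <- sp
  star$edge.length <- rep(1, n)
  x <- runif(n)
  y <- 0.4 + slope * x + rnorm(n, 0, sd_y)
  rec <- data.frame(species = sp, n_records = rep(50, n),
                    n_event = round(pmin(pmax(y, 0), 1) * 50))
  rec$prevalence <- pmin(pmax(y, 0), 1)
  rec$se <- rep(0, n)
  list(tree = star, x = stats::setNames(x, sp), records = rec)
}

test_that("all PGLS variants collapse to ordinary least squares on a star tree", {
  d <- star_data()
  ols <- summary(stats::lm(d$records$prevalence ~ d$x))$coefficients
  for (fn in list(pgls_sey, pgls_sey_pagel,
                  function(...) pgls_sey_optim(..., n_starts = 2, seed = 1))) {
    r <- fn(d$tree, d$x, d$records)
    expect_equal(r$slope, ols[2, 1], tolerance = 1e-8)
    expect_equal(r$slope_se, ols[2, 2], tolerance = 1e-6)
    expect_equal(r$p_value, ols[2, 4], tolerance = 1e-6)
  }
})

test_that("an exact linear relationship yields the exact slope and p near zero", {
  tr <- simulate_tree(25, seed = 40)
  sp <- tr$tip.label
  x <- stats::setNames(seq(0, 1, length.out = 25), sp)
  rec <- data.frame(species = sp, n_records = 100, n_event = 50)
  rec$prevalence <- 0.1 + 2 * unname(x) # exact line (allowed > 1 here? clip)
  rec$prevalence <- rec$prevalence / max(rec$prevalence) * 0.9
  slope_true <- 2 / max(0.1 + 2) * 0.9
  rec$se <- rep(0.01, 25)
  r <- pgls_sey(tr, x, rec)
  expect_equal(r$slope, slope_true, tolerance = 1e-6)
  expect_lt(r$p_value, 1e-12)
})

test_that("lambda-PGLS nests Brownian PGLS at lambda = 1", {
  tr <- simulate_tree(40, seed = 41)
  y <- simulate_trait(tr, evo_model("BM", 0.05, z0 = 0.5), seed = 42)
  sp <- tr$tip.label
  rec <- data.frame(species = sp, n_records = 60,
                    n_event = round(pmin(pmax(y[sp], 0.01), 0.99) * 60))
  x <- stats::setNames(runif(40), sp)
  bm <- pgls_sey(tr, x, rec)
  # evaluate the lambda machinery with lambda pinned at 1 and the BM rate
  pt <- phylopcm:::as_ptree(prune_to_taxa(tr, sp))
  d <- phylopcm:::prepare_regression_data(tr, x, rec)
  g <- bm$sigma2 / bm$resid_scale
  lam1 <- phylopcm:::gls_slope(pt, "lambda", g, 1, d$records$se^2, d$x,
                               d$records$prevalence, "REML", "pinned")
  expect_equal(lam1$slope, bm$slope, tolerance = 1e-8)
  expect_equal(lam1$p_value, bm$p_value, tolerance = 1e-8)
})

test_that("lambda-PGLS recovers strong and absent phylogenetic signal", {
  hi <- lo <- 0
  for (i in 1:10) {
    tr <- simulate_tree(200, seed = 1400 + i)
    sp <- tr$tip.label
    x <- stats::setNames(runif(200), sp)
    yb <- simulate_trait(tr, evo_model("lambda", 0.04, z0 = 0.5, lambda = 1),
                         seed = 1500 + i)
    yw <- stats::setNames(runif(200, 0.2, 0.8), sort(sp))
    mk <- function(y) {
      p <- pmin(pmax(y[sp], 0.01), 0.99)
      data.frame(species = sp, n_records = 200, n_event = round(p * 200))
    }
    hi <- hi + (pgls_sey_pagel(tr, x, mk(yb))$lambda > 0.8)
    lo <- lo + (pgls_sey_pagel(tr, x, mk(yw))$lambda < 0.2)
  }
  expect_gte(hi, 9)
  expect_gte(lo, 9)
})

test_that("PGLS slopes are equivariant under predictor scaling and response shifts", {
  tr <- simulate_tree(30, seed = 43)
  sp <- tr$tip.label
  x <- stats::setNames(runif(30), sp)
  y <- simulate_trait(tr, evo_model("BM", 0.03, z0 = 0.5), seed = 44)
  rec <- data.frame(species = sp, prevalence = pmin(pmax(y[sp], 0), 1),
                    n_records = 80, se = rep(0.05, 30))
  base <- pgls_sey(tr, x, rec)
  scaled <- pgls_sey(tr, 4 * x, rec)
  expect_equal(scaled$slope, base$slope / 4, tolerance = 1e-6)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-6)
  rec2 <- rec; rec2$prevalence <- rec$prevalence + 0.1
  shifted <- pgls_sey(tr, x, rec2)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-6)
  expect_equal(shifted$intercept, base$intercept + 0.1, tolerance = 1e-6)
})

test_that("pgls_sey agrees with the reference gls-based implementation", {
  tr <- phylopcm:::rescale_tree_height(simulate_tree(60, seed = 45))
  cnt <- simulate_records(60, 5, seed = 46)
  trial <- simulate_slope_trial(tr, "BM", 0.8, cnt, seed = 47)
  rec <- trial$records
  mine <- pgls_sey(tr, trial$x, rec)
  dat <- data.frame(y = rec$prevalence, x = unname(trial$x[rec$species]),
                    row.names = rec$species)
  ref <- phytools::pgls.SEy(y ~ x, data = dat, tree = tr,
                            se = stats::setNames(rec$se, rec$species),
                            method = "REML")
  tt <- summary(ref)$tTable
  expect_equal(mine$slope, tt[2, 1], tolerance = 1e-4)
  expect_equal(mine$slope_se, tt[2, 2], tolerance = 1e-3)
  expect_equal(mine$p_value, tt[2, 4], tolerance = 1e-3)
})

test_that("model-selected PGLS is deterministic and reports its stage-1 choice", {
  tr <- phylopcm:::rescale_tree_height(simulate_tree(80, seed = 48))
  cnt <- simulate_records(80, 10, seed = 49)
  trial <- simulate_slope_trial(tr, "BM", 1, cnt, seed = 50)
  r1 <- pgls_sey_optim(tr, trial$x, trial$records, n_starts = 3, seed = 51)
  r2 <- pgls_sey_optim(tr, trial$x, trial$records, n_starts = 3, seed = 51)
  expect_identical(r1$slope, r2$slope)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$chosen_model, r2$chosen_model)
  expect_true(r1$chosen_model %in%
                c("BM", "OU", "lambda", "delta", "kappa", "white", "trend"))
})

test_that("white-noise responses select white and match weighted regression", {
  tr <- simulate_tree(150, seed = 52)
  sp <- tr$tip.label
  set.seed(53)
  x <- stats::setNames(runif(150), sp)
  y <- 0.5 + 0.3 * (x - 0.5) + rnorm(150, 0, 0.08)
  p <- pmin(pmax(y, 0.02), 0.98)
  nr <- sample(c(30, 60, 200), 150, TRUE)
  rec <- data.frame(species = sp, n_records = nr, n_event = round(p * nr))
  r <- pgls_sey_optim(tr, x, rec, n_starts = 2, seed = 54)
  expect_identical(r$chosen_model, "white")
  w <- 1 / (r$evo_model$sigma2 + prevalence_se(rec$n_event, rec$n_records)$se^2)
  ref <- summary(stats::lm(rec$n_event / rec$n_records ~ unname(x[rec$species]),
                           weights = w))$coefficients
  expect_equal(r$slope, ref[2, 1], tolerance = 1e-8)
  expect_equal(r$slope_se, ref[2, 2], tolerance = 1e-8)
  expect_equal(r$p_value, ref[2, 4], tolerance = 1e-8)
})

test_that("the binomial GEE on a star tree equals the quasibinomial GLM", {
  d <- star_data(n = 40, seed = 55, sd_y = 0.15, slope = 0.8)
  r <- gee_binomial(d$tree, d$x, d$records)
  yv <- d$records$n_event / d$records$n_records
  ref <- summary(stats::glm(yv ~ unname(d$x[d$records$species]),
                            family = stats::quasibinomial()))
  expect_equal(r$slope, ref$coefficients[2, 1], tolerance = 1e-6)
  expect_equal(r$intercept, ref$coefficients[1, 1], tolerance = 1e-6)
  expect_equal(r$slope_se, sqrt(ref$cov.scaled[2, 2]), tolerance = 1e-8)
})

test_that("the GEE is quiet under a flat response and unrelated predictor", {
  # star tree: the GEE estimator coincides with the GLM its SEs come from,
  # so truly binomial data around 0.5 should look null
  star <- ape::stree(60, "star"); star$edge.length <- rep(1, 60)
  sp <- star$tip.label
  set.seed(57)
  x <- stats::setNames(runif(60), sp)
  ev <- rbinom(60, 100, 0.5)
  rec <- data.frame(species = sp, n_records = 100, n_event = ev)
  r <- gee_binomial(star, x, rec)
  expect_lt(abs(r$slope), 0.5)
  expect_gt(r$p_value, 0.05)
})

test_that("the GEE inflates false positives on overdispersed null data", {
  hits <- 0; n_rep <- 100
  for (i in 1:n_rep) {
    tr <- phylopcm:::rescale_tree_height(simulate_tree(100, seed = 1600 + i))
    cnt <- simulate_records(100, 5, seed = 1700 + i)
    trial <- simulate_null_trial(tr$tip.label, cnt, seed = 1800 + i)
    r <- tryCatch(gee_binomial(tr, trial$x, trial$records),
                  error = function(e) NULL)
    if (!is.null(r) && !is.na(r$p_value)) hits <- hits + (r$p_value < 0.05)
  }
  expect_gt(hits / n_rep, 0.15) # far above the nominal 5 percent
})

test_that("regression inputs are validated with informative errors", {
  tr <- simulate_tree(10, seed = 58)
  sp <- tr$tip.label
  rec <- data.frame(species = sp, prevalence = runif(10), se = 0.1)
  expect_error(gee_binomial(tr, stats::setNames(runif(10), sp), rec),
               "counts required")
  rec2 <- data.frame(species = sp[1:3], n_records = 10, n_event = 5)
  expect_error(pgls_sey(tr, stats::setNames(runif(3), sp[1:3]), rec2),
               "at least 4")
  rec3 <- data.frame(species = sp, n_records = 10, n_event = 5)
  expect_error(pgls_sey(tr, stats::setNames(rep(1, 10), sp), rec3),
               "constant")
  rec4 <- data.frame(species = c(sp, "nowhere"), n_records = 10, n_event = 5)
  expect_error(pgls_sey(tr, stats::setNames(runif(11), c(sp, "nowhere")), rec4),
               "nowhere")
})
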