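# Phylogenetic regressions for species-level prevalence traits with
# binomial sampling error, plus the phylogenetic binomial GEE.

#' Prevalence and its sampling standard error from necropsy counts
#'
#' The point estimate is the raw proportion `n_event / n_records`; the
#' standard error uses a lightly shrunk proportion
#' `p_tilde = (n_event + 0.5) / (n_records + 1)` so the SE is strictly
#' positive even for prevalences of exactly 0 or 1.
#'
#' @param n_event number of individuals with the event (vectorised).
#' @param n_records number of necropsy records per species (>= 1).
#' @return a data.frame with columns `prevalence` and `se`.
#' @examples
#' prevalence_se(c(0, 5), c(10, 10))
#' @export
prevalence_se <- function(n_event, n_records) {
  if (any(n_records < 1)) stopf("n_records must be >= 1")
  if (any(n_event < 0 | n_event > n_records))
    stopf("n_event must lie in [0, n_records]")
  p_tilde <- (n_event + 0.5) / (n_records + 1)
  data.frame(prevalence = n_event / n_records,
             se = sqrt(p_tilde * (1 - p_tilde) / n_records))
}

# Validate/complete a species record table and align it with the tree.
# Returns list(phy = pruned tree, records = table in phy$tip.label order, x).
prepare_regression_data <- function(phy, x, records) {
  if (!is.data.frame(records) || is.null(records$species))
    stopf("records must be a data.frame with a 'species' column")
  if (anyDuplicated(records$species))
    stopf("duplicated species in records: %s",
          paste(unique(records$species[duplicated(records$species)]), collapse = ", "))
  if (is.null(records$prevalence) || is.null(records$se)) {
    if (is.null(records$n_event) || is.null(records$n_records))
      stopf("records needs either prevalence + se or n_event + n_records")
    ps <- prevalence_se(records$n_event, records$n_records)
    if (is.null(records$prevalence)) records$prevalence <- ps$prevalence
    if (is.null(records$se)) records$se <- ps$se
  }
  if (any(records$prevalence < 0 | records$prevalence > 1))
    stopf("prevalence outside [0, 1]")
  if (any(records$se < 0)) stopf("negative sampling SE")
  if (is.character(x) && length(x) == 1) {
    if (is.null(records[[x]])) stopf("predictor column '%s' not found", x)
    x <- stats::setNames(records[[x]], records$species)
  }
  if (is.null(names(x)) && length(x) == nrow(records))
    names(x) <- records$species
  missing <- setdiff(records$species, phy$tip.label)
  if (length(missing))
    stopf("species absent from tree: %s", paste(missing, collapse = ", "))
  phy <- prune_to_taxa(phy, records$species)
  ord <- match(phy$tip.label, records$species)
  records <- records[ord, , drop = FALSE]
  xv <- x[phy$tip.label]
  if (anyNA(xv)) stopf("predictor is missing for some species")
  n <- nrow(records)
  if (n < 4) stopf("at least 4 species are required")
  if (stats::var(xv) == 0) stopf("predictor is constant (collinear design)")
  list(phy = phy, records = records, x = unname(xv))
}

new_regression_result <- function(method, beta, se_slope, stat, df, p, n,
                                  extra = list()) {
  structure(c(list(method = method, intercept = beta[1], slope = beta[2],
                   slope_se = se_slope, statistic = stat, df = df,
                   p_value = p, n_species = n), extra),
            class = "pcm_regression")
}

#' @export
print.pcm_regression <- function(x, ...) {
  cat(sprintf("<pcm_regression> %s (n = %d)\n", x$method, x$n_species))
  cat(sprintf("  slope = %.6g (SE %.3g), %s = %.4g, df = %.4g, p = %.4g\n",
              x$slope, x$slope_se, if (x$method == "gee_binomial") "t" else "t",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$evo_model) && inherits(x$evo_model, "evo_model")) print(x$evo_model)
  if (!is.null(x$lambda)) cat(sprintf("  lambda_hat = %.4f\n", x$lambda))
  invisible(x)
}

# Shared GLS machinery.  The working covariance is
#   s^2 * (g * C(model, shape) + diag(se^2)),
# i.e. the phylogenetic rate g is estimated *relative* to the known
# sampling variances, and the overall residual scale s^2 is estimated from
# the regression residuals (REML by default, as in gls-based PGLS
# implementations).  Residual-scale estimation is what keeps the slope test
# honest when the phylogenetic structure is misspecified: the reported
# slope covariance is s^2 (X' Vrel^-1 X)^-1.
gls_eval <- function(pt, name, g, shape, se2, x, y, method) {
  k <- kernel_gls(pt, name, g, shape, se2, x, y)
  n <- pt$ntip
  p <- 2
  quad <- max(k$quad, 1e-300)
  if (method == "REML") {
    s2 <- quad / (n - p)
    ldXVX <- -determinant(k$cov_unscaled)$modulus # log|X' Vrel^-1 X|
    crit <- (n - p) * log(quad) + k$logdet + ldXVX
    lnL <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + k$logdet + ldXVX)
  } else {
    s2 <- quad / n
    crit <- n * log(quad) + k$logdet
    lnL <- -0.5 * (n * (log(2 * pi * s2) + 1) + k$logdet)
  }
  list(beta = k$beta, cov = s2 * k$cov_unscaled, s2 = s2, crit = crit,
       lnL = lnL)
}

gls_slope <- function(pt, name, g, shape, se2, x, y, method, label,
                      extra = list()) {
  e <- gls_eval(pt, name, g, shape, se2, x, y, method)
  n <- pt$ntip
  se_slope <- sqrt(e$cov[2, 2])
  tval <- e$beta[2] / se_slope
  df <- n - 2
  p <- 2 * stats::pt(-abs(tval), df)
  new_regression_result(label, e$beta, se_slope, tval, df, p, n,
                        c(list(lnL = e$lnL, sigma2 = g * e$s2,
                               resid_scale = e$s2, method_fit = method),
                          extra))
}

# generous data-driven search range for the relative rate g (log scale)
g_search_range <- function(pt, y) {
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  ctr <- log(vy / pt$height)
  c(max(log(1e-12), ctr - 22), ctr + 14, ctr)
}

#' Brownian-motion PGLS with sampling error in the response
#'
#' Generalised least squares of prevalence on a predictor with working
#' covariance `s^2 (g * C_BM + diag(se^2))`, where `C_BM` is the Brownian
#' phylogenetic covariance and `se` the per-species sampling SE of
#' prevalence.  The relative Brownian rate `g` is estimated by maximising
#' the (restricted) likelihood jointly with the regression coefficients,
#' with the residual scale `s^2` profiled from the residual quadratic form;
#' the slope is tested with a t statistic on `n - 2` degrees of freedom.
#' This mirrors gls-based PGLS-with-sampling-error implementations, in
#' which the phylogeny-plus-error structure is a correlation structure
#' whose overall scale is estimated from the residuals.
#'
#' @param phy a `phylo` object; pruned automatically to the table's species.
#' @param x predictor: a named numeric vector (names = species) or the name
#'   of a column in `records`.
#' @param records species table with columns `species` and either
#'   `prevalence` + `se` or `n_event` + `n_records` (SEs derived via
#'   [prevalence_se()]).
#' @param method `"REML"` (default) or `"ML"` for the variance components.
#' @return a `pcm_regression` object.
#' @export
pgls_sey <- function(phy, x, records, method = c("REML", "ML")) {
  method <- match.arg(method)
  d <- prepare_regression_data(phy, x, records)
  pt <- as_ptree(d$phy)
  se2 <- d$records$se^2
  y <- d$records$prevalence
  rng <- g_search_range(pt, y)
  f <- function(lg) {
    v <- gls_eval(pt, "BM", exp(lg), NA_real_, se2, d$x, y, method)$crit
    if (!is.finite(v)) 1e12 else v
  }
  lg <- stats::optimize(f, rng[1:2], tol = 1e-8)$minimum
  gls_slope(pt, "BM", exp(lg), NA_real_, se2, d$x, y, method, "pgls_sey",
            list(evo_model = evo_model("BM", sigma2 = exp(lg))))
}

#' PGLS with sampling error and jointly estimated Pagel's lambda
#'
#' As [pgls_sey()] but with working covariance
#' `s^2 (g * C_lambda + diag(se^2))`; `lambda` is estimated by maximising
#' the (restricted) likelihood jointly with `g` and the regression
#' coefficients, and the fitted `lambda` is reported.
#'
#' @inheritParams pgls_sey
#' @return a `pcm_regression` object with an extra `lambda` element.
#' @export
pgls_sey_pagel <- function(phy, x, records, method = c("REML", "ML")) {
  method <- match.arg(method)
  d <- prepare_regression_data(phy, x, records)
  pt <- as_ptree(d$phy)
  se2 <- d$records$se^2
  y <- d$records$prevalence
  rng <- g_search_range(pt, y)
  obj <- function(par) {
    v <- gls_eval(pt, "lambda", exp(par[1]), par[2], se2, d$x, y, method)$crit
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (lam0 in c(0.05, 0.5, 0.95)) {
    o <- tryCatch(stats::optim(c(rng[3], lam0), obj, method = "L-BFGS-B",
                               lower = c(rng[1], 0), upper = c(rng[2], 1),
                               control = list(factr = 1e7)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stopf("lambda-PGLS optimisation failed")
  lam <- best$par[2]
  gls_slope(pt, "lambda", exp(best$par[1]), lam, se2, d$x, y, method,
            "pgls_sey_pagel",
            list(lambda = lam,
                 evo_model = evo_model("lambda", sigma2 = exp(best$par[1]),
                                       lambda = lam)))
}

#' Model-selected PGLS with sampling error (two-stage)
#'
#' Stage 1 fits all seven evolution models to the response (including the
#' sampling-error diagonal) via [fit_all_models()] and selects the AIC-best
#' model.  By default the selection is a plain AIC argmin (`delta_aic = 0`):
#' on an ultrametric tree the lambda model reproduces the white-noise
#' likelihood at `lambda = 0` (and Brownian motion at `lambda = 1`), so no
#' simpler model can ever beat it by a large AIC margin and a
#' decisive-support threshold would collapse every selection to the
#' Brownian fallback.  Setting `delta_aic > 0` applies the decisive rule,
#' with an `"uncertain"` verdict falling back to Brownian motion, the
#' conventional null model.  Stage 2 uses the selected
#' model's fitted covariance plus `diag(se^2)` as the fixed correlation
#' structure in GLS (only the residual scale `s^2` is re-estimated from the
#' regression residuals) and reports slope inference as in [pgls_sey()].
#'
#' @inheritParams pgls_sey
#' @param n_starts multi-start count for the stage-1 model fits.
#' @param seed optional seed for the stage-1 starting points.
#' @param delta_aic decisive-support threshold for stage 1 (default 0:
#'   plain AIC argmin).
#' @return a `pcm_regression` object with extra elements `chosen_model`,
#'   `selection` (the stage-1 [fit_all_models] object) and `fallback`
#'   (`TRUE` when stage 1 failed entirely and BM was used with a warning).
#' @export
pgls_sey_optim <- function(phy, x, records, n_starts = 5, seed = NULL,
                           delta_aic = 0, method = c("REML", "ML")) {
  method <- match.arg(method)
  d <- prepare_regression_data(phy, x, records)
  pt <- as_ptree(d$phy)
  se2 <- d$records$se^2
  y <- d$records$prevalence
  ultra <- is_ultrametric(d$phy)
  models <- if (ultra) model_names() else setdiff(model_names(), c("OU", "delta"))
  sel <- tryCatch(
    fit_all_models(d$phy, stats::setNames(y, d$phy$tip.label),
                   se = stats::setNames(d$records$se, d$phy$tip.label),
                   n_starts = n_starts, seed = seed, delta_aic = delta_aic,
                   models = models),
    error = function(e) NULL)
  fallback <- FALSE
  if (is.null(sel)) {
    warning("stage-1 model fitting failed entirely; falling back to Brownian motion",
            call. = FALSE)
    fallback <- TRUE
    chosen <- "BM"
    mod <- NULL
  } else {
    chosen <- if (sel$best == "uncertain") "BM" else sel$best
    mod <- sel$fits[[chosen]]$model
    if (is.null(mod)) { # chosen fit failed to produce parameters
      chosen <- "BM"
      mod <- sel$fits[["BM"]]$model
    }
  }
  if (is.null(mod)) { # total stage-1 failure: estimate the BM rate directly
    rng <- g_search_range(pt, y)
    f <- function(lg) {
      v <- gls_eval(pt, "BM", exp(lg), NA_real_, se2, d$x, y, method)$crit
      if (!is.finite(v)) 1e12 else v
    }
    mod <- evo_model("BM", sigma2 = exp(stats::optimize(f, rng[1:2])$minimum))
  }
  gls_slope(pt, mod$name, mod$sigma2, mod$shape, se2, d$x, y, method,
            "pgls_sey_optim",
            list(chosen_model = chosen, evo_model = mod,
                 selection = if (fallback) NULL else sel,
                 fallback = fallback))
}

#' Phylogenetic binomial GEE (logit link)
#'
#' Binomial-logit generalised estimating equations for species-level tumour
#' counts with a fixed phylogenetic working correlation, emulating the
#' classic comparative GEE: each species enters as one observation, its
#' prevalence `n_event / n_records` with working variance
#' `phi * mu * (1 - mu)` *regardless of how many records back it* - the
#' method deliberately ignores variation in trials per species and models
#' overdispersion only through a global Pearson scale.  Coefficients solve
#' the GEE score equations under the Brownian working correlation (the
#' phylogenetic covariance normalised to unit diagonal); standard errors
#' come from the overdispersion-scaled independence (quasi-binomial GLM)
#' covariance, as in the classic implementation, so the phylogenetically
#' weighted estimator is paired with a non-phylogenetic variance - the
#' mismatch that underestimates standard errors and inflates significance
#' on phylogenetically sampled or overdispersed data.  The slope is tested
#' against a t distribution on `dfP - 2` degrees of freedom, where
#' `dfP = n * L / trace(C)` is the phylogenetic degrees of freedom
#' (`L` total branch length, `C` the phylogenetic covariance).
#'
#' @inheritParams pgls_sey
#' @param maxit maximum Fisher-scoring iterations (default 50).
#' @param tol convergence tolerance on the coefficient update (default 1e-8).
#' @param df_correction apply the phylogenetic degrees-of-freedom correction
#'   (default `TRUE`; otherwise `df = n - 2`).
#' @return a `pcm_regression` object with extra elements `iterations`,
#'   `scale` (the Pearson overdispersion estimate) and `dfP`.
#' @export
gee_binomial <- function(phy, x, records, maxit = 50, tol = 1e-8,
                         df_correction = TRUE) {
  d <- prepare_regression_data(phy, x, records)
  if (is.null(d$records$n_event) || is.null(d$records$n_records))
    stopf("counts required: the binomial GEE needs n_event and n_records")
  n <- nrow(d$records)
  yv <- d$records$n_event / d$records$n_records
  X <- cbind(1, d$x)
  Cv <- ape::vcv.phylo(d$phy) + root_stem(d$phy)
  Rcor <- stats::cov2cor(Cv)

  # GEE coefficients: Fisher scoring under V = phi * A^(1/2) R A^(1/2),
  # A = mu(1-mu) per species (the scale phi cancels in the score equations)
  score_pieces <- function(beta) {
    eta <- pmin(pmax(drop(X %*% beta), -20), 20)
    mu <- stats::plogis(eta)
    a <- pmax(mu * (1 - mu), 1e-7)
    Vw <- sqrt(a) * Rcor * rep(sqrt(a), each = n)
    Rc <- tryCatch(chol(Vw), error = function(e) NULL)
    if (is.null(Rc)) return(NULL)
    D <- a * X
    iVD <- backsolve(Rc, backsolve(Rc, D, transpose = TRUE))
    iVr <- backsolve(Rc, backsolve(Rc, yv - mu, transpose = TRUE))
    U <- drop(crossprod(D, iVr))
    list(info = crossprod(D, iVD), U = U, unorm = sqrt(sum(U^2)))
  }
  beta <- c(stats::qlogis(min(max(mean(yv), 0.02), 0.98)), 0)
  sp <- score_pieces(beta)
  if (is.null(sp)) stopf("GEE working covariance is singular at the start")
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    delta <- drop(solve(sp$info, sp$U))
    # safeguarded scoring: halve the step until the score norm decreases
    step <- 1
    repeat {
      cand <- beta + step * delta
      sp_new <- score_pieces(cand)
      if (!is.null(sp_new) && sp_new$unorm <= sp$unorm * (1 + 1e-12)) break
      step <- step / 2
      if (step < 1e-10) { sp_new <- sp; cand <- beta; break }
    }
    move <- max(abs(cand - beta))
    beta <- cand
    sp <- sp_new
    trace <- c(trace, move)
    if (move < tol * (1 + max(abs(beta)))) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("GEE did not converge in %d iterations (update trace: %s)", maxit,
          paste(signif(utils::tail(trace, 5), 3), collapse = ", "))

  # overdispersion-scaled independence covariance from the quasi-binomial
  # GLM (refit on its own, as in the classic implementation)
  glm_fit <- stats::glm(yv ~ d$x, family = stats::quasibinomial())
  W <- summary(glm_fit)$cov.scaled
  se_b <- unname(sqrt(diag(W)))

  dfP <- (sum(d$phy$edge.length) + root_stem(d$phy)) * n / sum(diag(Cv))
  df <- if (df_correction) dfP - 2 else n - 2
  tval <- beta[2] / se_b[2]
  p <- if (df > 0) 2 * stats::pt(-abs(tval), df) else NA_real_
  if (df <= 0)
    warning("not enough phylogenetic degrees of freedom to compute a P-value",
            call. = FALSE)
  new_regression_result("gee_binomial", beta, se_b[2], tval, df, p, n,
                        list(iterations = it, dfP = dfP,
                             scale = summary(glm_fit)$dispersion))
}
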