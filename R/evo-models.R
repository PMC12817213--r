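#' Specify a continuous-trait evolution model
#'
#' Builds a parameterised model of continuous trait evolution on a phylogeny.
#' All seven models act on the phylogenetic variance-covariance matrix:
#'
#' * `BM` - Brownian motion; variance accumulates linearly along branches
#'   at rate `sigma2`.
#' * `OU` - Ornstein-Uhlenbeck with pull `alpha` towards a central value
#'   (fixed-root form on an ultrametric tree; the optimum is absorbed into
#'   the root state `z0`, as in standard maximum-likelihood fitters).
#' * `lambda` - Pagel's lambda multiplies the off-diagonal covariances:
#'   0 means phylogenetic independence, 1 recovers Brownian motion.
#' * `delta` - power transform of relative node depths; `delta > 1`
#'   accelerates evolution towards the present, `< 1` decelerates it.
#' * `kappa` - power transform of branch lengths; `kappa = 0` equalises all
#'   branches so change is proportional to speciation events, 1 keeps time.
#' * `white` - no phylogenetic structure; i.i.d. tips with variance `sigma2`.
#' * `trend` - Brownian motion whose instantaneous rate changes linearly in
#'   time, `r(t) = sigma2 * (1 + trend_b * t)`, clamped at a tiny positive
#'   floor so the covariance stays positive semi-definite for any slope.
#'
#' @param name one of `"BM"`, `"OU"`, `"lambda"`, `"delta"`, `"kappa"`,
#'   `"white"`, `"trend"`.
#' @param sigma2 step variance (trait units squared per unit time), >= 0.
#' @param z0 root (ancestral mean) state.
#' @param alpha OU pull strength (1/time), >= 0; `OU` only.
#' @param lambda Pagel's lambda in `[0, 1]`; `lambda` only.
#' @param delta Pagel's delta in `(0, 3]`; `delta` only.
#' @param kappa Pagel's kappa in `[0, 1]`; `kappa` only.
#' @param trend_b linear rate slope (1/time); `trend` only.
#' @return an object of class `evo_model`.
#' @examples
#' evo_model("lambda", sigma2 = 1, lambda = 0.5)
#' @export
evo_model <- function(name, sigma2 = 1, z0 = 0, alpha = NULL, lambda = NULL,
                      delta = NULL, kappa = NULL, trend_b = NULL) {
  name <- match.arg(name, model_names())
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 < 0)
    stopf("sigma2 must be a single value >= 0")
  given <- c(alpha = !is.null(alpha), lambda = !is.null(lambda),
             delta = !is.null(delta), kappa = !is.null(kappa),
             trend_b = !is.null(trend_b))
  need <- shape_par_name(name)
  extra <- names(given)[given & names(given) != need]
  if (length(extra))
    stopf("parameter(s) %s do not belong to the %s model",
          paste(extra, collapse = ", "), name)
  shape <- switch(name,
    BM = , white = NA_real_,
    OU = alpha %||% 0,
    lambda = lambda %||% 1,
    delta = delta %||% 1,
    kappa = kappa %||% 1,
    trend = trend_b %||% 0)
  check_shape(name, shape)
  structure(list(name = name, sigma2 = sigma2, z0 = z0, shape = shape),
            class = "evo_model")
}

model_names <- function() c("BM", "OU", "lambda", "delta", "kappa", "white", "trend")

model_code <- function(name) {
  match(name, c("BM", "lambda", "kappa", "delta", "OU", "white", "trend")) - 1L
}

shape_par_name <- function(name) {
  switch(name, BM = NA_character_, white = NA_character_, OU = "alpha",
         lambda = "lambda", delta = "delta", kappa = "kappa", trend = "trend_b")
}

check_shape <- function(name, shape) {
  ok <- switch(name,
    BM = , white = TRUE,
    OU = is.finite(shape) && shape >= 0,
    lambda = is.finite(shape) && shape >= 0 && shape <= 1,
    delta = is.finite(shape) && shape > 0 && shape <= 3,
    kappa = is.finite(shape) && shape >= 0 && shape <= 1,
    trend = is.finite(shape))
  if (!ok) stopf("parameter %s out of bounds for the %s model",
                 shape_par_name(name), name)
  invisible(TRUE)
}

needs_ultrametric <- function(name) name %in% c("OU", "delta")

#' @export
print.evo_model <- function(x, ...) {
  pn <- shape_par_name(x$name)
  cat(sprintf("<evo_model> %s: sigma2 = %.6g, z0 = %.6g%s\n", x$name,
              x$sigma2, x$z0,
              if (is.na(pn)) "" else sprintf(", %s = %.6g", pn, x$shape)))
  invisible(x)
}

# instantaneous-rate floor shared with the C++ kernel (trend model)
TREND_RATE_FLOOR <- 1e-10

trend_depth_r <- function(d, b) {
  if (b >= 0) return(d + 0.5 * b * d^2)
  t0 <- (1 - TREND_RATE_FLOOR) / (-b)
  ifelse(d <= t0, d + 0.5 * b * d^2,
         t0 + 0.5 * b * t0^2 + TREND_RATE_FLOOR * (d - t0))
}

ou_scale_r <- function(s, alpha, height) {
  if (alpha == 0) return(s)
  exp(-2 * alpha * height) * expm1(2 * alpha * s) / (2 * alpha)
}

#' Model-implied covariance among tips
#'
#' Applies the model's tree transformation and returns the full n x n trait
#' covariance matrix in sorted tip-label order.  `OU` and `delta` require an
#' ultrametric tree (their transforms are defined on relative node depths).
#'
#' @param phy a `phylo` object.
#' @param model an [evo_model].
#' @return a symmetric positive semi-definite matrix.
#' @export
model_covariance <- function(phy, model) {
  stopifnot(inherits(model, "evo_model"))
  phy <- validate_phylogeny(phy)
  if (needs_ultrametric(model$name) && !is_ultrametric(phy))
    stopf("the %s model requires an ultrametric tree", model$name)
  S <- phylo_vcv(phy)
  h <- max(diag(S))
  V <- switch(model$name,
    BM = S,
    white = diag(nrow(S)),
    lambda = {
      M <- model$shape * S
      diag(M) <- diag(S)
      M
    },
    kappa = {
      tk <- phy
      tk$edge.length <- phy$edge.length^model$shape
      if (!is.null(tk$root.edge)) tk$root.edge <- root_stem(phy)^model$shape
      phylo_vcv(tk)
    },
    delta = h^(1 - model$shape) * S^model$shape,
    OU = ou_scale_r(S, model$shape, h),
    trend = trend_depth_r(S, model$shape))
  V <- model$sigma2 * V
  dimnames(V) <- dimnames(S)
  V
}

# Covariance over tips AND internal nodes (used by ancestral reconstruction).
# Shared depths between any two nodes come from s_uv = (d_u + d_v - dist_uv)/2.
model_covariance_full <- function(phy, model) {
  stopifnot(inherits(model, "evo_model"))
  if (model$name == "white")
    stopf("the white-noise model has no ancestral covariance structure")
  if (needs_ultrametric(model$name) && !is_ultrametric(phy))
    stopf("the %s model requires an ultrametric tree", model$name)
  base <- if (model$name == "kappa") {
    tk <- phy
    tk$edge.length <- phy$edge.length^model$shape
    if (!is.null(tk$root.edge)) tk$root.edge <- root_stem(phy)^model$shape
    tk
  } else phy
  d <- node_depths(base)
  D <- ape::dist.nodes(base)
  S <- (outer(d, d, "+") - D) / 2
  S[S < 0] <- 0 # guard tiny negative round-off
  h <- tree_height(phy)
  V <- switch(model$name,
    BM = , kappa = S,
    lambda = {
      M <- model$shape * S
      diag(M) <- d
      M
    },
    delta = h^(1 - model$shape) * S^model$shape,
    OU = {
      a <- model$shape
      if (a == 0) S
      else exp(-a * outer(d, d, "+")) * expm1(2 * a * S) / (2 * a)
    },
    trend = trend_depth_r(S, model$shape))
  model$sigma2 * V
}

#' Simulate a trait under an evolution model
#'
#' Draws one multivariate-normal realisation with mean `z0` and covariance
#' [model_covariance()].
#'
#' @param phy a `phylo` object.
#' @param model an [evo_model].
#' @param seed optional integer seed for reproducibility.
#' @return a named numeric vector in sorted tip-label order.
#' @export
simulate_trait <- function(phy, model, seed = NULL) {
  V <- model_covariance(phy, model)
  n <- nrow(V)
  if (model$sigma2 == 0) {
    out <- rep(model$z0, n)
    names(out) <- rownames(V)
    return(out)
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R))
    R <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), n)),
                  error = function(e)
                    stopf("model covariance is not positive semi-definite"))
  z <- local_seed(seed, stats::rnorm(n))
  out <- model$z0 + drop(crossprod(R, z))
  names(out) <- rownames(V)
  out
}

# Fast path: profiled Gaussian likelihood through the C++ kernel.
# Returns lnL, the analytically profiled root state, and the GLS pieces.
kernel_lnL <- function(pt, name, sigma2, shape, se2, y) {
  k <- .ll_kernel_cpp(pt$parent, pt$child, pt$elen, pt$dpar, pt$dchild,
                      pt$ntip, pt$nnode, pt$height, model_code(name),
                      sigma2, if (is.na(shape)) 0 else shape, se2,
                      cbind(1, y), pt$root_edge)
  S11 <- k$Q[1, 1]; S1y <- k$Q[1, 2]; Syy <- k$Q[2, 2]
  z0 <- S1y / S11
  quad <- Syy - S1y^2 / S11
  list(lnL = -0.5 * (pt$ntip * log(2 * pi) + k$logdet + quad), z0 = z0)
}

# GLS cross-products under a model covariance: X = [1, x], response y.
kernel_gls <- function(pt, name, sigma2, shape, se2, x, y) {
  k <- .ll_kernel_cpp(pt$parent, pt$child, pt$elen, pt$dpar, pt$dchild,
                      pt$ntip, pt$nnode, pt$height, model_code(name),
                      sigma2, if (is.na(shape)) 0 else shape, se2,
                      cbind(1, x, y), pt$root_edge)
  XtVX <- k$Q[1:2, 1:2]
  XtVy <- k$Q[1:2, 3]
  beta <- solve(XtVX, XtVy)
  quad <- k$Q[3, 3] - sum(beta * XtVy)
  list(beta = beta, cov_unscaled = solve(XtVX), quad = quad,
       lnL = -0.5 * (pt$ntip * log(2 * pi) + k$logdet + quad),
       logdet = k$logdet)
}

#' Profiled log-likelihood of a trait under an evolution model
#'
#' Computes the Gaussian log-likelihood of tip values under the model's
#' covariance, with the root state profiled analytically:
#' `z0_hat = (1'V^-1 1)^-1 1'V^-1 x`.  When per-tip sampling standard errors
#' are supplied they are added as `diag(se^2)` to the model covariance.
#' The computation runs in linear time via a postorder structured-covariance
#' algorithm rather than a dense matrix factorisation.
#'
#' @param trait named numeric vector of tip values (or unnamed, in sorted
#'   tip-label order).
#' @param phy a `phylo` object.
#' @param model an [evo_model]; its `z0` entry is ignored (profiled out).
#' @param se optional per-tip sampling standard errors (same order/names).
#' @return a list with elements `lnL` and `z0_hat`.
#' @export
log_likelihood <- function(trait, phy, model, se = NULL) {
  stopifnot(inherits(model, "evo_model"))
  phy <- validate_phylogeny(phy)
  if (needs_ultrametric(model$name) && !is_ultrametric(phy))
    stopf("the %s model requires an ultrametric tree", model$name)
  if (model$sigma2 <= 0) stopf("log-likelihood requires sigma2 > 0")
  y <- align_to_tips(phy, trait)
  if (anyNA(y) || any(!is.finite(y))) stopf("trait contains non-finite values")
  se2 <- if (is.null(se)) rep(0, length(y)) else align_to_tips(phy, se, "se")^2
  pt <- as_ptree(phy)
  out <- tryCatch(
    kernel_lnL(pt, model$name, model$sigma2, model$shape, se2, y),
    error = function(e)
      stopf("likelihood evaluation failed (%s); the covariance may be singular - add sampling SEs or a small jitter, or choose another model",
            conditionMessage(e)))
  list(lnL = out$lnL, z0_hat = out$z0)
}
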