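# Maximum-likelihood fitting of the seven evolution models, AIC comparison,
# the decisive-support rule (delta-AIC >= 10 by default), and clade-wise
# model assignment with taxonomic fallback.

# Fit-time bounds.  sigma2 is optimised on the log scale around a
# data-driven centre; alpha on the log scale; shape bounds follow common
# practice so bound-hitting is visible in the fit output.
shape_bounds <- function(name, height) {
  switch(name,
    lambda = c(0, 1),
    kappa = c(0, 1),
    delta = c(1e-5, 3),
    OU = c(1e-8, 50 / height),
    trend = c(-10 / height, 10 / height),
    c(NA_real_, NA_real_))
}

# Value of the shape parameter at which the model collapses to BM.
bm_nest_shape <- function(name, height) {
  switch(name, lambda = 1, kappa = 1, delta = 1, OU = 1e-8, trend = 0,
         NA_real_)
}

n_params <- function(name) if (name %in% c("BM", "white")) 2L else 3L

#' Fit one evolution model by maximum likelihood
#'
#' Maximises the profiled Gaussian log-likelihood of the trait under the
#' chosen model.  The root state is profiled analytically; `sigma2` (and
#' `alpha` for OU) are optimised on the log scale.  For models with a shape
#' parameter the optimiser is run from `n_starts` Latin-hypercube starting
#' points inside the bounds, plus the Brownian-motion nest point, so the
#' fitted likelihood can never fall below the BM fit for nested models.
#'
#' @param phy a `phylo` object.
#' @param trait named numeric tip values (or unnamed in sorted label order).
#' @param name model name; see [evo_model()].
#' @param se optional per-tip sampling SEs added as `diag(se^2)`.
#' @param n_starts number of multi-start optimisations (shape models only).
#' @param seed optional seed controlling the starting points.
#' @return an object of class `evo_fit`: the fitted [evo_model], `lnL`,
#'   parameter count `k`, `AIC`, convergence flag and per-parameter
#'   bound-hit flags.
#' @export
fit_model <- function(phy, trait, name, se = NULL, n_starts = 5, seed = NULL) {
  name <- match.arg(name, model_names())
  phy <- validate_phylogeny(phy)
  if (needs_ultrametric(name) && !is_ultrametric(phy))
    stopf("the %s model requires an ultrametric tree", name)
  n <- length(phy$tip.label)
  if (n < 3 && n_params(name) == 3L)
    stopf("at least 3 tips are required to fit the %s model", name)
  y <- align_to_tips(phy, trait)
  se2 <- if (is.null(se)) rep(0, n) else align_to_tips(phy, se, "se")^2
  pt <- as_ptree(phy)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- max(abs(y), 1e-8)^2 * 1e-4 + 1e-12
  ls_centre <- log(vy / pt$height)
  ls_lo <- max(log(1e-10), ls_centre - 20)
  ls_hi <- ls_centre + 12

  obj1 <- function(ls) -kernel_lnL(pt, name, exp(ls), NA_real_, se2, y)$lnL

  if (name %in% c("BM", "white")) {
    opt <- stats::optimize(obj1, c(ls_lo, ls_hi), tol = 1e-8)
    sigma2 <- exp(opt$minimum)
    shape <- NA_real_
    lnL <- -opt$objective
    conv <- TRUE
    bound <- c(sigma2 = opt$minimum < ls_lo + 1e-3 || opt$minimum > ls_hi - 1e-3)
  } else {
    bnd <- shape_bounds(name, pt$height)
    # optimise (log sigma2, u) where u is alpha on the log scale for OU
    to_shape <- if (name == "OU") function(u) exp(u) else identity
    ub <- if (name == "OU") log(bnd) else bnd
    obj2 <- function(par) {
      v <- -kernel_lnL(pt, name, exp(par[1]), to_shape(par[2]), se2, y)$lnL
      if (!is.finite(v)) 1e12 else v
    }
    nest_u <- if (name == "OU") log(bm_nest_shape(name, pt$height))
              else bm_nest_shape(name, pt$height)
    starts <- rbind(c(ls_centre, nest_u))
    if (n_starts > 1) {
      H <- local_seed(seed, lhs::randomLHS(n_starts - 1L, 2L))
      # for OU, spread starts over the informative pull range (alpha * height
      # from ~0.05 to the bound): near-zero alpha has a vanishing log-scale
      # gradient and would strand the optimiser on the Brownian ridge
      srange <- if (name == "OU") c(log(0.05 / pt$height), ub[2]) else ub
      starts <- rbind(starts,
                      cbind(ls_centre - 4 + 8 * H[, 1],
                            srange[1] + (srange[2] - srange[1]) *
                              (0.05 + 0.9 * H[, 2])))
    }
    best <- NULL
    any_conv <- FALSE
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[i, ], obj2, method = "L-BFGS-B",
                     lower = c(ls_lo, ub[1]), upper = c(ls_hi, ub[2]),
                     control = list(factr = 1e7, maxit = 200)),
        error = function(e) NULL)
      if (is.null(o)) next
      any_conv <- any_conv || o$convergence == 0
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      return(structure(list(model = NULL, lnL = NA_real_, k = n_params(name),
                            AIC = NA_real_, converged = FALSE,
                            bound_hit = NULL, name = name,
                            diagnostics = "all optimiser starts failed"),
                       class = "evo_fit"))
    # guarantee the nesting inequality against the exact BM nest point
    nest_val <- obj2(c(best$par[1], nest_u))
    if (nest_val < best$value) best <- list(par = c(best$par[1], nest_u),
                                            value = nest_val, convergence = 0)
    sigma2 <- exp(best$par[1])
    shape <- to_shape(best$par[2])
    lnL <- -best$value
    conv <- any_conv
    tol <- 1e-6 * pmax(1, abs(ub))
    bound <- c(sigma2 = best$par[1] < ls_lo + 1e-3 || best$par[1] > ls_hi - 1e-3,
               shape = best$par[2] < ub[1] + tol[1] || best$par[2] > ub[2] - tol[2])
    names(bound)[2] <- shape_par_name(name)
  }

  z0 <- kernel_lnL(pt, name, sigma2, shape, se2, y)$z0
  mod <- do.call(evo_model, c(list(name = name, sigma2 = sigma2, z0 = z0),
                              if (!is.na(shape))
                                stats::setNames(list(shape), shape_par_name(name))))
  structure(list(model = mod, lnL = lnL, k = n_params(name),
                 AIC = 2 * n_params(name) - 2 * lnL, converged = conv,
                 bound_hit = bound, name = name),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(sprintf("<evo_fit> %s: lnL = %.4f, k = %d, AIC = %.4f, converged = %s\n",
              x$name, x$lnL, x$k, x$AIC, x$converged))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' Apply the decisive-support AIC rule
#'
#' The best model is declared only when its AIC undercuts every competitor
#' by at least `threshold` units; otherwise the verdict is `"uncertain"`.
#'
#' @param aic named numeric vector of AIC values.
#' @param threshold decisive-support margin (default 10 AIC units).
#' @return a list with `best` (model name or `"uncertain"`), `ranked`
#'   (AICs sorted increasing) and `delta` (margin over the runner-up).
#' @export
aic_decision <- function(aic, threshold = 10) {
  aic <- aic[is.finite(aic)]
  if (!length(aic)) return(list(best = "uncertain", ranked = aic, delta = NA_real_))
  ranked <- sort(aic)
  delta <- if (length(ranked) > 1) ranked[2] - ranked[1] else Inf
  list(best = if (delta >= threshold) names(ranked)[1] else "uncertain",
       ranked = ranked, delta = unname(delta))
}

#' Fit all seven evolution models and select by AIC
#'
#' Fits each model by maximum likelihood, ranks them by AIC and applies the
#' decisive-support rule of [aic_decision()].  Individual model failures are
#' recorded and skipped; only total failure is an error.
#'
#' @inheritParams fit_model
#' @param delta_aic decisive-support threshold (default 10).
#' @param models subset of models to fit (default: all seven).
#' @return an object of class `model_selection` with elements `fits`
#'   (named list of [fit_model] results), `table` (per-model lnL/k/AIC),
#'   `best` (name or `"uncertain"`) and `delta_aic_threshold`.
#' @export
fit_all_models <- function(phy, trait, se = NULL, n_starts = 5, seed = NULL,
                           delta_aic = 10, models = model_names()) {
  phy <- validate_phylogeny(phy)
  ultra <- is_ultrametric(phy)
  fits <- list()
  for (m in models) {
    fits[[m]] <- tryCatch(
      fit_model(phy, trait, m, se = se, n_starts = n_starts,
                seed = if (is.null(seed)) NULL else derive_seed(seed, model_code(m))),
      error = function(e) structure(
        list(model = NULL, lnL = NA_real_, k = n_params(m), AIC = NA_real_,
             converged = FALSE, bound_hit = NULL, name = m,
             diagnostics = conditionMessage(e)),
        class = "evo_fit"))
  }
  aic <- vapply(fits, function(f) if (isTRUE(f$converged)) f$AIC else NA_real_,
                numeric(1))
  if (all(is.na(aic))) stopf("all model fits failed")
  dec <- aic_decision(aic, delta_aic)
  tab <- data.frame(
    model = names(fits),
    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
    k = vapply(fits, `[[`, integer(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  tab <- tab[order(tab$AIC), ]
  structure(list(fits = fits, table = tab, best = dec$best,
                 delta = dec$delta, delta_aic_threshold = delta_aic,
                 ultrametric = ultra),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best: %s (runner-up margin %.2f, threshold %.1f)\n",
              x$best, x$delta, x$delta_aic_threshold))
  invisible(x)
}

#' Assign evolution models to nested clades with taxonomic fallback
#'
#' Runs [fit_all_models()] on the pruned subtree of each clade.  Clades with
#' an `"uncertain"` verdict (or too few tips for a reliable fit) inherit the
#' assignment of their parent rank, recursively; an unresolved top rank
#' defaults to Brownian motion.
#'
#' @param phy a `phylo` object.
#' @param trait named numeric tip values.
#' @param clades named list; each element is a list with `tips` (character
#'   vector of tip labels) and `parent` (name of the enclosing clade, or
#'   `NA` for a top rank).
#' @param se optional per-tip sampling SEs (named).
#' @param min_tips clades with fewer tips are skipped with a warning and
#'   inherit their parent's assignment (default 10).
#' @inheritParams fit_all_models
#' @return named character vector mapping clade labels to model names, with
#'   the per-clade [fit_all_models] verdicts attached as attribute
#'   `"verdicts"`.
#' @export
assign_clade_models <- function(phy, trait, clades, se = NULL, min_tips = 10,
                                n_starts = 5, seed = NULL, delta_aic = 10,
                                models = model_names()) {
  phy <- validate_phylogeny(phy)
  if (is.null(names(clades)) || anyDuplicated(names(clades)))
    stopf("clades must be a uniquely named list")
  parents <- vapply(clades, function(cl) as.character(cl$parent %||% NA), "")
  unknown <- setdiff(stats::na.omit(parents), names(clades))
  if (length(unknown))
    stopf("unknown parent rank(s): %s", paste(unknown, collapse = ", "))

  # topological order: parents before children
  order <- character(0)
  remaining <- names(clades)
  while (length(remaining)) {
    ready <- remaining[is.na(parents[remaining]) | parents[remaining] %in% order]
    if (!length(ready)) stopf("clade parent relations contain a cycle")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }

  verdicts <- assignment <- stats::setNames(rep(NA_character_, length(clades)),
                                            names(clades))
  for (cl in order) {
    tips <- unique(as.character(clades[[cl]]$tips))
    missing <- setdiff(tips, phy$tip.label)
    if (length(missing))
      stopf("clade %s contains tips absent from the tree: %s", cl,
            paste(missing, collapse = ", "))
    parent_assign <- if (is.na(parents[cl])) "BM" else assignment[parents[cl]]
    if (length(tips) < min_tips) {
      warning(sprintf("clade %s has %d tips (< %d); inheriting '%s'",
                      cl, length(tips), min_tips, parent_assign), call. = FALSE)
      verdicts[cl] <- "skipped"
      assignment[cl] <- parent_assign
      next
    }
    sub <- prune_to_taxa(phy, tips)
    tr <- align_to_tips(phy, trait)
    names(tr) <- phy$tip.label
    sub_se <- if (is.null(se)) NULL else {
      s <- align_to_tips(phy, se, "se"); names(s) <- phy$tip.label
      s[sub$tip.label]
    }
    sel <- fit_all_models(sub, tr[sub$tip.label], se = sub_se,
                          n_starts = n_starts,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, match(cl, order)),
                          delta_aic = delta_aic, models = models)
    verdicts[cl] <- sel$best
    assignment[cl] <- if (sel$best == "uncertain") parent_assign else sel$best
  }
  attr(assignment, "verdicts") <- verdicts
  assignment
}
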