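# Synthetic-data generation and the error-rate simulation benchmark
# comparing phylogenetic regression methods.

#' Configuration for the error-rate simulation benchmark
#'
#' Defaults reproduce the benchmark design: generating conditions
#' {BM, OU, lambda} slope trials plus an i.i.d.-uniform null, species counts
#' {50, 150, 350}, minimum-record thresholds {1, 5, 10, 20}, slopes drawn
#' uniformly on (-2, 2), additive uniform noise on (-0.05, 0.05), and
#' negative-binomial record counts (mean 55, dispersion 0.35: heavy right
#' skew with median near 15, emulating zoological necropsy databases).
#' Traits are simulated with tip standard deviation 0.25 on unit-height
#' trees; the OU pull is `alpha = 2 / height` and the lambda condition uses
#' `lambda = 0.5`.
#'
#' @param n_species_levels species counts per cell.
#' @param min_records_levels minimum necropsy records per species.
#' @param conditions generating conditions; `"null"` is the no-relationship
#'   control, the others name the trait-evolution model of the predictor.
#' @param iterations trials per cell.
#' @param slope_range range of the uniform slope draw (slope trials).
#' @param noise half-width `w` of the uniform noise `U(-w, w)`: pass the
#'   range as `c(-0.05, 0.05)` or the half-width `0.05`.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion (size)
#'   for record counts.
#' @param alpha significance threshold for the error definitions.
#' @param methods regression methods to score.
#' @param n_starts stage-1 multi-start count used by `pgls_sey_optim`
#'   within trials (2 keeps the benchmark tractable; the fitted likelihoods
#'   are profiled over one shape parameter and are well behaved at these
#'   tree sizes).
#' @param tree optional fixed `phylo` to sample species from; by default a
#'   fresh pure-birth tree (height normalised to 1) is simulated per trial.
#' @param ou_alpha_height OU pull times tree height for the OU condition.
#' @param gen_lambda Pagel's lambda for the lambda condition.
#' @param tip_sd target marginal tip standard deviation of simulated traits.
#' @param binomial_events draw event counts binomially from the trial
#'   prevalence instead of deterministic rounding.
#' @param seed base seed; every trial derives its own stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species_levels = c(50, 150, 350),
                       min_records_levels = c(1, 5, 10, 20),
                       conditions = c("BM", "OU", "lambda", "null"),
                       iterations = 1000,
                       slope_range = c(-2, 2),
                       noise = 0.05,
                       nb_mean = 55, nb_dispersion = 0.35,
                       alpha = 0.05,
                       methods = c("gee_binomial", "pgls_sey", "pgls_sey_optim"),
                       n_starts = 2,
                       tree = NULL,
                       ou_alpha_height = 2,
                       gen_lambda = 0.5,
                       tip_sd = 0.25,
                       binomial_events = FALSE,
                       seed = 1) {
  stopifnot(iterations >= 1, all(n_species_levels >= 4),
            all(min_records_levels >= 1), nb_mean > 0, nb_dispersion > 0)
  noise <- if (length(noise) == 2) max(abs(noise)) else abs(noise)
  structure(list(n_species_levels = n_species_levels,
                 min_records_levels = min_records_levels,
                 conditions = conditions, iterations = iterations,
                 slope_range = slope_range, noise = noise,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 alpha = alpha, methods = methods, n_starts = n_starts,
                 tree = tree, ou_alpha_height = ou_alpha_height,
                 gen_lambda = gen_lambda, tip_sd = tip_sd,
                 binomial_events = binomial_events, seed = seed),
            class = "sim_config")
}

#' Simulate necropsy record counts above a minimum threshold
#'
#' Draws i.i.d. negative-binomial counts and rejects draws below
#' `min_records`, mirroring the heavy right skew of necropsies per species
#' in zoological collections.
#'
#' @param n_species number of species.
#' @param min_records minimum accepted count (1, 5, 10 or 20 are the
#'   benchmark levels; other values are allowed with a warning).
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion.
#' @param seed optional seed.
#' @return integer vector of length `n_species`, all `>= min_records`.
#' @export
simulate_records <- function(n_species, min_records, nb_mean = 55,
                             nb_dispersion = 0.35, seed = NULL) {
  stopifnot(n_species >= 1, nb_mean > 0, nb_dispersion > 0)
  if (!min_records %in% c(1, 5, 10, 20))
    warning("min_records outside the benchmark levels {1, 5, 10, 20}",
            call. = FALSE)
  acc <- 1 - stats::pnbinom(min_records - 1, mu = nb_mean, size = nb_dispersion)
  if (acc < 1e-3)
    stopf("acceptance probability %.2g < 1e-3: degenerate threshold for NB(mu = %g, size = %g)",
          acc, nb_mean, nb_dispersion)
  local_seed(seed, {
    out <- integer(0)
    while (length(out) < n_species) {
      draw <- stats::rnbinom(ceiling(1.5 * (n_species - length(out)) / acc) + 8,
                             mu = nb_mean, size = nb_dispersion)
      out <- c(out, draw[draw >= min_records])
    }
    out[seq_len(n_species)]
  })
}

# Generating-model specification used by the slope trials.
generating_model <- function(name, height, tip_sd = 0.25,
                             ou_alpha_height = 2, gen_lambda = 0.5) {
  v <- tip_sd^2
  switch(name,
    BM = evo_model("BM", sigma2 = v / height),
    lambda = evo_model("lambda", sigma2 = v / height, lambda = gen_lambda),
    OU = {
      a <- ou_alpha_height / height
      evo_model("OU", sigma2 = v * 2 * a / (1 - exp(-2 * a * height)), alpha = a)
    },
    stopf("unknown generating condition '%s'", name))
}

#' Simulate one slope trial
#'
#' The predictor is a trait simulated under the generating model on the
#' tree, min-max rescaled to `[0, 1]`.  Prevalence follows a linear
#' slope-intercept response around 0.5 with additive uniform noise, clipped
#' to `[0, 1]`; event counts are the rounded product of prevalence and
#' record count (or a binomial draw when `binomial_events = TRUE`), so the
#' GEE sees the same data as the PGLS methods.
#'
#' @param phy tree for the trial (tips define the species set).
#' @param model generating condition: `"BM"`, `"OU"` or `"lambda"`, or an
#'   [evo_model] directly.
#' @param slope true slope in the benchmark's `(-2, 2)` range.
#' @param counts per-species record counts (from [simulate_records()]).
#' @param seed optional seed.
#' @param noise uniform noise half-width.
#' @param binomial_events see [sim_config()].
#' @param ... passed to the generating-model defaults (`tip_sd`,
#'   `ou_alpha_height`, `gen_lambda`).
#' @return a list with `records` (species table), `x` (named predictor) and
#'   `slope`.
#' @export
simulate_slope_trial <- function(phy, model, slope, counts, seed = NULL,
                                 noise = 0.05, binomial_events = FALSE, ...) {
  n <- length(phy$tip.label)
  stopifnot(length(counts) == n)
  if (!inherits(model, "evo_model"))
    model <- generating_model(model, tree_height(phy), ...)
  trait <- simulate_trait(phy, model,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  rng <- range(trait)
  x <- if (rng[2] > rng[1]) (trait - rng[1]) / (rng[2] - rng[1])
       else rep(0.5, n)
  local_seed(if (is.null(seed)) NULL else derive_seed(seed, 2), {
    y_raw <- 0.5 + slope * (x - 0.5) + stats::runif(n, -noise, noise)
    prev <- pmin(pmax(y_raw, 0), 1)
    n_event <- if (binomial_events) stats::rbinom(n, counts, prev)
               else round(prev * counts)
  })
  species <- names(trait)
  ps <- prevalence_se(n_event, counts)
  rec <- data.frame(species = species, n_records = counts, n_event = n_event,
                    prevalence = ps$prevalence, se = ps$se)
  list(records = rec, x = stats::setNames(unname(x), species), slope = slope)
}

#' Simulate one null trial
#'
#' Predictor and prevalence are independent uniform draws with no
#' phylogenetic structure - the no-relationship control of the benchmark.
#'
#' @param species species labels (length >= 4).
#' @param counts per-species record counts.
#' @param seed optional seed.
#' @param binomial_events see [sim_config()].
#' @return as [simulate_slope_trial()], with `slope = 0`.
#' @export
simulate_null_trial <- function(species, counts, seed = NULL,
                                binomial_events = FALSE) {
  n <- length(species)
  stopifnot(n >= 4, length(counts) == n)
  local_seed(seed, {
    x <- stats::runif(n)
    prev <- stats::runif(n)
    n_event <- if (binomial_events) stats::rbinom(n, counts, prev)
               else round(prev * counts)
  })
  ps <- prevalence_se(n_event, counts)
  rec <- data.frame(species = species, n_records = counts, n_event = n_event,
                    prevalence = ps$prevalence, se = ps$se)
  list(records = rec, x = stats::setNames(x, species), slope = 0)
}

#' Run the regression methods on one trial
#'
#' Prunes the tree to the trial's species and runs each requested method,
#' capturing per-method failures without aborting the trial.
#'
#' @param phy tree containing at least the trial's species.
#' @param trial result of [simulate_slope_trial()] or [simulate_null_trial()].
#' @param methods character vector of method names among `"pgls_sey"`,
#'   `"pgls_sey_pagel"`, `"pgls_sey_optim"`, `"gee_binomial"`.
#' @param n_starts stage-1 multi-start count for `pgls_sey_optim`.
#' @param seed optional seed for `pgls_sey_optim` starting points.
#' @return a data.frame with columns `method`, `p_value`, `failed`.
#' @export
run_trial <- function(phy, trial, methods = c("gee_binomial", "pgls_sey",
                                              "pgls_sey_optim"),
                      n_starts = 2, seed = NULL) {
  phy <- prune_to_taxa(phy, trial$records$species)
  res <- lapply(methods, function(m) {
    fit <- tryCatch(switch(m,
      pgls_sey = pgls_sey(phy, trial$x, trial$records),
      pgls_sey_pagel = pgls_sey_pagel(phy, trial$x, trial$records),
      pgls_sey_optim = pgls_sey_optim(phy, trial$x, trial$records,
                                      n_starts = n_starts, seed = seed),
      gee_binomial = gee_binomial(phy, trial$x, trial$records),
      stopf("unknown method '%s'", m)),
      error = function(e) NULL)
    p <- if (is.null(fit)) NA_real_ else fit$p_value
    data.frame(method = m, p_value = p, failed = is.na(p))
  })
  do.call(rbind, res)
}

#' Run the full error-rate simulation grid
#'
#' For every cell of condition x species count x minimum records, runs
#' `iterations` independent trials (fresh tree or fresh species sample,
#' fresh record counts, fresh slope and traits) and scores, per method,
#' false negatives (`p > alpha` under a true slope) or false positives
#' (`p < alpha` under the null).  Every trial derives its own seed from the
#' configuration seed, so cells are independently reproducible.
#'
#' @param config a [sim_config()].
#' @param progress print a line per completed cell.
#' @return an `error_rate_table` data.frame with one row per
#'   method x cell: `method`, `condition`, `n_species`, `min_records`,
#'   `error_type`, `n_trials`, `n_failed`, `n_errors`, `error_rate`.
#' @export
run_grid <- function(config = sim_config(), progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(condition = config$conditions,
                       n_species = config$n_species_levels,
                       min_records = config$min_records_levels,
                       stringsAsFactors = FALSE)
  fixed_tree <- config$tree
  if (!is.null(fixed_tree)) fixed_tree <- validate_phylogeny(fixed_tree)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cond <- cells$condition[ci]
    nsp <- cells$n_species[ci]
    minr <- cells$min_records[ci]
    errs <- fails <- stats::setNames(numeric(length(config$methods)),
                                     config$methods)
    for (it in seq_len(config$iterations)) {
      s <- derive_seed(config$seed, ci, it)
      tr <- if (is.null(fixed_tree)) {
        rescale_tree_height(simulate_tree(nsp, 1, 0, seed = derive_seed(s, 1)))
      } else {
        keep <- local_seed(derive_seed(s, 1),
                           sample(fixed_tree$tip.label, nsp))
        prune_to_taxa(fixed_tree, keep)
      }
      counts <- simulate_records(nsp, minr, config$nb_mean,
                                 config$nb_dispersion, seed = derive_seed(s, 2))
      trial <- if (cond == "null") {
        simulate_null_trial(tr$tip.label, counts, seed = derive_seed(s, 3),
                            binomial_events = config$binomial_events)
      } else {
        slope <- local_seed(derive_seed(s, 4),
                            stats::runif(1, config$slope_range[1],
                                         config$slope_range[2]))
        simulate_slope_trial(tr, cond, slope, counts, seed = derive_seed(s, 5),
                             noise = config$noise,
                             binomial_events = config$binomial_events,
                             tip_sd = config$tip_sd,
                             ou_alpha_height = config$ou_alpha_height,
                             gen_lambda = config$gen_lambda)
      }
      pr <- run_trial(tr, trial, config$methods, n_starts = config$n_starts,
                      seed = derive_seed(s, 6))
      for (j in seq_len(nrow(pr))) {
        m <- pr$method[j]
        if (pr$failed[j]) { fails[m] <- fails[m] + 1; next }
        err <- if (cond == "null") pr$p_value[j] < config$alpha
               else pr$p_value[j] > config$alpha
        errs[m] <- errs[m] + err
      }
    }
    out[[ci]] <- data.frame(
      method = config$methods, condition = cond, n_species = nsp,
      min_records = minr,
      error_type = if (cond == "null") "false_positive" else "false_negative",
      n_trials = config$iterations, n_failed = unname(fails),
      n_errors = unname(errs),
      error_rate = unname(errs) / pmax(config$iterations - fails, 1),
      row.names = NULL)
    if (progress)
      message(sprintf("[%d/%d] %s n=%d min=%d: %s", ci, nrow(cells), cond,
                      nsp, minr,
                      paste(sprintf("%s=%.3f", config$methods,
                                    out[[ci]]$error_rate), collapse = " ")))
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("error_rate_table", "data.frame")
  tab
}

#' Summarise an error-rate table
#'
#' @param tab an `error_rate_table` from [run_grid()].
#' @return a list with `per_method` (grand-mean error rate per method,
#'   weighted by valid trials), `by_condition` (method x condition means)
#'   and the input `table`.
#' @export
summarize_error_rates <- function(tab) {
  if (!nrow(tab)) stopf("empty error-rate table")
  valid <- tab$n_trials - tab$n_failed
  agg <- function(rows) sum(tab$n_errors[rows]) / max(sum(valid[rows]), 1)
  methods <- unique(tab$method)
  per_method <- data.frame(
    method = methods,
    error_rate = vapply(methods, function(m) agg(tab$method == m), numeric(1)),
    row.names = NULL)
  combos <- unique(tab[c("method", "condition")])
  combos$error_rate <- mapply(function(m, co)
    agg(tab$method == m & tab$condition == co), combos$method, combos$condition)
  rownames(combos) <- NULL
  list(per_method = per_method, by_condition = combos, table = tab)
}
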