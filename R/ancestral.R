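# Maximum-likelihood ancestral state reconstruction with confidence
# intervals under a fitted evolution model.

#' Reconstruct ancestral states under a fitted evolution model
#'
#' Internal-node states are the maximisers of the joint Gaussian likelihood
#' of tips and nodes under the model covariance extended to internal nodes -
#' equivalently, the conditional expectation of node states given the tips.
#' Variances come from the conditional covariance, holding the fitted
#' parameters fixed, and 95% intervals are Wald-type
#' (`estimate +/- 1.96 * sqrt(variance)`).  The root estimate equals the
#' profiled root state of the fitted model and carries zero conditional
#' variance (reconstruction is conditional on the fitted root).
#'
#' For the lambda model, internal nodes keep their original depths while
#' tip covariances are lambda-scaled (the standard transformed-covariance
#' convention); kappa, delta, OU and trend reconstructions use the
#' transformed covariance throughout.
#'
#' @param phy a `phylo` object.
#' @param trait named numeric tip values (or unnamed in sorted label order).
#' @param model a fitted [evo_model]; `"white"` is rejected (no ancestral
#'   structure), as is the string `"uncertain"` (resolve model choice first,
#'   e.g. via [fit_all_models()]).
#' @param se optional per-tip sampling SEs added to the tip covariance.
#' @return an object of class `ancestral_states`: a data.frame with one row
#'   per internal node (`node`, `estimate`, `variance`, `ci95_low`,
#'   `ci95_high`) plus attributes `model` and `z0`.
#' @export
reconstruct_states <- function(phy, trait, model, se = NULL) {
  if (identical(model, "uncertain"))
    stopf("model selection returned 'uncertain'; resolve the model choice before reconstructing (e.g. refit with a decisive threshold or choose BM)")
  stopifnot(inherits(model, "evo_model"))
  if (model$name == "white")
    stopf("the white-noise model has no ancestral structure to reconstruct")
  phy <- validate_phylogeny(phy)
  n <- length(phy$tip.label)
  y <- align_to_tips(phy, trait)
  Vfull <- model_covariance_full(phy, model)
  N <- nrow(Vfull)
  tips <- seq_len(n)
  anc <- (n + 1):N
  Vtt <- Vfull[tips, tips, drop = FALSE]
  if (!is.null(se)) {
    se2 <- align_to_tips(phy, se, "se")^2
    Vtt <- Vtt + diag(se2, n)
  }
  Vat <- Vfull[anc, tips, drop = FALSE]
  Vaa <- Vfull[anc, anc, drop = FALSE]
  # profiled root state under the same covariance (GLS mean)
  R <- chol(Vtt)
  iV1 <- backsolve(R, backsolve(R, rep(1, n), transpose = TRUE))
  iVy <- backsolve(R, backsolve(R, y, transpose = TRUE))
  z0 <- sum(iVy) / sum(iV1)
  W <- Vat %*% backsolve(R, backsolve(R, diag(n), transpose = TRUE))
  est <- drop(z0 + W %*% (y - z0))
  vr <- pmax(diag(Vaa) - rowSums(W * Vat), 0)
  out <- data.frame(node = anc, estimate = est, variance = vr,
                    ci95_low = est - 1.96 * sqrt(vr),
                    ci95_high = est + 1.96 * sqrt(vr))
  structure(out, model = model, z0 = z0, class = c("ancestral_states", "data.frame"))
}

#' Ancestral-state profile through time
#'
#' Tabulates reconstructed internal-node states against node age (time
#' before present: tree height minus node depth), sorted from the root
#' (maximum age) towards the present - the raw material for a
#' prevalence-through-time trace.
#'
#' @param states an [reconstruct_states()] result.
#' @param phy the same `phylo` object the states were reconstructed on.
#' @return a data.frame with columns `node`, `age`, `estimate`, `ci_low`,
#'   `ci_high`, sorted by decreasing age.
#' @export
reconstruction_profile <- function(states, phy) {
  stopifnot(inherits(states, "ancestral_states"))
  d <- node_depths(phy)
  h <- tree_height(phy)
  age <- h - d[states$node]
  out <- data.frame(node = states$node, age = age,
                    estimate = states$estimate,
                    ci_low = states$ci95_low, ci_high = states$ci95_high)
  out[order(-out$age), , drop = FALSE]
}
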