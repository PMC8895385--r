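#' Adapt the model state by retraining on a mixed dataset
#'
#' Emulates orientation adaptation as the paper's neurophysiological
#' protocols do: the model is retrained from scratch on an ensemble in
#' which gratings near the adaptor orientation are over-represented, so
#' the prior of the adaptor's co-shared component grows at the expense of
#' the others.  By default the covariances are re-learned along with the
#' priors (full retrain); `freeze_covariance = TRUE` keeps the baseline
#' covariances and transplants only the retrained priors -- the
#' prior-only ablation used to show that a prior change alone cannot
#' produce attractive tuning shifts.
#'
#' @param baseline the pre-adaptation [mgsm_state()] (used for the frozen
#'   covariances and recorded as provenance).
#' @param mixed_spec a [mixed_dataset_spec()] describing the adaptation
#'   ensemble.
#' @param bank the [build_filterbank()] shared by both states.
#' @param cfg an [em_config()].
#' @param freeze_covariance keep baseline covariances, update priors only.
#' @return the adapted `mgsm_state` (the full `mgsm_fit` is attached as
#'   attribute `"fit"`).
#' @export
adapt_by_prior <- function(baseline, mixed_spec, bank, cfg = em_config(),
                           freeze_covariance = FALSE) {
  stopifnot(inherits(baseline, "mgsm_state"),
            inherits(mixed_spec, "mixed_dataset_spec"))
  patches <- sample_mixed_dataset(mixed_spec)
  fit <- fit_mgsm(patches, bank, cfg,
                  meta = list(dataset = "mixed",
                              adaptor_deg = mixed_spec$adaptor_orientation_deg,
                              grating_fraction = mixed_spec$grating_fraction,
                              data_seed = mixed_spec$seed))
  state <- fit$state
  if (freeze_covariance) {
    state <- mgsm_state(state$priors, baseline$Sigma_C, baseline$Sigma_CN,
                        baseline$Sigma_N, meta = state$meta)
    state$meta$freeze_covariance <- TRUE
  }
  attr(state, "fit") <- fit
  state
}

#' Declarative covariance perturbation
#'
#' Describes a direct modification of the joint centre+surround
#' covariance of one co-shared component -- the "connectivity change"
#' route to adaptation.  Scalings act on the stored (trace-normalised)
#' matrix and no re-normalisation is applied afterwards: the perturbation
#' itself is the signal.
#'
#' @param target_component orientation (0/45/90/135) of the co-shared
#'   component whose covariance is perturbed (the adaptor's component).
#' @param center_variance_scale named numeric vector mapping centre
#'   orientations to positive factors applied to their diagonal entries
#'   (both phases) in the centre block, e.g. `c("0" = 2, "90" = 2,
#'   "135" = 2)`; omitted orientations are left untouched.
#' @param surround_variance_scale positive factor on the surround-block
#'   diagonal.
#' @param surround_covariance_scale positive factor on the surround-block
#'   off-diagonals and the centre--surround cross terms.
#' @return object of class `covariance_perturbation`.
#' @export
covariance_perturbation <- function(target_component,
                                    center_variance_scale = numeric(0),
                                    surround_variance_scale = 1,
                                    surround_covariance_scale = 1) {
  target <- as.character(target_component)
  if (!target %in% component_orientations()) {
    stop("target_component must be one of 0, 45, 90, 135")
  }
  if (length(center_variance_scale)) {
    if (is.null(names(center_variance_scale)) ||
        !all(names(center_variance_scale) %in% component_orientations())) {
      stop("center_variance_scale must be named with orientations")
    }
    if (any(center_variance_scale <= 0)) stop("scale factors must be > 0")
  }
  stopifnot(surround_variance_scale > 0, surround_covariance_scale > 0)
  structure(
    list(target_component = target,
         center_variance_scale = center_variance_scale,
         surround_variance_scale = surround_variance_scale,
         surround_covariance_scale = surround_covariance_scale),
    class = "covariance_perturbation"
  )
}

#' Preset covariance perturbations
#'
#' The four perturbations used to dissect the attraction effect, for an
#' adaptor 45 degrees from the model's preferred orientation (target
#' component defaults to 45):
#' \describe{
#'   \item{center_up}{centre variances of the three non-adapted
#'     orientations scaled by `center_factor` (default 2): enhanced,
#'     non-specific suppression within the CRF.}
#'   \item{surround_down}{surround variances and covariances scaled by
#'     `surround_factor` (default 0.5): weakened surround suppression.}
#'   \item{combined}{both of the above.}
#'   \item{combined_double}{as `combined` with the centre scaling doubled
#'     (default 4): the strongest attraction.}
#' }
#'
#' @param name preset name (see Description).
#' @param target_component orientation of the perturbed co-shared
#'   component (default 45, the flank adaptor).
#' @param center_factor,surround_factor the two magnitudes; defaults 2
#'   and 0.5.
#' @return a [covariance_perturbation()].
#' @export
perturbation_preset <- function(name = c("center_up", "surround_down",
                                         "combined", "combined_double"),
                                target_component = 45,
                                center_factor = 2, surround_factor = 0.5) {
  name <- match.arg(name)
  target <- as.character(target_component)
  others <- setdiff(component_orientations(), target)
  cvs <- stats::setNames(rep(center_factor, 3), others)
  switch(name,
    center_up = covariance_perturbation(target, cvs),
    surround_down = covariance_perturbation(
      target, surround_variance_scale = surround_factor,
      surround_covariance_scale = surround_factor),
    combined = covariance_perturbation(
      target, cvs, surround_factor, surround_factor),
    combined_double = covariance_perturbation(
      target, stats::setNames(rep(2 * center_factor, 3), others),
      surround_factor, surround_factor)
  )
}

#' Apply a covariance perturbation to a state
#'
#' Returns a copy of `state` whose target joint covariance has the
#' declared entries scaled.  If the scaled matrix loses positive
#' definiteness it is projected back by flooring eigenvalues at
#' `1e-8 * max(eigenvalue)` (recorded in the state metadata); for
#' moderate factors the projection is a no-op.
#'
#' @param state an [mgsm_state()].
#' @param pert a [covariance_perturbation()].
#' @return the perturbed `mgsm_state`.
#' @export
adapt_by_covariance <- function(state, pert) {
  stopifnot(inherits(state, "mgsm_state"),
            inherits(pert, "covariance_perturbation"))
  target <- pert$target_component
  comp <- state$Sigma_CN[[target]]
  S <- comp$Sigma
  ci <- 1:8
  si <- 9:24
  for (o in names(pert$center_variance_scale)) {
    ii <- center_channel_index(as.numeric(o), "even") +
      c(0L, 1L)  # even and odd entries of that orientation
    S[cbind(ii, ii)] <- S[cbind(ii, ii)] * pert$center_variance_scale[[o]]
  }
  if (pert$surround_variance_scale != 1) {
    S[cbind(si, si)] <- S[cbind(si, si)] * pert$surround_variance_scale
  }
  if (pert$surround_covariance_scale != 1) {
    sc <- pert$surround_covariance_scale
    off <- matrix(FALSE, 24, 24)
    off[si, si] <- TRUE
    diag(off) <- FALSE
    S[off] <- S[off] * sc
    S[ci, si] <- S[ci, si] * sc
    S[si, ci] <- S[si, ci] * sc
  }
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  projected <- FALSE
  if (min(eg$values) < 1e-8 * max(eg$values)) {
    flo <- 1e-8 * max(eg$values)
    S <- eg$vectors %*% diag(pmax(eg$values, flo)) %*% t(eg$vectors)
    S <- (S + t(S)) / 2
    projected <- TRUE
  }
  # the perturbation is the signal: no trace re-normalisation
  new_comp <- gsm_component(S, scale = comp$scale, normalize = FALSE)
  out <- state
  out$Sigma_CN[[target]] <- new_comp
  out$meta$perturbation <- c(
    list(target = target, spd_projected = projected),
    pert[c("center_variance_scale", "surround_variance_scale",
           "surround_covariance_scale")]
  )
  out
}

#' Compare two model states
#'
#' Per-component prior deltas and covariance-block Frobenius-norm deltas
#' (on the effective covariances `scale * Sigma`); identical states give
#' all-zero deltas.
#'
#' @param before,after [mgsm_state()] objects with matching geometry.
#' @return a tibble with one row per component: `component`,
#'   `prior_before`, `prior_after`, `prior_delta`, `cov_delta`
#'   (Frobenius norm of the difference of the component's covariance:
#'   `Sigma_C` for `nonshared`, `Sigma_CN[theta]` otherwise).
#' @export
compare_states <- function(before, after) {
  stopifnot(inherits(before, "mgsm_state"), inherits(after, "mgsm_state"))
  eff <- function(comp) comp$scale * comp$Sigma
  covs_b <- c(list(eff(before$Sigma_C)), lapply(before$Sigma_CN, eff))
  covs_a <- c(list(eff(after$Sigma_C)), lapply(after$Sigma_CN, eff))
  if (!all(mapply(function(a, b) all(dim(a) == dim(b)), covs_a, covs_b))) {
    stop("states have incompatible covariance dimensions")
  }
  tibble::tibble(
    component = component_names(),
    prior_before = unname(before$priors),
    prior_after = unname(after$priors),
    prior_delta = unname(after$priors - before$priors),
    cov_delta = mapply(function(a, b) sqrt(sum((a - b)^2)),
                       covs_a, covs_b)
  )
}
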