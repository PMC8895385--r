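#' MGSM model state
#'
#' The mixture of Gaussian scale mixtures has five components: one
#' "non-shared" component, in which the centre (CRF) responses are
#' statistically independent of every surround group, and four "co-shared"
#' components, one per model orientation, in which the centre and the
#' surround group at that orientation share a common mixer (a common
#' multiplicative scale) and are therefore dependent.  The state -- the
#' component priors together with the covariance matrices -- entirely
#' determines the model's responses; adaptation acts by changing it.
#'
#' Covariances per component family: `Sigma_C` (8 x 8, centre block),
#' `Sigma_CN[[theta]]` (24 x 24, centre + surround-at-theta) and
#' `Sigma_N[[theta]]` (16 x 16, surround-at-theta alone, used by the
#' components in which that surround group has its own mixer).  All are
#' stored trace-normalised with a separate scalar `scale` (see
#' [gsm_component()]).
#'
#' @param priors named numeric vector of length 5 in order
#'   (`nonshared`, `0`, `45`, `90`, `135`), non-negative, summing to 1.
#' @param Sigma_C,Sigma_CN,Sigma_N covariance matrices as
#'   [gsm_component()] objects (or plain SPD matrices, converted).
#' @param meta free-form list of provenance metadata (seed, dataset spec,
#'   training configuration).
#' @return object of class `mgsm_state`.
#' @export
mgsm_state <- function(priors, Sigma_C, Sigma_CN, Sigma_N, meta = list()) {
  priors <- validate_priors(priors)
  as_comp <- function(x, d) {
    if (!inherits(x, "gsm_component")) x <- gsm_component(x)
    if (x$d != d) stop("covariance has dimension ", x$d, ", expected ", d)
    x
  }
  Sigma_C <- as_comp(Sigma_C, 8)
  orients <- component_orientations()
  stopifnot(length(Sigma_CN) == 4, length(Sigma_N) == 4)
  Sigma_CN <- stats::setNames(lapply(Sigma_CN, as_comp, d = 24), orients)
  Sigma_N <- stats::setNames(lapply(Sigma_N, as_comp, d = 16), orients)
  structure(
    list(priors = priors, Sigma_C = Sigma_C, Sigma_CN = Sigma_CN,
         Sigma_N = Sigma_N, meta = meta),
    class = "mgsm_state"
  )
}

component_names <- function() c("nonshared", "0", "45", "90", "135")
component_orientations <- function() c("0", "45", "90", "135")

validate_priors <- function(priors) {
  if (is.null(names(priors))) names(priors) <- component_names()
  priors <- priors[component_names()]
  if (anyNA(priors) || any(priors < 0)) {
    stop("priors must be non-negative and named ",
         paste(component_names(), collapse = ", "))
  }
  s <- sum(priors)
  if (abs(s - 1) > 1e-10) stop("priors must sum to 1 (got ", s, ")")
  priors
}

#' @export
print.mgsm_state <- function(x, ...) {
  cat("<mgsm_state>\n priors:\n")
  print(round(x$priors, 4))
  cat(sprintf(" scales: C %.3g | CN %s | N %s\n",
              x$Sigma_C$scale,
              paste(sprintf("%.3g", vapply(x$Sigma_CN, `[[`, 0, "scale")),
                    collapse = "/"),
              paste(sprintf("%.3g", vapply(x$Sigma_N, `[[`, 0, "scale")),
                    collapse = "/")))
  if (!is.null(x$meta$trained_on)) {
    cat(" trained on:", x$meta$trained_on, "\n")
  }
  invisible(x)
}

# Per-family log-likelihood pieces for a response matrix R (n x 72).
# Returns list(center = n-vector, surround = list over theta,
#              joint = list over theta).
family_logliks <- function(R, state, bank) {
  cols <- component_columns(bank)
  list(
    center = gsm_loglik(R[, cols$center, drop = FALSE], state$Sigma_C),
    surround = lapply(component_orientations(), function(o) {
      gsm_loglik(R[, cols$surround[[o]], drop = FALSE], state$Sigma_N[[o]])
    }) |> stats::setNames(component_orientations()),
    joint = lapply(component_orientations(), function(o) {
      gsm_loglik(R[, cols$joint[[o]], drop = FALSE], state$Sigma_CN[[o]])
    }) |> stats::setNames(component_orientations())
  )
}

# n x 5 matrix of full-observation component log-likelihoods:
#   nonshared: p(C) * prod_theta p(N_theta)
#   co-shared theta: p(C, N_theta) * prod_{theta' != theta} p(N_theta')
component_logliks <- function(R, state, bank) {
  fl <- family_logliks(R, state, bank)
  surround_sum <- Reduce(`+`, fl$surround)
  ll <- matrix(0, length(fl$center), 5,
               dimnames = list(NULL, component_names()))
  ll[, 1] <- fl$center + surround_sum
  for (o in component_orientations()) {
    ll[, o] <- fl$joint[[o]] + surround_sum - fl$surround[[o]]
  }
  ll
}

#' Posterior probabilities of the five mixture components
#'
#' Bayes combination of the component priors with the component
#' likelihoods of the observed centre and surround responses, computed in
#' the log domain with log-sum-exp normalisation.
#'
#' @param r a `response_vector` from [extract_responses()], or an
#'   `n x 72` response matrix from [response_matrix()].
#' @param state an [mgsm_state()].
#' @param bank the [build_filterbank()] the responses came from.
#' @return for a single response vector, a named probability vector of
#'   length 5 (ordered `nonshared`, `0`, `45`, `90`, `135`); for matrix
#'   input an `n x 5` matrix with rows summing to 1.
#' @export
component_posteriors <- function(r, state, bank) {
  single <- inherits(r, "response_vector")
  R <- if (single) matrix(c(r$c, unlist(r$n, use.names = FALSE)), 1)
       else r
  if (all(state$priors == 0)) stop("all component priors are zero")
  lp <- log(state$priors)
  lj <- sweep(component_logliks(R, state, bank), 2, lp, `+`)
  m <- apply(lj, 1, max)
  w <- exp(lj - m)
  post <- w / rowSums(w)
  if (single) post[1, ] else post
}

#' Normalised component responses of one channel
#'
#' For a centre channel (orientation, phase), returns the five component
#' estimates of its response: the non-shared estimate uses the centre
#' covariance alone, each co-shared estimate uses the joint
#' centre+surround covariance at its orientation.
#'
#' Two estimators are available.  The default, `"quadratic"`, is the
#' model's printed response rule `R_i = x_i * (x' Sigma^-1 x)`: the
#' channel response weighted by the component's Mahalanobis energy, so
#' that raising a channel's variance in the covariance (strengthening
#' the normalisation pool from that orientation) *suppresses* responses
#' driven by it, and weakening surround variance/covariance
#' *facilitates* -- the directions adaptation phenomenology requires.
#' `"posterior_mean"` is the Bayesian coefficient estimate
#' [gsm_posterior_mean_g()] (divisive-normalisation form); it is
#' oracle-validated but responds to covariance changes with the opposite
#' sign, so it is offered for comparison rather than as the default
#' readout.
#'
#' @inheritParams component_posteriors
#' @param channel list with `orientation` (0/45/90/135) and `phase`
#'   (`"even"` or `"odd"`).
#' @param estimator `"quadratic"` (default) or `"posterior_mean"`.
#' @return named numeric vector of length 5 (matrix `n x 5` for matrix
#'   input).
#' @export
normalized_component_responses <- function(r, state, bank,
                                           channel = list(orientation = 90,
                                                          phase = "even"),
                                           estimator = c("quadratic",
                                                         "posterior_mean")) {
  estimator <- match.arg(estimator)
  single <- inherits(r, "response_vector")
  R <- if (single) matrix(c(r$c, unlist(r$n, use.names = FALSE)), 1)
       else r
  i <- center_channel_index(channel$orientation, channel$phase)
  cols <- component_columns(bank)
  est <- function(X, comp) {
    if (estimator == "quadratic") {
      X[, i] * gsm_lambda(X, comp)^2
    } else {
      gsm_posterior_mean_g(X, comp, i = i)
    }
  }
  out <- matrix(0, nrow(R), 5, dimnames = list(NULL, component_names()))
  out[, 1] <- est(R[, cols$center, drop = FALSE], state$Sigma_C)
  for (o in component_orientations()) {
    out[, o] <- est(R[, cols$joint[[o]], drop = FALSE],
                    state$Sigma_CN[[o]])
  }
  if (single) out[1, ] else out
}

#' Mixture (posterior-weighted) model response
#'
#' The model's estimated firing before adaptation: the five normalised
#' component responses weighted by their posterior probabilities.
#'
#' @inheritParams normalized_component_responses
#' @return numeric scalar (or n-vector for matrix input).
#' @export
mixture_response <- function(r, state, bank,
                             channel = list(orientation = 90,
                                            phase = "even"),
                             estimator = c("quadratic",
                                           "posterior_mean")) {
  post <- component_posteriors(r, state, bank)
  comps <- normalized_component_responses(r, state, bank, channel,
                                          estimator)
  if (is.matrix(post)) rowSums(post * comps) else sum(post * comps)
}

#' Winner-take-all model response
#'
#' The prior-based WTA readout used after adaptation: the selection
#' vector over components is one-hot at the maximal posterior, so the
#' response equals the winning component's normalised response.  Ties are
#' broken deterministically towards the lowest component index
#' (non-shared first).
#'
#' @inheritParams normalized_component_responses
#' @return for a single response vector, a scalar with attribute
#'   `"winner"` (the winning component's name); for matrix input a vector
#'   with a `"winner"` attribute of the same length.
#' @export
wta_response <- function(r, state, bank,
                         channel = list(orientation = 90,
                                        phase = "even"),
                         estimator = c("quadratic", "posterior_mean")) {
  post <- component_posteriors(r, state, bank)
  comps <- normalized_component_responses(r, state, bank, channel,
                                          estimator)
  if (!is.matrix(post)) {
    post <- matrix(post, 1, dimnames = list(NULL, names(post)))
    comps <- matrix(comps, 1)
    single <- TRUE
  } else single <- FALSE
  k <- apply(post, 1, which.max)  # which.max breaks ties at lowest index
  val <- comps[cbind(seq_len(nrow(comps)), k)]
  winner <- component_names()[k]
  if (single) {
    structure(val[1], winner = winner[1])
  } else {
    structure(val, winner = winner)
  }
}

#' Simulate response vectors from an MGSM state
#'
#' Draws component labels from the priors, then responses from the
#' corresponding generative factorisation (co-shared: joint centre +
#' surround-at-theta draw with one mixer, other surround groups
#' independent; non-shared: all five groups independent).  Useful for
#' parameter-recovery experiments: the sample comes from exactly the
#' density the EM fit maximises.
#'
#' @param state an [mgsm_state()].
#' @param n number of samples.
#' @param bank a [build_filterbank()] (provides the column layout).
#' @return `n x 72` matrix with attribute `"component"` (the true
#'   component label per row).
#' @export
simulate_mgsm_responses <- function(state, n, bank) {
  cols <- component_columns(bank)
  R <- matrix(0, n, 72)
  k <- sample(component_names(), n, replace = TRUE, prob = state$priors)
  orients <- component_orientations()
  for (comp in component_names()) {
    ii <- which(k == comp)
    if (!length(ii)) next
    if (comp == "nonshared") {
      R[ii, cols$center] <- gsm_sample(length(ii), state$Sigma_C)
      for (o in orients) {
        R[ii, cols$surround[[o]]] <- gsm_sample(length(ii),
                                                state$Sigma_N[[o]])
      }
    } else {
      R[ii, cols$joint[[comp]]] <- gsm_sample(length(ii),
                                              state$Sigma_CN[[comp]])
      for (o in setdiff(orients, comp)) {
        R[ii, cols$surround[[o]]] <- gsm_sample(length(ii),
                                                state$Sigma_N[[o]])
      }
    }
  }
  structure(R, component = k)
}
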