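#' EM training configuration
#'
#' @param n_iter_max maximum number of EM iterations.
#' @param loglik_tol convergence threshold on the relative change of the
#'   data log-likelihood between iterations.
#' @param init_seed integer seed controlling any randomised part of the
#'   fit (initialisation is deterministic, but the seed is recorded and
#'   set for reproducibility of the full pipeline).
#' @param min_prior floor applied to component priors after each M-step,
#'   preventing component death (the WTA readout needs all five
#'   components live); must be `< 0.2`.
#' @param ridge relative ridge added to initial covariances
#'   (`ridge * mean(diag)` on the diagonal).
#' @param cov_ridge optional relative ridge added to every M-step
#'   covariance (`cov_ridge * trace(S)/d` on the diagonal).  Default 0:
#'   a ridge perturbs the exact EM update and can break log-likelihood
#'   monotonicity, so degenerate updates are instead caught by a
#'   conditional eigenvalue guard.  Set it positive only for ensembles
#'   known to span a degenerate response manifold.
#' @param verbose print per-iteration log-likelihood and priors.
#' @return object of class `em_config`.
#' @export
em_config <- function(n_iter_max = 200, loglik_tol = 1e-6, init_seed = 1L,
                      min_prior = 1e-4, ridge = 1e-4, cov_ridge = 0,
                      verbose = FALSE) {
  stopifnot(n_iter_max >= 1, loglik_tol > 0,
            min_prior >= 0, min_prior < 0.2, ridge >= 0, cov_ridge >= 0)
  structure(
    list(n_iter_max = as.integer(n_iter_max), loglik_tol = loglik_tol,
         init_seed = as.integer(init_seed), min_prior = min_prior,
         ridge = ridge, cov_ridge = cov_ridge, verbose = isTRUE(verbose)),
    class = "em_config"
  )
}

#' Fit an MGSM state to an ensemble of patches by EM
#'
#' The E-step computes, per patch, the posterior responsibility of each
#' of the five components.  The M-step sets each prior to the mean
#' responsibility and each covariance to the responsibility- and
#' `E[1/v^2 | x]`-weighted second-moment matrix of its coefficient
#' vector (the exact Gaussian-scale-mixture update), then splits off the
#' trace so stored matrices satisfy `trace(Sigma) = d`.  The data
#' log-likelihood is non-decreasing across iterations.
#'
#' Training operates on response vectors; filtering is done once up
#' front, and a precomputed response matrix can be supplied instead of
#' patches (e.g. simulated responses for parameter recovery).
#'
#' @param patches list of image patches, or `NULL` if `responses` is
#'   given.
#' @param bank a [build_filterbank()].
#' @param cfg an [em_config()].
#' @param responses optional precomputed `n x 72` response matrix.
#' @param init optional `mgsm_state` to start from (default: uniform
#'   priors and per-family sample second moments).
#' @param meta list merged into the fitted state's metadata.
#' @return object of class `mgsm_fit`: list with `state` (the fitted
#'   [mgsm_state()]) and `report` (class `mgsm_fit_report`: per-iteration
#'   log-likelihood and prior trace, iterations used, convergence flag).
#' @export
fit_mgsm <- function(patches = NULL, bank, cfg = em_config(),
                     responses = NULL, init = NULL, meta = list()) {
  stopifnot(inherits(bank, "filter_bank"), inherits(cfg, "em_config"))
  R <- responses %||% response_matrix(patches, bank)
  if (nrow(R) < 100) stop("need at least 100 patches to fit the mixture")
  set.seed(cfg$init_seed)
  cols <- component_columns(bank)
  orients <- component_orientations()

  state <- init %||% init_state(R, cols, cfg)

  trace <- list()
  ll_prev <- -Inf
  ll_last <- -Inf
  converged <- FALSE
  iter_used <- 0L
  for (iter in seq_len(cfg$n_iter_max)) {
    # E-step
    ll <- component_logliks(R, state, bank)
    lj <- sweep(ll, 2, log(state$priors), `+`)
    m <- apply(lj, 1, max)
    w <- exp(lj - m)
    rs <- rowSums(w)
    loglik <- sum(m + log(rs))
    ll_last <- loglik
    q <- w / rs

    trace[[iter]] <- c(iter = iter, loglik = loglik, state$priors)
    iter_used <- iter
    if (cfg$verbose) {
      cat(sprintf("iter %3d loglik %.4f priors %s\n", iter, loglik,
                  paste(sprintf("%.3f", state$priors), collapse = " ")))
    }
    if (is.finite(ll_prev) &&
        abs(loglik - ll_prev) <= cfg$loglik_tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- loglik

    # M-step
    priors <- colMeans(q)
    priors <- pmax(priors, cfg$min_prior)
    priors <- priors / sum(priors)

    Sigma_C <- m_step_cov(R[, cols$center, drop = FALSE], q[, 1],
                          state$Sigma_C, cfg$cov_ridge)
    Sigma_CN <- lapply(orients, function(o) {
      m_step_cov(R[, cols$joint[[o]], drop = FALSE], q[, o],
                 state$Sigma_CN[[o]], cfg$cov_ridge)
    }) |> stats::setNames(orients)
    Sigma_N <- lapply(orients, function(o) {
      m_step_cov(R[, cols$surround[[o]], drop = FALSE], 1 - q[, o],
                 state$Sigma_N[[o]], cfg$cov_ridge)
    }) |> stats::setNames(orients)

    state <- mgsm_state(priors, Sigma_C, Sigma_CN, Sigma_N,
                        meta = state$meta)
  }

  trace <- dplyr::bind_rows(lapply(trace, function(x) {
    tibble::as_tibble(as.list(x))
  }))
  names(trace) <- c("iter", "loglik", paste0("prior_", component_names()))
  report <- structure(
    list(trace = trace, n_iter_used = iter_used, converged = converged,
         final_priors = state$priors, loglik = ll_last),
    class = "mgsm_fit_report"
  )
  state$meta <- utils::modifyList(
    state$meta,
    c(list(trained_on = if (is.null(patches)) "responses" else "patches",
           n_obs = nrow(R), seed = cfg$init_seed,
           n_iter = iter_used, converged = converged), meta)
  )
  structure(list(state = state, report = report), class = "mgsm_fit")
}

# GSM-exact covariance update: responsibility- and E[1/v^2]-weighted
# second moment plus a relative ridge, split into trace-normalised shape
# and scalar scale.
m_step_cov <- function(X, q, comp, cov_ridge = 0) {
  ev2 <- gsm_expected_inv_v2(X, comp)
  w <- q * ev2
  S <- crossprod(X * sqrt(w)) / sum(q)
  d <- ncol(X)
  if (cov_ridge > 0) S <- S + diag(cov_ridge * sum(diag(S)) / d, d)
  # conditional guard: regularise only a (near-)rank-deficient update
  eg <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(eg) < 1e-10 * max(eg)) {
    S <- S + diag(1e-8 * max(eg) + 1e-12, d)
    warning("rank-deficient covariance update regularised", call. = FALSE)
  }
  gsm_component(S)
}

# Orientation-aligned initialisation: each patch is hard-assigned to its
# dominant centre orientation and each co-shared covariance starts from
# its own cluster's second moment.  This anchors the component labels to
# their orientations (the orientation-aligned optimum of the likelihood),
# so that e.g. gratings at 90 degrees and 90-degree-dominated patches
# enter the same component from the first iteration.
init_state <- function(R, cols, cfg) {
  second_moment <- function(X) {
    S <- crossprod(X) / nrow(X)
    S + diag(cfg$ridge * mean(diag(S)) + 1e-12, ncol(X))
  }
  orients <- component_orientations()
  Xc <- R[, cols$center, drop = FALSE]
  energy <- sapply(seq_along(orients), function(i) {
    rowSums(Xc[, c(2 * i - 1, 2 * i), drop = FALSE]^2)
  })
  dominant <- orients[max.col(energy, ties.method = "first")]
  mgsm_state(
    priors = stats::setNames(rep(0.2, 5), component_names()),
    Sigma_C = second_moment(Xc),
    Sigma_CN = lapply(orients, function(o) {
      X <- R[, cols$joint[[o]], drop = FALSE]
      ii <- which(dominant == o)
      # fall back to the full ensemble for empty/small clusters
      if (length(ii) >= ncol(X)) X <- X[ii, , drop = FALSE]
      second_moment(X)
    }),
    Sigma_N = lapply(orients, function(o) {
      second_moment(R[, cols$surround[[o]], drop = FALSE])
    }),
    meta = list(init = "orientation-aligned-second-moment")
  )
}

#' Total data log-likelihood of an ensemble under a state
#'
#' Sum over patches of the log mixture density
#' `log sum_k prior_k p(C, N | xi_k)`.
#'
#' @inheritParams fit_mgsm
#' @param state an [mgsm_state()].
#' @return scalar log-likelihood.
#' @export
loglik_dataset <- function(patches = NULL, bank, state, responses = NULL) {
  R <- responses %||% response_matrix(patches, bank)
  lj <- sweep(component_logliks(R, state, bank), 2, log(state$priors), `+`)
  m <- apply(lj, 1, max)
  sum(m + log(rowSums(exp(lj - m))))
}

#' Train the baseline ("natural") state on surrogate textures
#'
#' Convenience pipeline: sample a texture ensemble, filter it, and fit
#' the mixture.  This is the model's normal state, against which
#' adaptation is measured.
#'
#' @param bank a [build_filterbank()].
#' @param n_patches ensemble size (default 25000; desk-scale studies use
#'   a few thousand).
#' @param texture a [texture_params()].
#' @param cfg an [em_config()].
#' @param seed integer seed for the patch sample.
#' @return an `mgsm_fit`.
#' @export
train_baseline <- function(bank, n_patches = 25000,
                           texture = texture_params(), cfg = em_config(),
                           seed = 1L) {
  patches <- sample_texture_dataset(n_patches, texture, seed = seed)
  fit_mgsm(patches, bank, cfg,
           meta = list(dataset = "texture", n_patches = n_patches,
                       data_seed = seed))
}

#' @export
print.mgsm_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<mgsm_fit> %d iterations, %s, loglik %.4f\n",
              r$n_iter_used,
              if (r$converged) "converged" else "not converged",
              r$loglik))
  print(x$state)
  invisible(x)
}

#' @export
print.mgsm_fit_report <- function(x, ...) {
  cat(sprintf("<mgsm_fit_report> %d iterations, converged: %s\n",
              x$n_iter_used, x$converged))
  print(utils::tail(x$trace, 3))
  invisible(x)
}
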