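#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MGSM state
#'
#' @param x an [mgsm_state()].
#' @param ... unused.
#' @return a tibble with one row per mixture component: `component`,
#'   `prior`, `covariance_dim`, `covariance_scale`.
#' @exportS3Method generics::tidy
tidy.mgsm_state <- function(x, ...) {
  comps <- c(list(x$Sigma_C), unname(x$Sigma_CN))
  tibble::tibble(
    component = component_names(),
    prior = unname(x$priors),
    covariance_dim = vapply(comps, `[[`, 0L, "d"),
    covariance_scale = vapply(comps, `[[`, 0, "scale")
  )
}

#' @rdname tidy.mgsm_state
#' @exportS3Method generics::glance
glance.mgsm_state <- function(x, ...) {
  tibble::tibble(
    prior_nonshared = x$priors[["nonshared"]],
    max_coshared = component_orientations()[
      which.max(x$priors[component_orientations()])],
    n_obs = x$meta$n_obs %||% NA_integer_,
    converged = x$meta$converged %||% NA
  )
}

#' Tidy an EM fit
#'
#' @param x an `mgsm_fit` from [fit_mgsm()].
#' @param ... unused.
#' @return the per-iteration trace as a long tibble: `iter`, `loglik`,
#'   and one `prior_*` column per component.
#' @exportS3Method generics::tidy
tidy.mgsm_fit <- function(x, ...) x$report$trace

#' @rdname tidy.mgsm_fit
#' @exportS3Method generics::glance
glance.mgsm_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$report$loglik,
    n_iter = x$report$n_iter_used,
    converged = x$report$converged
  )
}

#' Tidy an OTC result
#'
#' @param x an `otc_result` from [measure_otc()].
#' @param ... unused.
#' @return long tibble with columns `orientation_deg`, `epoch`
#'   (`before` / `after`) and `response`.
#' @exportS3Method generics::tidy
tidy.otc_result <- function(x, ...) {
  tibble::as_tibble(x)[c("orientation_deg", "before", "after")] |>
    tidyr::pivot_longer(c("before", "after"), names_to = "epoch",
                        values_to = "response")
}
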