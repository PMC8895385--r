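bank <- default_bank()

# a deterministic, moderately structured state for unit tests
unit_state <- function(priors = NULL) {
  set.seed(77)
  pr <- priors %||% stats::setNames(rep(0.2, 5),
                                    c("nonshared", "0", "45", "90", "135"))
  mgsm_state(pr,
             Sigma_C = random_spd(8),
             Sigma_CN = lapply(1:4, function(i) random_spd(24)),
             Sigma_N = lapply(1:4, function(i) random_spd(16)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_response <- function() {
  extract_responses(matrix(stats::rnorm(33^2), 33), bank)
}

test_that("posteriors are a proper probability vector on random inputs", {
  st <- unit_state()
  set.seed(123)
  for (k in 1:10) {
    p <- component_posteriors(random_response(), st, bank)
    expect_length(p, 5)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("a degenerate prior forces a one-hot posterior", {
  eps <- 1e-300
  pr <- stats::setNames(c(eps, eps, eps, 1 - 3 * eps - eps, eps),
                        c("nonshared", "0", "45", "90", "135"))
  st <- unit_state(pr / sum(pr))
  set.seed(9)
  p <- component_posteriors(random_response(), st, bank)
  expect_equal(unname(p[["90"]]), 1, tolerance = 1e-10)
  st0 <- unit_state()
  st0$priors[] <- 0
  expect_error(component_posteriors(random_response(), st0, bank), "zero")
})

test_that("posteriors match a direct prior-times-likelihood normalisation", {
  st <- unit_state(stats::setNames(c(0.1, 0.15, 0.2, 0.25, 0.3),
                                   c("nonshared", "0", "45", "90", "135")))
  set.seed(15)
  r <- random_response()
  v <- assemble_component_vectors(r)
  # independent composition: per-family quadrature-oracle likelihoods
  oll <- function(x, comp) gsm_moment_quadrature("marginal_loglik", x, comp)
  ll_n <- vapply(c("0", "45", "90", "135"), function(o) {
    oll(r$n[[o]], st$Sigma_N[[o]])
  }, 0)
  ll <- c(oll(v$x_star, st$Sigma_C) + sum(ll_n),
          vapply(c("0", "45", "90", "135"), function(o) {
            oll(v$x[[o]], st$Sigma_CN[[o]]) + sum(ll_n) - ll_n[[o]]
          }, 0))
  direct <- exp(log(st$priors) + ll - max(log(st$priors) + ll))
  direct <- direct / sum(direct)
  expect_equal(unname(component_posteriors(r, st, bank)), unname(direct),
               tolerance = 1e-6)
})

test_that("component responses vanish for a blank stimulus", {
  st <- unit_state()
  r0 <- extract_responses(matrix(0, 33, 33), bank)
  for (est in c("quadratic", "posterior_mean")) {
    resp <- normalized_component_responses(r0, st, bank, estimator = est)
    expect_equal(unname(resp), rep(0, 5))
  }
})

test_that("co-shared responses stay finite when the surround is silent", {
  st <- unit_state()
  g <- make_grating(grating_spec(90, 0.8, aperture = 9))
  r <- extract_responses(g, bank)
  resp <- normalized_component_responses(r, st, bank)
  expect_true(all(is.finite(resp)))
})

test_that("component responses compose gsm_core with the component vectors", {
  st <- unit_state()
  set.seed(19)
  r <- random_response()
  v <- assemble_component_vectors(r)
  ch <- list(orientation = 90, phase = "even")
  i <- 5  # 90-degree even channel in the centre ordering
  pm <- normalized_component_responses(r, st, bank, ch, "posterior_mean")
  expect_equal(unname(pm[["nonshared"]]),
               gsm_moment_quadrature("mean_g", v$x_star, st$Sigma_C, i = i),
               tolerance = 1e-6)
  expect_equal(unname(pm[["45"]]),
               gsm_moment_quadrature("mean_g", v$x[["45"]],
                                     st$Sigma_CN[["45"]], i = i),
               tolerance = 1e-6)
  qd <- normalized_component_responses(r, st, bank, ch, "quadratic")
  lam2 <- drop(v$x_star %*% solve(st$Sigma_C$scale * st$Sigma_C$Sigma,
                                  v$x_star))
  expect_equal(unname(qd[["nonshared"]]), r$c[i] * lam2, tolerance = 1e-8)
})

test_that("the mixture response is a convex combination of components", {
  st <- unit_state()
  set.seed(33)
  for (k in 1:5) {
    r <- random_response()
    comps <- normalized_component_responses(r, st, bank)
    m <- mixture_response(r, st, bank)
    expect_gte(m, min(comps) - 1e-12)
    expect_lte(m, max(comps) + 1e-12)
    post <- component_posteriors(r, st, bank)
    expect_equal(m, sum(post * comps), tolerance = 1e-12)
  }
})

test_that("a one-hot posterior makes mixture and WTA readouts coincide", {
  eps <- 1e-300
  pr <- stats::setNames(c(eps, 1 - 4 * eps, eps, eps, eps),
                        c("nonshared", "0", "45", "90", "135"))
  st <- unit_state(pr / sum(pr))
  set.seed(41)
  r <- random_response()
  w <- wta_response(r, st, bank)
  expect_equal(as.numeric(w), mixture_response(r, st, bank),
               tolerance = 1e-8)
  expect_identical(attr(w, "winner"), "0")
})

test_that("the WTA readout returns the maximal-posterior component", {
  st <- unit_state()
  set.seed(55)
  r <- random_response()
  post <- component_posteriors(r, st, bank)
  comps <- normalized_component_responses(r, st, bank)
  w <- wta_response(r, st, bank)
  expect_equal(as.numeric(w), unname(comps[which.max(post)]))
  expect_identical(attr(w, "winner"), names(post)[which.max(post)])
})

test_that("readouts stay finite from zero up to extreme stimulus energy", {
  st <- unit_state()
  set.seed(60)
  base <- matrix(stats::rnorm(33^2), 33)
  for (s in c(0, 1e-8, 1, 1e6)) {
    r <- extract_responses(s * base, bank)
    expect_true(is.finite(mixture_response(r, st, bank)))
    expect_true(is.finite(as.numeric(wta_response(r, st, bank))))
    expect_true(all(is.finite(component_posteriors(r, st, bank))))
  }
})

test_that("simulated responses follow the requested component labels", {
  st <- unit_state(stats::setNames(c(0.5, 0.5, 0, 0, 0) + 1e-12,
                                   c("nonshared", "0", "45", "90", "135")) /
                     (1 + 5e-12))
  set.seed(71)
  R <- simulate_mgsm_responses(st, 600, bank)
  k <- attr(R, "component")
  expect_equal(sort(unique(k)), c("0", "nonshared"))
  expect_equal(mean(k == "nonshared"), 0.5, tolerance = 0.1)
  expect_equal(dim(R), c(600, 72))
})

test_that("tidiers expose priors and traces as tibbles", {
  st <- unit_state()
  td <- tidy(st)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$component, c("nonshared", "0", "45", "90", "135"))
  expect_equal(sum(td$prior), 1, tolerance = 1e-10)
  expect_equal(td$covariance_dim, c(8L, 24L, 24L, 24L, 24L))
})
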