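bank <- default_bank()

test_that("EM recovers a known two-component state", {
  set.seed(1)
  truth <- recovery_truth()
  R <- simulate_mgsm_responses(truth, 5000, bank)
  fit <- fit_mgsm(responses = R, bank = bank,
                  cfg = em_config(n_iter_max = 300, loglik_tol = 1e-8))
  pr <- fit$state$priors
  expect_lt(abs(pr[["nonshared"]] - 0.3), 0.05)
  expect_lt(abs(pr[["0"]] - 0.7), 0.05)
  expect_gt(cor(as.numeric(fit$state$Sigma_CN[["0"]]$Sigma),
                as.numeric(truth$Sigma_CN[["0"]]$Sigma)), 0.95)
  expect_gt(cor(as.numeric(fit$state$Sigma_C$Sigma),
                as.numeric(truth$Sigma_C$Sigma)), 0.95)
  # monotone log-likelihood on this fixture
  expect_gte(min(diff(fit$report$trace$loglik)), -1e-8)
  # store the fit for downstream tests in this file
  assign("recovery_fit", list(R = R, fit = fit), envir = .fixtures)
})

test_that("a single forced component recovers its covariance", {
  set.seed(2)
  truth <- recovery_truth()
  truth$priors <- stats::setNames(c(1 - 4e-12, rep(1e-12, 4)),
                                  names(truth$priors))
  R <- simulate_mgsm_responses(truth, 5000, bank)
  fit <- fit_mgsm(responses = R, bank = bank,
                  cfg = em_config(n_iter_max = 150))
  expect_gt(cor(as.numeric(fit$state$Sigma_C$Sigma),
                as.numeric(truth$Sigma_C$Sigma)), 0.98)
})

test_that("EM is deterministic given data and seed", {
  rec <- get("recovery_fit", envir = .fixtures)
  refit <- fit_mgsm(responses = rec$R[1:1000, ], bank = bank,
                    cfg = em_config(n_iter_max = 25))
  refit2 <- fit_mgsm(responses = rec$R[1:1000, ], bank = bank,
                     cfg = em_config(n_iter_max = 25))
  expect_identical(refit$state$priors, refit2$state$priors)
  expect_identical(refit$state$Sigma_CN[["90"]]$Sigma,
                   refit2$state$Sigma_CN[["90"]]$Sigma)
})

test_that("restarting EM from a converged state barely moves it", {
  rec <- get("recovery_fit", envir = .fixtures)
  again <- fit_mgsm(responses = rec$R, bank = bank,
                    cfg = em_config(n_iter_max = 3),
                    init = rec$fit$state)
  expect_lt(max(abs(again$state$priors - rec$fit$state$priors)), 1e-3)
})

test_that("dataset log-likelihood is additive and order-invariant", {
  rec <- get("recovery_fit", envir = .fixtures)
  st <- rec$fit$state
  R10 <- rec$R[1:10, ]
  ll10 <- loglik_dataset(bank = bank, state = st, responses = R10)
  # additivity: duplicating a patch adds exactly its own contribution
  ll1 <- loglik_dataset(bank = bank, state = st,
                        responses = R10[1, , drop = FALSE])
  expect_equal(loglik_dataset(bank = bank, state = st,
                              responses = rbind(R10, R10[1, ])),
               ll10 + ll1, tolerance = 1e-8)
  # order invariance
  expect_equal(loglik_dataset(bank = bank, state = st,
                              responses = R10[10:1, ]),
               ll10, tolerance = 1e-8)
  # matches a direct per-patch mixture-density summation
  direct <- sum(vapply(1:10, function(t) {
    r <- v1adapt:::response_vector_from_row(R10[t, ], bank)
    post_unnorm <- log(st$priors) +
      v1adapt:::component_logliks(R10[t, , drop = FALSE], st, bank)[1, ]
    m <- max(post_unnorm)
    m + log(sum(exp(post_unnorm - m)))
  }, 0))
  expect_equal(ll10, direct, tolerance = 1e-8)
})

test_that("the fit refuses too-small ensembles and reports its trace", {
  expect_error(fit_mgsm(responses = matrix(stats::rnorm(50 * 72), 50),
                        bank = bank),
               "at least 100")
  rec <- get("recovery_fit", envir = .fixtures)
  tr <- tidy(rec$fit)
  expect_s3_class(tr, "tbl_df")
  expect_named(tr, c("iter", "loglik", "prior_nonshared", "prior_0",
                     "prior_45", "prior_90", "prior_135"))
  g <- glance(rec$fit)
  expect_true(g$converged %in% c(TRUE, FALSE))
  expect_equal(g$n_iter, rec$fit$report$n_iter_used)
})
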