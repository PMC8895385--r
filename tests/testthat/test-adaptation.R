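bank <- default_bank()

test_that("the identity perturbation leaves the state bit-identical", {
  st <- small_baseline()$state
  pert <- covariance_perturbation(45)
  out <- adapt_by_covariance(st, pert)
  expect_identical(out$Sigma_CN[["45"]]$Sigma, st$Sigma_CN[["45"]]$Sigma)
  expect_identical(out$Sigma_CN[["45"]]$scale, st$Sigma_CN[["45"]]$scale)
  expect_identical(out$priors, st$priors)
})

test_that("the centre-variance preset touches exactly six diagonal entries", {
  st <- small_baseline()$state
  pert <- perturbation_preset("center_up", target_component = 45,
                              center_factor = 2)
  out <- adapt_by_covariance(st, pert)
  A <- st$Sigma_CN[["45"]]$Sigma
  B <- out$Sigma_CN[["45"]]$Sigma
  changed <- which(abs(A - B) > 1e-12, arr.ind = TRUE)
  # only diagonal entries change
  expect_true(all(changed[, 1] == changed[, 2]))
  # the six centre entries of orientations 0, 90, 135 (both phases)
  expect_setequal(unique(changed[, 1]), c(1, 2, 5, 6, 7, 8))
  expect_equal(B[cbind(c(1, 2, 5, 6, 7, 8), c(1, 2, 5, 6, 7, 8))],
               2 * A[cbind(c(1, 2, 5, 6, 7, 8), c(1, 2, 5, 6, 7, 8))])
  # untouched blocks are bit-identical
  expect_identical(out$Sigma_CN[["90"]]$Sigma, st$Sigma_CN[["90"]]$Sigma)
  expect_identical(out$Sigma_C$Sigma, st$Sigma_C$Sigma)
})

test_that("the doubled preset applies twice the centre scaling of the combined one", {
  st <- small_baseline()$state
  a <- adapt_by_covariance(st, perturbation_preset("combined"))
  b <- adapt_by_covariance(st, perturbation_preset("combined_double"))
  ii <- cbind(c(1, 2, 5, 6, 7, 8), c(1, 2, 5, 6, 7, 8))
  expect_equal(b$Sigma_CN[["45"]]$Sigma[ii],
               2 * a$Sigma_CN[["45"]]$Sigma[ii])
  # surround scalings agree between the two presets
  expect_equal(a$Sigma_CN[["45"]]$Sigma[9:24, 9:24],
               b$Sigma_CN[["45"]]$Sigma[9:24, 9:24])
})

test_that("the surround preset scales the declared blocks and stays SPD", {
  st <- small_baseline()$state
  out <- adapt_by_covariance(st, perturbation_preset("surround_down"))
  A <- st$Sigma_CN[["45"]]$Sigma
  B <- out$Sigma_CN[["45"]]$Sigma
  expect_equal(B[1:8, 9:24], 0.5 * A[1:8, 9:24])
  expect_equal(B[9:24, 9:24], 0.5 * A[9:24, 9:24])
  expect_equal(B[1:8, 1:8], A[1:8, 1:8])
  expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_false(isTRUE(out$meta$perturbation$spd_projected))
})

test_that("moderate factors never trigger the SPD projection", {
  st <- small_baseline()$state
  for (nm in c("center_up", "surround_down", "combined",
               "combined_double")) {
    out <- adapt_by_covariance(st, perturbation_preset(nm))
    expect_false(isTRUE(out$meta$perturbation$spd_projected))
  }
  hard <- covariance_perturbation(
    45, c("0" = 4, "90" = 4, "135" = 4),
    surround_variance_scale = 0.25, surround_covariance_scale = 0.25)
  out <- adapt_by_covariance(st, hard)
  expect_gt(min(eigen(out$Sigma_CN[["45"]]$Sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("perturbation validation rejects bad arguments", {
  expect_error(covariance_perturbation(30), "target_component")
  expect_error(covariance_perturbation(45, c("0" = -1)), "> 0")
  expect_error(covariance_perturbation(45, c(2, 2)), "named")
})

test_that("state comparison reports exactly what changed", {
  st <- small_baseline()$state
  expect_true(all(compare_states(st, st)$prior_delta == 0))
  expect_true(all(compare_states(st, st)$cov_delta == 0))
  out <- adapt_by_covariance(st, perturbation_preset("combined"))
  d <- compare_states(st, out)
  expect_true(all(d$prior_delta == 0))
  expect_equal(d$component[d$cov_delta > 0], "45")
})

test_that("prior adaptation is reproducible and boosts the adaptor prior", {
  base <- small_baseline()$state
  spec <- mixed_dataset_spec(n_patches = 1200,
                             adaptor_orientation_deg = 90, seed = 12)
  cfg <- em_config(n_iter_max = 80)
  a <- adapt_by_prior(base, spec, bank, cfg)
  b <- adapt_by_prior(base, spec, bank, cfg)
  expect_identical(a$priors, b$priors)
  expect_identical(a$Sigma_CN[["90"]]$Sigma, b$Sigma_CN[["90"]]$Sigma)
  expect_gt(a$priors[["90"]], base$priors[["90"]])
  # the frozen variant keeps baseline covariances but adopts new priors
  fz <- adapt_by_prior(base, spec, bank, cfg, freeze_covariance = TRUE)
  expect_identical(fz$Sigma_CN[["90"]]$Sigma, base$Sigma_CN[["90"]]$Sigma)
  expect_identical(fz$Sigma_C$Sigma, base$Sigma_C$Sigma)
  expect_identical(fz$priors, a$priors)
})
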