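# Shared fixtures, built lazily and memoised for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_bank <- function() fixture("bank", function() build_filterbank())

# a random SPD matrix with unit-scale eigenvalues
random_spd <- function(d) {
  A <- matrix(stats::rnorm(2 * d * d), 2 * d, d)
  crossprod(A) / (2 * d) + diag(d) * 0.1
}

# ground-truth two-component state used for parameter recovery: the
# co-shared component carries a one-factor centre--surround comodulation
# so the two components are well separated
recovery_truth <- function() {
  u <- c(rep(1, 8), rep(0.8, 16))
  eps <- 1e-12
  pr <- c(0.3, 0.7, 0, 0, 0) + eps
  mgsm_state(
    priors = stats::setNames(pr / sum(pr),
                             c("nonshared", "0", "45", "90", "135")),
    Sigma_C = diag(c(1.5, 1.5, 1, 1, 0.7, 0.7, 1.2, 1.2)),
    Sigma_CN = lapply(1:4, function(i) diag(24) + 1.2 * tcrossprod(u)),
    Sigma_N = lapply(1:4, function(i) diag(16))
  )
}

# a small texture-trained state for OTC tests (cheap but realistic)
small_baseline <- function() {
  fixture("small_baseline", function() {
    train_baseline(default_bank(), n_patches = 1200,
                   cfg = em_config(n_iter_max = 60), seed = 2)
  })
}

# centre-channel energies (one per orientation) of a response vector
center_energies <- function(r) {
  vapply(1:4, function(i) sum(r$c[(2 * i - 1):(2 * i)]^2), 0)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) /
              max(abs(expected), .Machine$double.eps), tol)
}
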