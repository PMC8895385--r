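#' Gaussian scale mixture component
#'
#' A GSM component models a d-dimensional filter-response vector as
#' `x = v * g` with `g ~ N(0, Sigma)` and a positive mixer
#' `v ~ Rayleigh(1)`.  The multiplicative mixer produces the heavy tails
#' and multiplicative dependencies characteristic of oriented-filter
#' responses to natural images.  The overall scale of the covariance is
#' kept separate from its shape: `Sigma` is stored trace-normalised
#' (`trace(Sigma) = d`) and a scalar `scale` multiplies it, so the
#' effective covariance is `scale * Sigma`.
#'
#' @param Sigma symmetric positive-definite d x d covariance matrix.
#' @param scale positive scalar multiplier; effective covariance is
#'   `scale * Sigma`.
#' @param normalize if `TRUE` (default) the matrix is trace-normalised to
#'   `trace(Sigma) = d` and the removed factor is folded into `scale`.
#' @return an object of class `gsm_component` with fields `Sigma`,
#'   `scale`, `d` and a cached Cholesky factor.
#' @export
gsm_component <- function(Sigma, scale = 1, normalize = TRUE) {
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  if (ncol(Sigma) != d) stop("Sigma must be square")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("Sigma must be symmetric")
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a positive scalar")
  }
  if (normalize) {
    tr <- sum(diag(Sigma))
    if (tr <= 0) stop("Sigma has non-positive trace")
    scale <- scale * tr / d
    Sigma <- Sigma * (d / tr)
  }
  L <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma is not positive definite: ", conditionMessage(e))
  })
  structure(
    list(Sigma = Sigma, scale = scale, d = d, chol = L),
    class = "gsm_component"
  )
}

#' @export
print.gsm_component <- function(x, ...) {
  cat(sprintf("<gsm_component> d = %d, scale = %.6g, trace(Sigma) = %.6g\n",
              x$d, x$scale, sum(diag(x$Sigma))))
  invisible(x)
}

# Mahalanobis norms lambda = sqrt(x' (scale*Sigma)^-1 x) for rows of X.
gsm_lambda <- function(X, comp) {
  X <- as_row_matrix(X, comp$d)
  Z <- backsolve(comp$chol, t(X), transpose = TRUE)
  sqrt(pmax(colSums(Z^2) / comp$scale, 0))
}

as_row_matrix <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("input has ", ncol(x), " columns, expected ", d)
    x
  } else {
    if (length(x) != d) stop("input has length ", length(x), ", expected ", d)
    matrix(x, nrow = 1)
  }
}

# log K_nu(x), elementwise in x, with a small-argument series fallback for
# the region where besselK overflows.
log_besselK <- function(nu, x) {
  nu <- abs(nu)
  out <- numeric(length(x))
  b <- besselK(x, nu, expon.scaled = TRUE)
  ok <- is.finite(b) & b > 0
  out[ok] <- log(b[ok]) - x[ok]
  if (any(!ok)) {
    xs <- x[!ok]
    if (nu > 0) {
      # K_nu(x) ~ Gamma(nu)/2 * (2/x)^nu as x -> 0
      out[!ok] <- log(0.5) + lgamma(nu) + nu * (log(2) - log(xs))
    } else {
      # K_0(x) ~ -log(x/2) - Euler gamma
      out[!ok] <- log(-log(xs / 2) - 0.5772156649015329)
    }
  }
  out
}

# Ratio K_a(x) / K_b(x), elementwise; exploits exponential scaling so the
# e^-x factors cancel exactly.
besselK_ratio <- function(a, b, x) {
  a <- abs(a); b <- abs(b)
  num <- besselK(x, a, expon.scaled = TRUE)
  den <- besselK(x, b, expon.scaled = TRUE)
  r <- num / den
  bad <- !is.finite(r) | den == 0
  if (any(bad)) {
    r[bad] <- exp(log_besselK(a, x[bad]) - log_besselK(b, x[bad]))
  }
  r
}

# numerical floor on lambda: densities/moments are evaluated at
# max(lambda, lambda_floor) to avoid the singularity at 0 (the marginal
# diverges there for d >= 2); small enough to keep relative errors below
# 1e-9 where the density is finite, large enough that scaled Bessel
# values stay representable for every block dimension used
.lambda_floor <- 1e-12

#' GSM marginal log-likelihood
#'
#' Log of the marginal density of `x` under the Rayleigh-mixer GSM,
#' `p(x) = integral Rayleigh(v; 1) N(x; 0, v^2 scale Sigma) dv`.
#' The integral has the closed form
#' `(2 pi)^(-d/2) |scale Sigma|^(-1/2) lambda^(1 - d/2) K_(d/2 - 1)(lambda)`
#' with `lambda` the Mahalanobis norm of `x`; it is evaluated through
#' exponentially scaled Bessel functions so it is finite over the whole
#' usable range of `x`.
#'
#' @param x a d-vector, or a matrix with one observation per row.
#' @param comp a [gsm_component()].
#' @return a numeric vector of log-densities, one per observation.
#' @export
gsm_loglik <- function(x, comp) {
  stopifnot(inherits(comp, "gsm_component"))
  d <- comp$d
  lam <- pmax(gsm_lambda(x, comp), .lambda_floor)
  logdet <- 2 * sum(log(diag(comp$chol))) + d * log(comp$scale)
  -0.5 * d * log(2 * pi) - 0.5 * logdet +
    (1 - d / 2) * log(lam) + log_besselK(d / 2 - 1, lam)
}

# Posterior moments E[v^p | x] for the Rayleigh-mixer GSM reduce to Bessel
# ratios: E[v^p | x] = lambda^(p/2) K_((2-d+p)/2)(lambda) / K_((2-d)/2)(lambda).
gsm_mixer_moment <- function(lam, d, p) {
  lam <- pmax(lam, .lambda_floor)
  lam^(p / 2) * besselK_ratio((2 - d + p) / 2, (2 - d) / 2, lam)
}

#' Posterior mean of the Gaussian coefficient
#'
#' `E[g_i | x]` under the GSM.  Because `g = x / v` given the mixer, the
#' posterior mean factorises as `x_i * E[1/v | x]`: each coefficient is the
#' observed response divided by a pooled (Mahalanobis) activity term.  This
#' is the divisive-normalisation form of the model response.
#'
#' @inheritParams gsm_loglik
#' @param i optional index (or indices) of the coefficient; default all d.
#' @return for vector `x`, a numeric vector `E[g_i|x]`; for matrix input, a
#'   matrix with one row per observation.
#' @export
gsm_posterior_mean_g <- function(x, comp, i = NULL) {
  stopifnot(inherits(comp, "gsm_component"))
  X <- as_row_matrix(x, comp$d)
  if (is.null(i)) i <- seq_len(comp$d)
  lam <- gsm_lambda(X, comp)
  fac <- gsm_mixer_moment(lam, comp$d, -1)
  fac[lam == 0] <- 0  # x = 0: posterior over g is symmetric around 0
  out <- X[, i, drop = FALSE] * fac
  if (!is.matrix(x)) out <- drop(out)
  out
}

#' Posterior expectation of the inverse squared mixer
#'
#' `E[v^-2 | x]`, the weight with which an observation enters the
#' covariance update of the EM M-step.
#'
#' @inheritParams gsm_loglik
#' @return numeric vector, one value per observation.
#' @export
gsm_expected_inv_v2 <- function(x, comp) {
  stopifnot(inherits(comp, "gsm_component"))
  lam <- gsm_lambda(x, comp)
  gsm_mixer_moment(lam, comp$d, -2)
}

#' Quadrature oracle for GSM moments
#'
#' Evaluates the defining one-dimensional integrals over the mixer by
#' adaptive quadrature, independently of the Bessel-function closed forms
#' used by [gsm_loglik()], [gsm_posterior_mean_g()] and
#' [gsm_expected_inv_v2()].  Intended for verification and tests.
#'
#' @param what one of `"marginal_loglik"`, `"mean_g"`, `"inv_v2"`,
#'   `"posterior_norm"` (integral of the posterior weight over the mixer,
#'   which must be 1).
#' @param x a single d-vector.
#' @param comp a [gsm_component()].
#' @param i coefficient index for `what = "mean_g"`.
#' @param rel_tol requested relative accuracy of the quadrature.
#' @return a single numeric value.
#' @export
gsm_moment_quadrature <- function(what = c("marginal_loglik", "mean_g",
                                           "inv_v2", "posterior_norm"),
                                  x, comp, i = 1, rel_tol = 1e-10) {
  what <- match.arg(what)
  stopifnot(inherits(comp, "gsm_component"))
  d <- comp$d
  x <- as.numeric(x)
  lam <- gsm_lambda(x, comp)
  # unnormalised log posterior weight over the mixer v
  lf <- function(v) (1 - d) * log(v) - v^2 / 2 - lam^2 / (2 * v^2)
  # mode of lf: v^4 + (d-1) v^2 - lam^2 = 0
  vstar2 <- (-(d - 1) + sqrt((d - 1)^2 + 4 * lam^2)) / 2
  vstar <- if (vstar2 > 0) sqrt(vstar2) else 1
  M <- lf(vstar)
  if (!is.finite(M)) M <- 0
  quad <- function(g) {
    f <- function(v) {
      val <- g(v) * exp(lf(v) - M)
      val[!is.finite(val)] <- 0
      val
    }
    stats::integrate(f, 0, Inf, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L, stop.on.error = TRUE)$value
  }
  Z <- quad(function(v) 1)
  if (Z <= 0 || !is.finite(Z)) stop("quadrature failed to converge")
  switch(what,
    marginal_loglik = {
      logdet <- 2 * sum(log(diag(comp$chol))) + d * log(comp$scale)
      -0.5 * d * log(2 * pi) - 0.5 * logdet + M + log(Z)
    },
    mean_g = {
      if (all(x == 0)) return(0)
      x[i] * quad(function(v) 1 / v) / Z
    },
    inv_v2 = quad(function(v) 1 / v^2) / Z,
    posterior_norm = {
      # integral of the posterior weight normalised by the closed-form
      # marginal normaliser; equals 1 when the two paths agree
      lamf <- pmax(lam, .lambda_floor)
      logZ_closed <- (1 - d / 2) * log(lamf) + log_besselK(d / 2 - 1, lamf)
      exp(M + log(Z) - logZ_closed)
    }
  )
}

# Draw n samples from a GSM component (v ~ Rayleigh(1), g ~ N(0, scale*Sigma)).
gsm_sample <- function(n, comp) {
  v <- sqrt(-2 * log(stats::runif(n)))
  G <- matrix(stats::rnorm(n * comp$d), n, comp$d) %*% comp$chol *
    sqrt(comp$scale)
  G * v
}
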