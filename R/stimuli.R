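#' Sinusoidal grating specification
#'
#' @param orientation_deg stripe orientation in degrees, taken modulo 180;
#'   0 = horizontal stripes, increasing counter-clockwise.
#' @param contrast dimensionless amplitude in `[0, 1]`; 0 gives a constant
#'   mid-grey (all-zero) patch.
#' @param phase_rad spatial phase in radians, taken modulo 2 pi.
#' @param spatial_freq cycles per pixel, > 0.
#' @param aperture `"full"` or a positive diameter in pixels; a circular
#'   aperture must fit strictly inside the patch.
#' @param patch_size odd positive integer, patch side in pixels.
#' @return an object of class `grating_spec`.
#' @export
grating_spec <- function(orientation_deg, contrast = 1, phase_rad = 0,
                         spatial_freq = 0.25, aperture = "full",
                         patch_size = 33) {
  stopifnot(is.numeric(orientation_deg), length(orientation_deg) == 1,
            is.numeric(contrast), contrast >= 0, contrast <= 1,
            is.numeric(spatial_freq), spatial_freq > 0,
            patch_size >= 3)
  if (!identical(aperture, "full")) {
    if (!is.numeric(aperture) || aperture <= 0) {
      stop("aperture must be \"full\" or a positive diameter in pixels")
    }
    if (aperture >= patch_size) {
      stop("aperture (", aperture, " px) must fit strictly inside the ",
           patch_size, " px patch")
    }
  }
  structure(
    list(orientation_deg = orientation_deg %% 180, contrast = contrast,
         phase_rad = phase_rad %% (2 * pi), spatial_freq = spatial_freq,
         aperture = aperture, patch_size = as.integer(patch_size)),
    class = "grating_spec"
  )
}

#' Render a sinusoidal grating patch
#'
#' Deterministic function of its specification.  Luminance is in contrast
#' units around mid-grey, i.e. zero outside the aperture and
#' `contrast * cos(2 pi f n + phase)` inside, where `n` is the coordinate
#' along the normal to the stripes.
#'
#' @param spec a [grating_spec()] (or arguments forwarded to it).
#' @param ... used to build a `grating_spec` when `spec` is an orientation.
#' @return an `image_patch`: a square numeric matrix with a `provenance`
#'   attribute `"grating"`.
#' @export
make_grating <- function(spec, ...) {
  if (!inherits(spec, "grating_spec")) spec <- grating_spec(spec, ...)
  n <- spec$patch_size
  cx <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - cx, each = n), n)   # col offset
  y <- matrix(rep(rev(seq_len(n)) - cx, times = n), n)  # y axis up
  th <- spec$orientation_deg * pi / 180
  coord <- -x * sin(th) + y * cos(th)
  g <- spec$contrast * cos(2 * pi * spec$spatial_freq * coord +
                             spec$phase_rad)
  if (!identical(spec$aperture, "full")) {
    g[x^2 + y^2 > (spec$aperture / 2)^2] <- 0
  }
  image_patch(g, "grating")
}

image_patch <- function(m, provenance) {
  structure(m, provenance = provenance, class = c("image_patch", "matrix",
                                                  "array"))
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> %dx%d, provenance: %s, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "provenance") %||% "?",
              min(x), max(x)))
  invisible(x)
}

#' Natural-surrogate texture parameters
#'
#' The surrogate emulates the statistics of natural image patches that
#' the model's training depends on: a falling (1/f-like) power spectrum;
#' ensemble-level orientation isotropy with *locally oriented* structure
#' (each patch has a random dominant stripe orientation, uniform over
#' orientation, the way natural patches are dominated by local edges and
#' contours); heavy-tailed filter-response marginals and a shared
#' centre--surround scaling within homogeneous patches (a patch-wide
#' Rayleigh mixer); and a fraction of *heterogeneous* patches whose
#' centre and surround come from independent fields with independent
#' mixers, emulating patches straddling an object boundary.
#'
#' @param size odd patch side in pixels.
#' @param spectral_slope exponent of the amplitude spectrum (1 = natural
#'   1/f amplitude).
#' @param patch_anisotropy in `[0, 1)`: orientation bandwidth of a single
#'   patch; each patch's spectrum is modulated by
#'   `1 + patch_anisotropy * cos(2 (psi - psi_patch))` with its own
#'   `psi_patch ~ Uniform[0, 180)`, so the ensemble stays isotropic.
#' @param heterogeneity probability that a patch is centre/surround
#'   heterogeneous (independent fields and mixers inside vs outside
#'   `boundary_radius`).
#' @param boundary_radius radius in pixels of the centre region used for
#'   heterogeneous patches.
#' @param anisotropy in `[0, 1)`: ensemble-level anisotropy; positive
#'   values boost energy of stripes near `anisotropy_axis_deg` in every
#'   patch.  Default 0 (isotropic ensemble).
#' @param anisotropy_axis_deg favoured stripe orientation, degrees.
#' @param base_rms root-mean-square luminance of the Gaussian field before
#'   the mixer is applied (contrast units, matched to the grating
#'   contrast range).
#' @return an object of class `texture_params` with precomputed spectral
#'   grids.
#' @export
texture_params <- function(size = 33, spectral_slope = 1,
                           patch_anisotropy = 0.85, heterogeneity = 0.25,
                           boundary_radius = 7, anisotropy = 0,
                           anisotropy_axis_deg = 0, base_rms = 0.3) {
  stopifnot(size %% 2 == 1, spectral_slope >= 0,
            patch_anisotropy >= 0, patch_anisotropy < 1,
            heterogeneity >= 0, heterogeneity <= 1, boundary_radius > 0,
            anisotropy >= 0, anisotropy < 1, base_rms > 0)
  k <- c(0:((size - 1) / 2), -((size - 1) / 2):-1) / size
  fx <- matrix(rep(k, each = size), size)
  fy <- matrix(rep(k, times = size), size)
  f <- sqrt(fx^2 + fy^2)
  # stripe orientation carried by a wave vector is its angle + 90 degrees
  psi <- atan2(fy, fx) + pi / 2
  gain0 <- 1 + anisotropy * cos(2 * (psi - anisotropy_axis_deg * pi / 180))
  radial <- ifelse(f > 0, f^(-spectral_slope), 0) * gain0
  # smooth radial blend for heterogeneous patches (2 px transition)
  cx <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - cx, each = size), size)
  y <- matrix(rep(seq_len(size) - cx, times = size), size)
  blend <- 1 / (1 + exp((sqrt(x^2 + y^2) - boundary_radius) / 1))
  structure(
    list(size = size, spectral_slope = spectral_slope,
         patch_anisotropy = patch_anisotropy,
         heterogeneity = heterogeneity,
         boundary_radius = boundary_radius,
         anisotropy = anisotropy,
         anisotropy_axis_deg = anisotropy_axis_deg,
         base_rms = base_rms, radial = radial, psi = psi, blend = blend),
    class = "texture_params"
  )
}

# isotropic 1/f Gaussian noise at a fixed RMS (no mixer): the broadband
# floor of any physically displayed stimulus
noise_field <- function(params, rms) {
  n <- params$size
  z <- matrix(stats::rnorm(n * n), n)
  g <- Re(stats::fft(stats::fft(z) * params$radial, inverse = TRUE)) /
    (n * n)
  g <- g - mean(g)
  r <- sqrt(mean(g^2))
  if (r > 0) g <- g * (rms / r)
  g
}

# one oriented, mixer-scaled Gaussian field
texture_field <- function(params) {
  n <- params$size
  mask <- params$radial
  if (params$patch_anisotropy > 0) {
    psi0 <- stats::runif(1, 0, pi)
    mask <- mask * (1 + params$patch_anisotropy *
                      cos(2 * (params$psi - psi0)))
  }
  z <- matrix(stats::rnorm(n * n), n)
  g <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / (n * n)
  g <- g - mean(g)
  rms <- sqrt(mean(g^2))
  if (rms > 0) g <- g * (params$base_rms / rms)
  v <- sqrt(-2 * log(stats::runif(1)))  # patch-wide Rayleigh mixer
  g * v
}

#' Generate one natural-surrogate texture patch
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility (the same seed gives a bit-identical patch).
#'
#' @param params a [texture_params()] object.
#' @return an `image_patch` with provenance `"texture"`.
#' @export
make_texture_patch <- function(params = texture_params()) {
  stopifnot(inherits(params, "texture_params"))
  g <- texture_field(params)
  if (params$heterogeneity > 0 &&
      stats::runif(1) < params$heterogeneity) {
    g2 <- texture_field(params)  # independent field + mixer for surround
    g <- params$blend * g + (1 - params$blend) * g2
  }
  image_patch(g - mean(g), "texture")
}

#' Mixed adaptation dataset specification
#'
#' Describes the ensemble used to emulate adaptation: a mixture of
#' natural-surrogate textures and full-field sinusoidal gratings whose
#' orientations cluster around the adaptor.  Grating orientation is drawn
#' from a Gaussian with mean `adaptor_orientation_deg` and standard
#' deviation `orientation_spread_deg`, wrapped into `[0, 180)`; contrast
#' is uniform on `[contrast_min, contrast_max]` and phase uniform on
#' `[0, 2 pi)`.
#'
#' @param n_patches number of patches (default 26000, the adaptation
#'   ensemble size used throughout).
#' @param grating_fraction probability that a patch is a grating rather
#'   than a texture, in `[0, 1]` (default 0.3).
#' @param adaptor_orientation_deg adaptor stripe orientation, degrees.
#' @param orientation_spread_deg Gaussian standard deviation of grating
#'   orientations around the adaptor, degrees (default 5).
#' @param contrast_min,contrast_max grating contrast range.
#' @param spatial_freq grating spatial frequency, cycles per pixel; keep
#'   at the filter bank's peak frequency.
#' @param grating_noise_rms RMS of the broadband (1/f) luminance noise
#'   added to each grating patch.  A displayed and sensed grating is
#'   never a mathematically pure sinusoid; without a noise floor the
#'   grating ensemble spans a measure-zero response manifold, EM drives
#'   the adapted component's covariance singular, and that component
#'   expels its own natural patches.  Default 0.1 (a third of the
#'   texture RMS), the smallest round level at which the adapted
#'   component keeps holding both gratings and matching-orientation
#'   textures.
#' @param texture texture parameters for the natural-surrogate patches.
#' @param seed optional integer seed making the sample reproducible.
#' @return an object of class `mixed_dataset_spec`.
#' @export
mixed_dataset_spec <- function(n_patches = 26000, grating_fraction = 0.3,
                               adaptor_orientation_deg = 90,
                               orientation_spread_deg = 5,
                               contrast_min = 0.2, contrast_max = 1,
                               spatial_freq = 0.25,
                               grating_noise_rms = 0.1,
                               texture = texture_params(), seed = NULL) {
  stopifnot(n_patches > 0, grating_fraction >= 0, grating_fraction <= 1,
            orientation_spread_deg >= 0,
            contrast_min >= 0, contrast_max <= 1,
            contrast_min <= contrast_max, grating_noise_rms >= 0)
  structure(
    list(n_patches = as.integer(n_patches),
         grating_fraction = grating_fraction,
         adaptor_orientation_deg = adaptor_orientation_deg %% 180,
         orientation_spread_deg = orientation_spread_deg,
         contrast_min = contrast_min, contrast_max = contrast_max,
         spatial_freq = spatial_freq,
         grating_noise_rms = grating_noise_rms,
         texture = texture, seed = seed),
    class = "mixed_dataset_spec"
  )
}

# the per-patch random draws of a mixed dataset (type, orientation,
# contrast, phase); orientation is wrapped Gaussian around the adaptor
mixed_draws <- function(spec) {
  n <- spec$n_patches
  is_grating <- stats::runif(n) < spec$grating_fraction
  ori <- (stats::rnorm(n, spec$adaptor_orientation_deg,
                       spec$orientation_spread_deg)) %% 180
  con <- stats::runif(n, spec$contrast_min, spec$contrast_max)
  ph <- stats::runif(n, 0, 2 * pi)
  tibble::tibble(
    index = seq_len(n), type = ifelse(is_grating, "grating", "texture"),
    orientation_deg = ifelse(is_grating, ori, NA_real_),
    contrast = ifelse(is_grating, con, NA_real_),
    phase_rad = ifelse(is_grating, ph, NA_real_)
  )
}

#' Sample a mixed adaptation dataset
#'
#' @param spec a [mixed_dataset_spec()].
#' @return a list of `n_patches` `image_patch` objects in random order,
#'   with a `manifest` attribute (a tibble of the per-patch draws) for
#'   exact regeneration.
#' @export
sample_mixed_dataset <- function(spec) {
  stopifnot(inherits(spec, "mixed_dataset_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  draws <- mixed_draws(spec)
  n <- spec$n_patches
  is_grating <- draws$type == "grating"
  size <- spec$texture$size
  ori <- draws$orientation_deg
  con <- draws$contrast
  ph <- draws$phase_rad
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    patches[[i]] <- if (is_grating[i]) {
      g <- make_grating(grating_spec(ori[i], con[i], ph[i],
                                     spec$spatial_freq, "full", size))
      if (spec$grating_noise_rms > 0) {
        g <- image_patch(g + noise_field(spec$texture,
                                         spec$grating_noise_rms),
                         "grating")
      }
      g
    } else {
      make_texture_patch(spec$texture)
    }
  }
  attr(patches, "manifest") <- draws
  patches
}

#' Sample a pure texture ensemble
#'
#' Convenience wrapper: the baseline ("natural state") training ensemble.
#'
#' @param n_patches number of patches (default 25000, the baseline
#'   ensemble size).
#' @param texture a [texture_params()] object.
#' @param seed optional integer seed.
#' @return list of `image_patch` objects.
#' @export
sample_texture_dataset <- function(n_patches = 25000,
                                   texture = texture_params(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_patches), function(i) make_texture_patch(texture))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
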