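#' Build a V1-like oriented quadrature filter bank
#'
#' Constructs Gabor-like quadrature pairs (even = cosine phase, odd = sine
#' phase) at the four model orientations 0, 45, 90, 135 degrees, one
#' central position (the classical receptive field, CRF) and eight
#' surround positions equally spaced on a ring (the extra-classical
#' surround, nCRF).  Kernels are zero-mean and unit L2 norm; even/odd
#' members of a pair are exactly orthogonal by the reflection symmetry of
#' the sampling grid at these four orientations.
#'
#' Orientation convention: 0 degrees means horizontal grating stripes and
#' angles increase counter-clockwise.  This convention is shared by
#' [make_grating()] so a filter at orientation theta responds maximally to
#' a grating of orientation theta.
#'
#' @param patch_size odd integer, side of the square patches the bank is
#'   applied to (pixels).
#' @param kernel_size odd integer, side of the square kernel support.
#' @param spatial_freq peak spatial frequency in cycles per pixel.
#' @param sigma standard deviation of the isotropic Gaussian envelope
#'   (pixels).
#' @param ring_radius centre-to-centre distance between the CRF and each
#'   surround position (pixels); default one kernel support, so surround
#'   kernels abut but do not overlap the centre kernel.
#' @return an object of class `filter_bank`: the stacked filter matrix
#'   `W` (72 x patch_size^2, one embedded kernel per row), a `layout`
#'   tibble describing every row, the raw kernels, and index helpers for
#'   the centre block and the per-orientation surround blocks.
#' @export
build_filterbank <- function(patch_size = 33, kernel_size = 9,
                             spatial_freq = 0.25, sigma = 2.2,
                             ring_radius = kernel_size) {
  if (patch_size %% 2 != 1 || kernel_size %% 2 != 1) {
    stop("patch_size and kernel_size must be odd")
  }
  if (kernel_size > patch_size) stop("kernel support exceeds patch size")
  h <- (kernel_size - 1) / 2
  cx <- (patch_size + 1) / 2
  if (ring_radius + h > cx - 1) {
    stop("geometry overflow: surround kernels would leave the patch ",
         "(ring_radius + kernel half-support must be < patch half-size)")
  }
  orientations <- c(0, 45, 90, 135)
  kernels <- list()
  for (ori in orientations) {
    for (ph in c("even", "odd")) {
      kernels[[paste0(ori, "_", ph)]] <-
        gabor_kernel(kernel_size, ori, spatial_freq, sigma, ph)
    }
  }
  # surround positions: 8 points on the ring, 45 degree steps, rounded to
  # the pixel grid
  ang <- seq(0, 315, by = 45) * pi / 180
  sx <- round(ring_radius * cos(ang))
  sy <- round(ring_radius * sin(ang))

  npix <- patch_size^2
  rows <- list()
  layout <- list()
  add_unit <- function(unit, pos, ori, ph, dx, dy) {
    k <- kernels[[paste0(ori, "_", ph)]]
    # y axis points up: row = cy - y, col = cx + x
    emb <- matrix(0, patch_size, patch_size)
    rr <- (cx - dy) + (-h:h)   # kernel rows (y decreasing down)
    cc <- (cx + dx) + (-h:h)
    emb[rr, cc] <- k
    rows[[length(rows) + 1]] <<- as.numeric(emb)
    layout[[length(layout) + 1]] <<- tibble::tibble(
      unit = unit, position = pos, orientation = ori, phase = ph,
      dx = dx, dy = dy
    )
  }
  for (ori in orientations) for (ph in c("even", "odd")) {
    add_unit("center", 0L, ori, ph, 0, 0)
  }
  for (ori in orientations) for (p in 1:8) for (ph in c("even", "odd")) {
    add_unit("surround", p, ori, ph, sx[p], sy[p])
  }
  W <- do.call(rbind, rows)
  layout <- dplyr::bind_rows(layout)
  layout$index <- seq_len(nrow(layout))

  idx_center <- 1:8
  idx_surround <- lapply(stats::setNames(orientations, orientations),
                         function(o) {
                           layout$index[layout$unit == "surround" &
                                          layout$orientation == o]
                         })
  # CRF aperture: centre kernel footprint plus a 1 px margin.  It covers
  # the classical receptive field while driving the surround kernels only
  # marginally (< 5% of the centre energy at this geometry), but keeps
  # their responses finite -- the GSM marginal diverges at an
  # exactly-zero response block.
  crf_aperture <- kernel_size + 2
  structure(
    list(W = W, layout = layout, kernels = kernels,
         patch_size = patch_size, kernel_size = kernel_size,
         spatial_freq = spatial_freq, sigma = sigma,
         ring_radius = ring_radius, crf_aperture = crf_aperture,
         orientations = orientations,
         idx_center = idx_center, idx_surround = idx_surround),
    class = "filter_bank"
  )
}

# Gabor kernel on a kernel_size grid; orientation is the stripe direction
# (deg CCW from horizontal), modulation runs along the normal.
gabor_kernel <- function(kernel_size, orientation_deg, spatial_freq, sigma,
                         phase = c("even", "odd")) {
  phase <- match.arg(phase)
  h <- (kernel_size - 1) / 2
  x <- matrix(rep(-h:h, each = kernel_size), kernel_size)   # col offset
  y <- matrix(rep(h:-h, times = kernel_size), kernel_size)  # row offset, y up
  th <- orientation_deg * pi / 180
  n <- -x * sin(th) + y * cos(th)  # coordinate along the modulation axis
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  carrier <- if (phase == "even") cos(2 * pi * spatial_freq * n) else
    sin(2 * pi * spatial_freq * n)
  k <- env * carrier
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(paste0("<filter_bank> patch %dx%d, kernel %dx%d, ",
                     "f0 = %.3g cyc/px, ring radius %g px, %d units\n"),
              x$patch_size, x$patch_size, x$kernel_size, x$kernel_size,
              x$spatial_freq, x$ring_radius, nrow(x$W)))
  invisible(x)
}

#' Extract centre and surround filter responses from a patch
#'
#' Inner products of every (embedded) kernel with the mean-centred patch.
#' Responses are linear in the patch.
#'
#' @param patch a square numeric matrix of side `bank$patch_size` (an
#'   [image_patch] or plain matrix).
#' @param bank a [build_filterbank()] object.
#' @return an object of class `response_vector`: list with `c` (8 centre
#'   responses, orientation-major then phase) and `n` (named list over
#'   orientation of 16 surround responses, position-major then phase).
#' @export
extract_responses <- function(patch, bank) {
  r <- drop(response_matrix(list(patch), bank))
  response_vector_from_row(r, bank)
}

response_vector_from_row <- function(r, bank) {
  structure(
    list(
      c = r[bank$idx_center],
      n = lapply(bank$idx_surround, function(ii) r[ii])
    ),
    class = "response_vector"
  )
}

#' Filter many patches at once
#'
#' @param patches list of patches (square matrices of side
#'   `bank$patch_size`).
#' @param bank a [build_filterbank()] object.
#' @return an `n x 72` numeric matrix, one response row per patch, columns
#'   ordered as in `bank$layout`.
#' @export
response_matrix <- function(patches, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  npix <- bank$patch_size^2
  P <- vapply(patches, function(p) {
    p <- unclass(p)
    if (!is.matrix(p) || any(dim(p) != bank$patch_size)) {
      stop("patch dimensions must be ", bank$patch_size, " x ",
           bank$patch_size)
    }
    as.numeric(p) - mean(p)
  }, numeric(npix))
  t(bank$W %*% P)
}

#' Assemble per-component coefficient vectors
#'
#' The mixture's non-shared component models the full centre vector
#' `x_* = c` (8-dim); each co-shared component at orientation theta models
#' the concatenation `x_theta = (c, n_theta)` (24-dim) of the full centre
#' block (all four orientations, both phases) with the surround responses
#' at theta.
#'
#' @param r a `response_vector` from [extract_responses()].
#' @return list with `x_star` (8-vector) and `x` (named list over
#'   orientation of 24-vectors).
#' @export
assemble_component_vectors <- function(r) {
  stopifnot(inherits(r, "response_vector"))
  list(
    x_star = r$c,
    x = lapply(r$n, function(n_th) c(r$c, n_th))
  )
}

# Column index blocks of the 72-column response matrix for each GSM family.
component_columns <- function(bank) {
  list(
    center = bank$idx_center,
    surround = bank$idx_surround,
    joint = lapply(bank$idx_surround, function(ii) c(bank$idx_center, ii))
  )
}

# Index of a centre channel in the 8-dim centre block.
center_channel_index <- function(orientation, phase = c("even", "odd"),
                                 orientations = c(0, 45, 90, 135)) {
  phase <- match.arg(phase)
  oi <- match(orientation %% 180, orientations)
  if (is.na(oi)) stop("channel orientation must be one of ",
                      paste(orientations, collapse = ", "))
  (oi - 1) * 2 + if (phase == "even") 1L else 2L
}
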