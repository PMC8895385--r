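#' Orientation tuning curve protocol
#'
#' Describes how tuning curves are probed: grating orientations on a grid
#' relative to the model neuron's preferred orientation (the
#' 90-degree-preferring centre channel), a small aperture covering only
#' the CRF or a large (full-field) one covering CRF and surround, and the
#' readout used before and after adaptation (posterior-weighted mixture
#' before, winner-take-all after, both overridable).  Responses at each
#' grid point are averaged over `n_phases` equally spaced grating phases
#' of the rectified channel estimate, emulating drift-averaged firing
#' rates.
#'
#' @param orientation_grid_deg orientations relative to preferred,
#'   degrees (default -90 to 90 in 15-degree steps).
#' @param aperture `"small"` (CRF-only) or `"large"` (full field).
#' @param n_phases number of grating phases averaged (>= 1).
#' @param contrast grating contrast in `[0, 1]`.
#' @param readout_before,readout_after `"mixture"` or `"wta"`.  The WTA
#'   readout selects ONE component -- the posterior winner for the
#'   adapting stimulus under the state being read out -- and reports that
#'   component's response across the whole grid (the selection vector is
#'   one-hot and constant over the tuning curve).  If no adaptor is given
#'   the winner is selected per test stimulus instead.
#' @param adaptor_deg_relative adaptor orientation relative to preferred,
#'   degrees; used by the WTA readout and by [otc_metrics()].
#' @param estimator component response estimator, `"quadratic"` (default)
#'   or `"posterior_mean"`; see [normalized_component_responses()].
#' @param preferred_deg absolute preferred orientation of the reported
#'   channel (degrees; default 90).
#' @return object of class `otc_protocol`.
#' @export
otc_protocol <- function(orientation_grid_deg = seq(-90, 90, by = 15),
                         aperture = c("small", "large"), n_phases = 8,
                         contrast = 0.5,
                         readout_before = c("mixture", "wta"),
                         readout_after = c("wta", "mixture"),
                         estimator = c("quadratic", "posterior_mean"),
                         adaptor_deg_relative = NULL,
                         preferred_deg = 90) {
  aperture <- match.arg(aperture)
  estimator <- match.arg(estimator)
  stopifnot(n_phases >= 1, contrast >= 0, contrast <= 1)
  grid <- orientation_grid_deg
  if (any(grid < -90 | grid > 90)) {
    warning("grid orientations outside [-90, 90] wrapped")
    grid <- ((grid + 90) %% 180) - 90
  }
  structure(
    list(orientation_grid_deg = grid, aperture = aperture,
         n_phases = as.integer(n_phases), contrast = contrast,
         readout_before = match.arg(readout_before),
         readout_after = match.arg(readout_after),
         estimator = estimator,
         adaptor_deg_relative = adaptor_deg_relative,
         preferred_deg = preferred_deg),
    class = "otc_protocol"
  )
}

otc_aperture_px <- function(protocol, bank) {
  if (protocol$aperture == "small") bank$crf_aperture else "full"
}

# WTA winner for the adapting stimulus: posterior under `state`, averaged
# over grating phases
otc_adaptor_winner <- function(state, bank, protocol) {
  rel <- protocol$adaptor_deg_relative
  if (is.null(rel)) return(NA_character_)
  ori_abs <- (protocol$preferred_deg + rel) %% 180
  phases <- 2 * pi * (seq_len(protocol$n_phases) - 1) / protocol$n_phases
  post <- rowMeans(vapply(phases, function(ph) {
    g <- make_grating(grating_spec(ori_abs, protocol$contrast, ph,
                                   bank$spatial_freq,
                                   otc_aperture_px(protocol, bank),
                                   bank$patch_size))
    component_posteriors(extract_responses(g, bank), state, bank)
  }, numeric(5)))
  component_names()[which.max(post)]
}

# response of one state at one grid orientation: mean over phases of the
# rectified even/odd channel estimates.  For the WTA readout with a known
# adaptor, `winner` fixes the selected component for the whole curve;
# otherwise the winner is chosen per stimulus and the modal one reported.
otc_point <- function(state, bank, ori_abs, protocol, readout,
                      winner = NA_character_) {
  diam <- otc_aperture_px(protocol, bank)
  phases <- 2 * pi * (seq_len(protocol$n_phases) - 1) / protocol$n_phases
  vals <- numeric(length(phases))
  winners <- character(length(phases))
  for (j in seq_along(phases)) {
    g <- make_grating(grating_spec(ori_abs, protocol$contrast, phases[j],
                                   bank$spatial_freq, diam,
                                   bank$patch_size))
    r <- extract_responses(g, bank)
    resp_one <- function(phase) {
      ch <- list(orientation = protocol$preferred_deg %% 180, phase = phase)
      if (readout == "mixture") {
        list(v = mixture_response(r, state, bank, ch,
                                  protocol$estimator),
             w = NA_character_)
      } else if (!is.na(winner)) {
        comps <- normalized_component_responses(r, state, bank, ch,
                                                protocol$estimator)
        list(v = comps[[winner]], w = winner)
      } else {
        v <- wta_response(r, state, bank, ch, protocol$estimator)
        list(v = as.numeric(v), w = attr(v, "winner"))
      }
    }
    ev <- resp_one("even")
    od <- resp_one("odd")
    vals[j] <- (abs(ev$v) + abs(od$v)) / 2
    winners[j] <- ev$w
  }
  list(response = mean(vals),
       winner = if (all(is.na(winners))) NA_character_ else
         names(sort(table(winners), decreasing = TRUE))[1])
}

#' Measure orientation tuning curves before and after adaptation
#'
#' Renders a grating at each grid orientation (aperture per protocol),
#' extracts filter responses, and evaluates the before readout on
#' `state_before` and the after readout on `state_after`.  Deterministic
#' given the protocol.
#'
#' @param state_before,state_after [mgsm_state()] objects sharing the
#'   bank geometry (pass the same state twice for a no-adaptation
#'   control).
#' @param bank the [build_filterbank()].
#' @param protocol an [otc_protocol()].
#' @return an `otc_result`: a tibble with columns `orientation_deg`
#'   (relative to preferred), `before`, `after`, `winner_after`, with the
#'   protocol attached as attribute `"protocol"`.
#' @export
measure_otc <- function(state_before, state_after, bank,
                        protocol = otc_protocol()) {
  stopifnot(inherits(state_before, "mgsm_state"),
            inherits(state_after, "mgsm_state"),
            inherits(protocol, "otc_protocol"))
  grid <- protocol$orientation_grid_deg
  winner_b <- if (protocol$readout_before == "wta")
    otc_adaptor_winner(state_before, bank, protocol) else NA_character_
  winner_a <- if (protocol$readout_after == "wta")
    otc_adaptor_winner(state_after, bank, protocol) else NA_character_
  res <- purrr::map(grid, function(rel) {
    ori_abs <- (protocol$preferred_deg + rel) %% 180
    b <- otc_point(state_before, bank, ori_abs, protocol,
                   protocol$readout_before, winner_b)
    a <- otc_point(state_after, bank, ori_abs, protocol,
                   protocol$readout_after, winner_a)
    tibble::tibble(orientation_deg = rel, before = b$response,
                   after = a$response, winner_after = a$winner)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "protocol") <- protocol
  class(out) <- c("otc_result", class(out))
  out
}

# parabolic interpolation of the peak of a sampled curve;
# returns c(location, value)
interp_peak <- function(x, y) {
  m <- which.max(y)
  if (m == 1 || m == length(y)) return(c(x[m], y[m]))
  y0 <- y[m - 1]; y1 <- y[m]; y2 <- y[m + 1]
  denom <- y0 - 2 * y1 + y2
  if (abs(denom) < 1e-12) return(c(x[m], y[m]))
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 1), -1)
  h <- x[m + 1] - x[m]
  c(x[m] + delta * h, y1 - 0.25 * (y0 - y2) * delta)
}

#' Adaptation metrics of a tuning-curve pair
#'
#' Preferred orientations are located by parabolic interpolation around
#' the grid argmax.  `shift_deg` is signed so that positive means the
#' preferred orientation moved toward the adaptor (attraction) and
#' negative away from it (repulsion).
#'
#' @param result an `otc_result` from [measure_otc()].
#' @param adaptor_deg_relative adaptor orientation relative to the
#'   preferred orientation, degrees.
#' @return one-row tibble: `preferred_before_deg`, `preferred_after_deg`,
#'   `shift_deg`, `peak_ratio` (after/before interpolated peak heights),
#'   `response_ratio_at_adaptor`, `mean_response_ratio`.
#' @export
otc_metrics <- function(result, adaptor_deg_relative) {
  stopifnot(inherits(result, "otc_result"))
  x <- result$orientation_deg
  if (diff(range(result$before)) < 1e-12 ||
      diff(range(result$after)) < 1e-12) {
    warning("flat tuning curve: preferred orientation undefined")
    return(tibble::tibble(
      preferred_before_deg = NA_real_, preferred_after_deg = NA_real_,
      shift_deg = NA_real_, peak_ratio = NA_real_,
      response_ratio_at_adaptor = NA_real_,
      mean_response_ratio = NA_real_
    ))
  }
  pb <- interp_peak(x, result$before)
  pa <- interp_peak(x, result$after)
  toward <- sign(adaptor_deg_relative - pb[1])
  if (toward == 0) toward <- 1
  at_adaptor <- function(y) stats::approx(x, y, xout = adaptor_deg_relative,
                                          rule = 2)$y
  tibble::tibble(
    preferred_before_deg = pb[1],
    preferred_after_deg = pa[1],
    shift_deg = (pa[1] - pb[1]) * toward,
    peak_ratio = pa[2] / pb[2],
    response_ratio_at_adaptor = at_adaptor(result$after) /
      at_adaptor(result$before),
    mean_response_ratio = mean(result$after) / mean(result$before)
  )
}

#' Named adaptation paradigms
#'
#' End-to-end train / adapt / measure pipelines reproducing the model's
#' characteristic adaptation effects.  Small-aperture paradigms probe the
#' CRF alone; large-aperture paradigms probe CRF and surround together.
#' The `large_attraction_*` paradigms additionally perturb the adapted
#' component's covariance (see [perturbation_preset()]).
#'
#' \describe{
#'   \item{small_suppression}{adaptor at the preferred orientation;
#'     response suppression, maximal at the preferred orientation.}
#'   \item{small_repulsion}{flank adaptor 45 deg away; tuning peak
#'     repelled from the adaptor.}
#'   \item{small_facilitation}{orthogonal adaptor; overall facilitation.}
#'   \item{large_maintain}{adaptor at preferred, large grating; peak
#'     response maintained.}
#'   \item{large_flank_prior}{flank adaptor, prior change only; fails to
#'     attract (the negative control for attraction).}
#'   \item{large_facilitation}{orthogonal adaptor, large grating;
#'     facilitation.}
#'   \item{large_attraction_center / _surround / _combined / _double}{
#'     flank adaptor with covariance perturbation presets `center_up`,
#'     `surround_down`, `combined`, `combined_double`.}
#' }
#'
#' @param paradigm one of the names above.
#' @param bank a [build_filterbank()].
#' @param baseline a baseline `mgsm_fit` or `mgsm_state` (from
#'   [train_baseline()]); trained on the spot if `NULL`.
#' @param n_patches_baseline,n_patches_mixed ensemble sizes for the
#'   baseline fit (if needed) and the mixed-dataset retrain.
#' @param grating_fraction,orientation_spread_deg mixed-dataset
#'   parameters (defaults 0.3 and 5 degrees).
#' @param cfg an [em_config()].
#' @param protocol optional [otc_protocol()]; the aperture is forced to
#'   the paradigm's own.
#' @param freeze_covariance override the paradigm's adaptation route:
#'   `TRUE` = prior substitution into the baseline state, `FALSE` = full
#'   retrain, `NULL` (default) = the paradigm's own choice (small
#'   paradigms retrain fully, large paradigms substitute priors).
#' @param seed integer seed for dataset sampling.
#' @return list with `paradigm`, `adaptor_deg_relative`, `result` (the
#'   [measure_otc()] tibble), `metrics` ([otc_metrics()]), and the
#'   `before`/`after` states.
#' @export
run_paradigm <- function(paradigm, bank, baseline = NULL,
                         n_patches_baseline = 4000, n_patches_mixed = 4000,
                         grating_fraction = 0.3,
                         orientation_spread_deg = 5,
                         cfg = em_config(n_iter_max = 60), protocol = NULL,
                         freeze_covariance = NULL, seed = 1L) {
  # Small-aperture paradigms retrain the full state on the mixed dataset
  # (covariances carry the adaptation signal when the surround is not
  # driven); large-aperture paradigms transplant the retrained priors
  # into the baseline state (prior substitution), so the baseline
  # covariances -- on which the declarative perturbations are defined --
  # stay in place.
  paradigms <- list(
    small_suppression        = list(aperture = "small", adaptor = 0,
                                    freeze = FALSE),
    small_repulsion          = list(aperture = "small", adaptor = -45,
                                    freeze = FALSE),
    small_facilitation       = list(aperture = "small", adaptor = -90,
                                    freeze = FALSE),
    large_maintain           = list(aperture = "large", adaptor = 0,
                                    freeze = TRUE),
    large_flank_prior        = list(aperture = "large", adaptor = -45,
                                    freeze = TRUE),
    large_facilitation       = list(aperture = "large", adaptor = -90,
                                    freeze = TRUE),
    large_attraction_center  = list(aperture = "large", adaptor = -45,
                                    freeze = TRUE, preset = "center_up"),
    large_attraction_surround = list(aperture = "large", adaptor = -45,
                                     freeze = TRUE,
                                     preset = "surround_down"),
    large_attraction_combined = list(aperture = "large", adaptor = -45,
                                     freeze = TRUE, preset = "combined"),
    large_attraction_double  = list(aperture = "large", adaptor = -45,
                                    freeze = TRUE,
                                    preset = "combined_double")
  )
  if (!paradigm %in% names(paradigms)) {
    stop("unknown paradigm: ", paradigm, "; available: ",
         paste(names(paradigms), collapse = ", "))
  }
  p <- paradigms[[paradigm]]
  if (is.null(baseline)) {
    baseline <- train_baseline(bank, n_patches_baseline, cfg = cfg,
                               seed = seed)
  }
  before <- if (inherits(baseline, "mgsm_fit")) baseline$state else baseline
  preferred <- (protocol$preferred_deg %||% 90)
  adaptor_abs <- (preferred + p$adaptor) %% 180
  spec <- mixed_dataset_spec(
    n_patches = n_patches_mixed, grating_fraction = grating_fraction,
    adaptor_orientation_deg = adaptor_abs,
    orientation_spread_deg = orientation_spread_deg,
    spatial_freq = bank$spatial_freq,
    texture = texture_params(size = bank$patch_size),
    seed = seed + 1L
  )
  after <- adapt_by_prior(before, spec, bank, cfg,
                          freeze_covariance = freeze_covariance %||%
                            p$freeze)
  if (!is.null(p$preset)) {
    pert <- perturbation_preset(p$preset,
                                target_component = adaptor_abs %% 180)
    after <- adapt_by_covariance(after, pert)
  }
  proto <- protocol %||% otc_protocol(aperture = p$aperture)
  proto$aperture <- p$aperture
  proto$adaptor_deg_relative <- p$adaptor
  result <- measure_otc(before, after, bank, proto)
  list(paradigm = paradigm, adaptor_deg_relative = p$adaptor,
       result = result, metrics = otc_metrics(result, p$adaptor),
       before = before, after = after)
}
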