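#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an orientation tuning curve pair
#'
#' Before-adaptation (black) and after-adaptation (red) tuning curves on
#' the relative-orientation axis, the field's standard presentation.
#'
#' @param object an `otc_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.otc_result <- function(object, ...) {
  df <- tidy(object)
  df$epoch <- factor(df$epoch, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$orientation_deg,
                                   y = .data$response,
                                   colour = .data$epoch)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(before = "black",
                                            after = "red")) +
    ggplot2::labs(x = "orientation relative to preferred (deg)",
                  y = "model response", colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot the component priors of a state
#'
#' @param object an [mgsm_state()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mgsm_state <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = component_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$prior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mixture component", y = "prior probability") +
    ggplot2::theme_classic()
}

#' Plot the EM training trace
#'
#' Prior probability of every component across EM iterations, the
#' standard view of mixture training dynamics.
#'
#' @param object an `mgsm_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mgsm_fit <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("prior_"),
                        names_to = "component", names_prefix = "prior_",
                        values_to = "prior")
  df$component <- factor(df$component, levels = component_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$prior,
                                   colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "EM iteration", y = "prior probability",
                  colour = "component") +
    ggplot2::theme_classic()
}

#' Export filter kernels as an inspection image grid
#'
#' @param bank a [build_filterbank()].
#' @return a ggplot object showing every kernel of the bank.
#' @export
plot_kernels <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  df <- purrr::imap(bank$kernels, function(k, nm) {
    n <- nrow(k)
    tibble::tibble(
      kernel = nm,
      row = rep(seq_len(n), times = n),
      col = rep(seq_len(n), each = n),
      value = as.numeric(k)
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~kernel, nrow = 2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
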