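#' Plot a recording
#'
#' Spike raster over time with the summed stimulus trace overlaid (scaled to
#' the unit axis), faceted above the first LFP channel. Intended as a quick
#' look at what the synthetic plant produced.
#'
#' @param object A [recording()].
#' @param max_s Plot at most this many seconds (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recording
#' @export
autoplot.recording <- function(object, max_s = 5, ...) {
  lim <- min(object$duration_s, max_s)
  spk <- dplyr::filter(object$spikes, .data$time_s <= lim)
  lfp1 <- tibble::tibble(time_s = seq_len(nrow(object$lfp)) / object$lfp_fs,
                         value = object$lfp[, 1L])
  lfp1 <- dplyr::filter(lfp1, .data$time_s <= lim)
  stim <- tibble::tibble(time_s = seq_len(nrow(object$stimulus)) / object$stim_fs,
                         value = rowSums(object$stimulus))
  stim <- dplyr::filter(stim, .data$time_s <= lim)
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = spk$time_s, y = as.numeric(spk$unit),
                   panel = "spikes"),
    tibble::tibble(time_s = lfp1$time_s, y = lfp1$value, panel = "lfp ch1"),
    tibble::tibble(time_s = stim$time_s,
                   y = stim$value * max(1, object$n_units) /
                     max(stim$value, 1e-12),
                   panel = "stimulus"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$y)) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$panel == "spikes"),
                        shape = "|", size = 2) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$panel != "spikes")) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stimulation sequence
#'
#' Per-channel pulse lollipops (time vs amplitude), one facet row per
#' channel.
#'
#' @param object A [stimulation_sequence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stimulation_sequence
#' @export
autoplot.stimulation_sequence <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms / 1000,
                                   y = .data$amplitude_uA)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time_ms / 1000, yend = 0)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uA)") +
    ggplot2::theme_minimal()
}

#' Plot decoded versus desired stimulus
#'
#' Overlays the decoder output on the target trace for one channel of a test
#' dataset.
#'
#' @param model A trained [qklms()] decoder.
#' @param ds A `decoding_dataset`.
#' @param channel Target channel to display.
#' @return A ggplot object.
#' @export
plot_decoding <- function(model, ds, channel = 1) {
  pred <- predict(model, ds)
  df <- tibble::tibble(
    time_s = rep(ds$times_ms / 1000, 2L),
    value = c(ds$targets[, channel], pred[, channel]),
    signal = rep(c("desired", "decoded"), each = length(ds$times_ms)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   color = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "stimulus", color = NULL) +
    ggplot2::theme_minimal()
}
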