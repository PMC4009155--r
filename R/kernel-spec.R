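#' Composite kernel specification
#'
#' Bundles every kernel hyperparameter: the spike and LFP Schoenberg kernel
#' sizes, the rectangular intensity-smoothing width, channel normalization,
#' and how the two modalities are combined.
#'
#' `sigma_s` scales the squared intensity-function distance, so `sigma_s^2`
#' carries the units of the integrated squared intensity (1/ms); `sigma_x^2`
#' carries the units of the time-integrated squared LFP amplitude. Both are
#' usually set from data with [kernel_size_heuristic()].
#'
#' @param sigma_s Spike kernel size, > 0.
#' @param sigma_x LFP kernel size, > 0.
#' @param smoothing_width Rectangular smoothing width (the intensity
#'   estimator's window) in ms, > 0, or `NULL` to default to each spike
#'   window's own length, which makes the smoothed intensity a cumulative
#'   spike-count profile.
#' @param normalize_channels Divide the direct-sum kernels by the unit/channel
#'   count so self-similarity is 1 (default `TRUE`). Set `FALSE` for the
#'   plain unweighted sum.
#' @param modality_rule How spike and LFP kernels are combined:
#'   `"product"` (tensor-product, strict joint similarity), `"sum"`
#'   (direct-sum, lenient), or a single modality (`"spikes_only"`,
#'   `"lfp_only"`).
#' @return An object of class `composite_kernel_spec`.
#' @examples
#' composite_kernel_spec(sigma_s = 0.2, sigma_x = 1, modality_rule = "product")
#' @export
composite_kernel_spec <- function(sigma_s, sigma_x, smoothing_width = NULL,
                                  normalize_channels = TRUE,
                                  modality_rule = c("product", "sum",
                                                    "spikes_only", "lfp_only")) {
  assert_scalar_pos(sigma_s, "sigma_s")
  assert_scalar_pos(sigma_x, "sigma_x")
  if (!is.null(smoothing_width)) assert_scalar_pos(smoothing_width, "smoothing_width")
  modality_rule <- match.arg(modality_rule)
  structure(list(sigma_s = sigma_s, sigma_x = sigma_x,
                 smoothing_width = smoothing_width,
                 normalize_channels = isTRUE(normalize_channels),
                 modality_rule = modality_rule),
            class = "composite_kernel_spec")
}

#' @export
print.composite_kernel_spec <- function(x, ...) {
  cat(sprintf(
    "<composite_kernel_spec> rule = %s, sigma_s = %g, sigma_x = %g, smoothing width = %s ms, %s\n",
    x$modality_rule, x$sigma_s, x$sigma_x,
    if (is.null(x$smoothing_width)) "window-length" else format(x$smoothing_width),
    if (x$normalize_channels) "normalized" else "unnormalized"))
  invisible(x)
}

smoothing_width_for <- function(spec, window_length) {
  spec$smoothing_width %||% window_length
}

#' Read or write a kernel specification as JSON
#'
#' Serializes the fields `sigma_s`, `sigma_x`, `smoothing_width_ms`,
#' `normalize_channels` and `modality_rule`.
#'
#' @param spec A [composite_kernel_spec()].
#' @param path File path.
#' @return `read_kernel_spec()` returns a `composite_kernel_spec`;
#'   `write_kernel_spec()` returns `path` invisibly.
#' @export
write_kernel_spec <- function(spec, path) {
  stopifnot(inherits(spec, "composite_kernel_spec"))
  doc <- list(sigma_s = spec$sigma_s, sigma_x = spec$sigma_x,
              smoothing_width_ms = spec$smoothing_width,
              normalize_channels = spec$normalize_channels,
              modality_rule = spec$modality_rule)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_kernel_spec
#' @export
read_kernel_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_kernel_spec(sigma_s = doc$sigma_s, sigma_x = doc$sigma_x,
                        smoothing_width = doc$smoothing_width_ms,
                        normalize_channels = doc$normalize_channels,
                        modality_rule = doc$modality_rule)
}
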