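#' Spike window
#'
#' A window of spike times from a single unit, in milliseconds relative to the
#' window start. Windows are the atomic spike-train input of the Schoenberg
#' kernel: the spike train is treated as a realization of a point process and
#' compared through its smoothed intensity function.
#'
#' @param times Numeric vector of spike times in ms, `0 <= t <= window_length`,
#'   strictly increasing. May be empty.
#' @param window_length Window length `T_s` in ms.
#' @return An object of class `spike_window`.
#' @examples
#' spike_window(c(2, 3.5), window_length = 9)
#' @export
spike_window <- function(times = numeric(0), window_length) {
  assert_scalar_pos(window_length, "window_length")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) abort("spike times must be finite")
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1L) {
    abort("spike times must be strictly increasing")
  }
  if (length(times) && (times[1L] < 0 || times[length(times)] > window_length)) {
    abort("spike times must lie in [0, window_length]")
  }
  structure(list(times = times, window_length = window_length),
            class = "spike_window")
}

#' Multiunit spike window
#'
#' A list of per-unit spike windows sharing one window length; the population
#' is compared with a direct-sum kernel over units.
#'
#' @param units A list of [spike_window()] objects or bare numeric time vectors.
#' @param window_length Shared window length in ms; required when `units` are
#'   bare vectors.
#' @return An object of class `multiunit_spike_window` holding `units` (a list
#'   of numeric time vectors) and `window_length`.
#' @export
multiunit_spike_window <- function(units, window_length = NULL) {
  if (!is.list(units) || length(units) < 1L) abort("need at least one unit")
  if (inherits(units[[1L]], "spike_window")) {
    wl <- unique(vapply(units, function(u) u$window_length, numeric(1)))
    if (length(wl) != 1L) abort("window-mismatch: units must share window_length")
    window_length <- wl
    units <- lapply(units, function(u) u$times)
  } else {
    if (is.null(window_length)) abort("`window_length` required for bare vectors")
    units <- lapply(units, function(u) spike_window(u, window_length)$times)
  }
  structure(list(units = units, window_length = window_length),
            class = "multiunit_spike_window")
}

n_units <- function(x) length(x$units)

#' LFP window
#'
#' A uniformly sampled segment of a single local-field-potential channel.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param sample_period Sampling period in ms.
#' @return An object of class `lfp_window`.
#' @export
lfp_window <- function(samples, sample_period) {
  assert_scalar_pos(sample_period, "sample_period")
  samples <- as.numeric(samples)
  if (length(samples) < 1L || any(!is.finite(samples))) {
    abort("LFP samples must be non-empty and finite")
  }
  structure(list(samples = samples, sample_period = sample_period,
                 window_length = length(samples) * sample_period),
            class = "lfp_window")
}

#' Multichannel LFP window
#'
#' Congruent single-channel LFP windows stacked into a samples-by-channels
#' matrix; channels are compared with a direct-sum kernel.
#'
#' @param channels A list of [lfp_window()] objects, or a numeric matrix with
#'   one column per channel.
#' @param sample_period Sampling period in ms; required for a bare matrix.
#' @return An object of class `multichannel_lfp_window` with fields `samples`
#'   (matrix), `sample_period` and `window_length`.
#' @export
multichannel_lfp_window <- function(channels, sample_period = NULL) {
  if (is.matrix(channels)) {
    if (is.null(sample_period)) abort("`sample_period` required for a matrix")
    assert_scalar_pos(sample_period, "sample_period")
    if (!nrow(channels) || !ncol(channels) || any(!is.finite(channels))) {
      abort("LFP matrix must be non-empty and finite")
    }
    m <- channels
  } else {
    if (!is.list(channels) || length(channels) < 1L) abort("need at least one channel")
    sp <- unique(vapply(channels, function(x) x$sample_period, numeric(1)))
    ln <- unique(vapply(channels, function(x) length(x$samples), numeric(1)))
    if (length(sp) != 1L || length(ln) != 1L) {
      abort("shape mismatch: channels must share length and sample_period")
    }
    sample_period <- sp
    m <- vapply(channels, function(x) x$samples, numeric(ln))
    m <- matrix(m, nrow = ln)
  }
  structure(list(samples = m, sample_period = sample_period,
                 window_length = nrow(m) * sample_period),
            class = "multichannel_lfp_window")
}

#' Multiscale sample
#'
#' One analysis window pairing multiunit spiking with a multichannel LFP
#' segment, both ending at the same prediction time. This is the joint input
#' of the tensor-product kernel.
#'
#' @param spikes A [multiunit_spike_window()].
#' @param lfp A [multichannel_lfp_window()].
#' @return An object of class `multiscale_sample`.
#' @export
multiscale_sample <- function(spikes, lfp) {
  if (!inherits(spikes, "multiunit_spike_window")) abort("`spikes` must be a multiunit_spike_window")
  if (!inherits(lfp, "multichannel_lfp_window")) abort("`lfp` must be a multichannel_lfp_window")
  structure(list(spikes = spikes, lfp = lfp), class = "multiscale_sample")
}

#' @export
print.multiscale_sample <- function(x, ...) {
  cat(sprintf(
    "<multiscale_sample> %d units / T_s = %g ms; %d LFP channels x %d samples / T_x = %g ms\n",
    n_units(x$spikes), x$spikes$window_length,
    ncol(x$lfp$samples), nrow(x$lfp$samples), x$lfp$window_length))
  invisible(x)
}
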