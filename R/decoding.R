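#' Assemble a recording
#'
#' A continuous multiscale recording: a spike event table, a multichannel LFP
#' matrix with its sampling rate, and one or more stimulus traces with their
#' own sampling rate. Times on the interface are in seconds; windowed analysis
#' works in milliseconds internally.
#'
#' Sample `i` of a trace sampled at `fs` is taken to sit at time `i / fs`
#' seconds (the sample closes the interval it summarizes), which keeps sliding
#' windows causal.
#'
#' @param spikes Tibble/data frame with columns `unit` (integer) and `time_s`.
#' @param lfp Numeric matrix, time by channels.
#' @param lfp_fs LFP sampling rate in Hz.
#' @param stimulus Numeric matrix, time by stimulus channels.
#' @param stim_fs Stimulus sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param n_units Number of spiking units; defaults to `max(spikes$unit)`.
#' @param meta Optional list of extra metadata (kept as-is).
#' @return An object of class `recording`.
#' @export
recording <- function(spikes, lfp, lfp_fs, stimulus, stim_fs, duration_s,
                      n_units = NULL, meta = list()) {
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("unit", "time_s") %in% names(spikes)))
  assert_scalar_pos(lfp_fs, "lfp_fs")
  assert_scalar_pos(stim_fs, "stim_fs")
  assert_scalar_pos(duration_s, "duration_s")
  lfp <- as.matrix(lfp)
  stimulus <- as.matrix(stimulus)
  if (nrow(spikes) && (min(spikes$time_s) < 0 || max(spikes$time_s) > duration_s)) {
    abort("spike times must lie within [0, duration_s]")
  }
  n_units <- as.integer(n_units %||% max(1L, suppressWarnings(max(spikes$unit, 0L))))
  structure(list(spikes = spikes, lfp = lfp, lfp_fs = lfp_fs,
                 stimulus = stimulus, stim_fs = stim_fs,
                 duration_s = duration_s, n_units = n_units, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %.3f s, %d units (%d spikes), %d LFP ch @ %g Hz, %d stim ch @ %g Hz\n",
    x$duration_s, x$n_units, nrow(x$spikes), ncol(x$lfp), x$lfp_fs,
    ncol(x$stimulus), x$stim_fs))
  invisible(x)
}

#' Slide analysis windows over a recording
#'
#' Builds the decoding dataset: at every target time `t_k = k * step` with
#' `t_k >= max(T_s, T_x)` (ms), the spike window collects events in
#' `(t_k - T_s, t_k]` shifted to window coordinates, the LFP window collects
#' the samples in `(t_k - T_x, t_k]`, and the target is the stimulus value at
#' `t_k` (nearest stimulus sample, no interpolation). Windows are causal: they
#' end at the prediction time.
#'
#' For inverse-model training a positive `target_delay_ms` pairs each window
#' with the stimulus `target_delay_ms` earlier, so that a causal response
#' window covers the activity its stimulus evoked (the control scheme's
#' modeling delay).
#'
#' @param rec A [recording()].
#' @param spike_window_ms Spike window length `T_s` in ms (default 9).
#' @param lfp_window_ms LFP window length `T_x` in ms (default 20).
#' @param step_ms Window step in ms (default 5, the stimulus discretization).
#' @param target_delay_ms Pair the window ending at `t` with the stimulus at
#'   `t - target_delay_ms` (default 0: the stimulus at the right edge).
#' @return An object of class `decoding_dataset`: a list with `samples` (list
#'   of [multiscale_sample()]), `targets` (matrix, windows by stimulus
#'   channels), `times_ms`, and the windowing parameters.
#' @export
slide_windows <- function(rec, spike_window_ms = 9, lfp_window_ms = 20,
                          step_ms = 5, target_delay_ms = 0) {
  stopifnot(inherits(rec, "recording"))
  assert_scalar_pos(step_ms, "step_ms")
  dur_ms <- rec$duration_s * 1000
  wmax <- max(spike_window_ms, lfp_window_ms)
  if (wmax > dur_ms) abort("window longer than recording")
  times <- wmax + step_ms * (0:floor((dur_ms - wmax) / step_ms))
  n <- length(times)

  lfp_tau <- 1000 / rec$lfp_fs
  lfp_len <- round(lfp_window_ms / lfp_tau)
  if (lfp_len < 1L) abort("LFP window shorter than one sample")

  # per-unit sorted times in ms
  unit_times <- lapply(seq_len(rec$n_units), function(u) {
    sort(rec$spikes$time_s[rec$spikes$unit == u]) * 1000
  })

  stim_tau <- 1000 / rec$stim_fs
  stim_idx <- pmin(pmax(round((times - target_delay_ms) / stim_tau), 1L),
                   nrow(rec$stimulus))
  targets <- rec$stimulus[stim_idx, , drop = FALSE]

  samples <- vector("list", n)
  for (k in seq_len(n)) {
    tk <- times[k]
    lo <- tk - spike_window_ms
    units <- lapply(unit_times, function(tt) {
      tt[tt > lo & tt <= tk] - lo
    })
    sw <- structure(list(units = units, window_length = spike_window_ms),
                    class = "multiunit_spike_window")
    hi_idx <- round(tk / lfp_tau)
    seg <- rec$lfp[(hi_idx - lfp_len + 1L):hi_idx, , drop = FALSE]
    lw <- structure(list(samples = seg, sample_period = lfp_tau,
                         window_length = lfp_len * lfp_tau),
                    class = "multichannel_lfp_window")
    samples[[k]] <- structure(list(spikes = sw, lfp = lw),
                              class = "multiscale_sample")
  }
  structure(list(samples = samples, targets = targets, times_ms = times,
                 step_ms = step_ms, spike_window_ms = spike_window_ms,
                 lfp_window_ms = lfp_window_ms,
                 target_delay_ms = target_delay_ms,
                 alignment = "right-edge-causal"),
            class = "decoding_dataset")
}

#' @export
print.decoding_dataset <- function(x, ...) {
  cat(sprintf(
    "<decoding_dataset> %d windows (T_s = %g ms, T_x = %g ms, step = %g ms), %d target channel(s)\n",
    length(x$samples), x$spike_window_ms, x$lfp_window_ms, x$step_ms,
    ncol(x$targets)))
  invisible(x)
}

#' @export
length.decoding_dataset <- function(x) length(x$samples)

#' @export
`[.decoding_dataset` <- function(x, i) {
  structure(list(samples = x$samples[i],
                 targets = x$targets[i, , drop = FALSE],
                 times_ms = x$times_ms[i], step_ms = x$step_ms,
                 spike_window_ms = x$spike_window_ms,
                 lfp_window_ms = x$lfp_window_ms,
                 target_delay_ms = x$target_delay_ms,
                 alignment = x$alignment),
            class = "decoding_dataset")
}

#' Autocorrelation coefficients
#'
#' Sample autocorrelation
#' `rho_h = sum_{t=h+1} (y_t - ybar)(y_{t-h} - ybar) / sum_t (y_t - ybar)^2`,
#' computed per channel and averaged over channels for matrix input.
#'
#' @param y Numeric vector, or matrix with one column per channel.
#' @param max_lag Largest lag (in samples).
#' @return A tibble with columns `lag` (0..max_lag) and `acf`; `acf[lag 0]`
#'   is 1 by construction.
#' @export
autocorr <- function(y, max_lag) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n <= max_lag) abort("signal shorter than max_lag")
  per_ch <- vapply(seq_len(ncol(y)), function(c) {
    yc <- y[, c]
    d <- yc - mean(yc)
    denom <- sum(d^2)
    if (denom == 0) abort("zero-variance signal")
    vapply(0:max_lag, function(h) {
      if (h == 0) 1 else sum(d[(h + 1):n] * d[1:(n - h)]) / denom
    }, numeric(1))
  }, numeric(max_lag + 1L))
  tibble::tibble(lag = 0:max_lag, acf = rowMeans(as.matrix(per_ch)))
}

#' Confidence bounds for an autocorrelation coefficient
#'
#' Large-sample 95% bounds `+/- 2 SE` for the hypothesis that the lag-`h`
#' autocorrelation is zero, with
#' `SE = sqrt((1 + 2 sum_{i=1}^{h-1} rho_i^2) / N)` (Bartlett's growing
#' bound).
#'
#' @param rho Numeric vector of autocorrelation estimates starting at lag 1.
#' @param N Signal length.
#' @param h Lag being tested, >= 1.
#' @return Numeric `c(lo, hi)`, symmetric about zero.
#' @export
autocorr_bounds <- function(rho, N, h) {
  stopifnot(N > 0, h >= 1)
  s <- if (h > 1) sum(rho[seq_len(h - 1)]^2) else 0
  se <- sqrt((1 + 2 * s) / N)
  c(-2 * se, 2 * se)
}

#' Estimate an analysis window length from the autocorrelation
#'
#' Returns the smallest lag `h*` (converted to ms) from which the
#' autocorrelation stays inside its +/-2 SE confidence band up to `max_lag`
#' -- the point where the stimulus-locked response has died out, hence a
#' natural sliding-window length for that signal. If the band is never
#' sustained, `max_lag` is returned with attribute `converged = FALSE` and a
#' warning.
#'
#' @param y Numeric vector or matrix (channels in columns).
#' @param max_lag Largest lag inspected, in samples.
#' @param sample_period_ms Sampling period in ms (default 1).
#' @return Window length in ms with attribute `converged`.
#' @export
estimate_window_length <- function(y, max_lag, sample_period_ms = 1) {
  ac <- autocorr(y, max_lag)
  rho <- ac$acf[-1L]
  N <- nrow(as.matrix(y))
  inside <- vapply(seq_len(max_lag), function(h) {
    abs(rho[h]) < autocorr_bounds(rho, N, h)[2L]
  }, logical(1))
  sustained <- rev(cumprod(rev(inside))) > 0
  if (any(sustained)) {
    h_star <- which(sustained)[1L]
    out <- h_star * sample_period_ms
    attr(out, "converged") <- TRUE
  } else {
    warn("autocorrelation never stays inside the confidence band; returning max_lag")
    out <- max_lag * sample_period_ms
    attr(out, "converged") <- FALSE
  }
  out
}

#' Normalized mean squared error
#'
#' `NMSE = sum (y - d)^2 / sum (d - mean(d))^2`: 0 for a perfect
#' reconstruction, 1 for predicting the target mean.
#'
#' @param y Estimate (vector, or matrix by channel).
#' @param d Desired signal, same shape; must be non-constant.
#' @return Scalar for vectors, per-channel numeric vector for matrices.
#' @export
nmse <- function(y, d) {
  y <- as.matrix(y); d <- as.matrix(d)
  stopifnot(identical(dim(y), dim(d)))
  out <- vapply(seq_len(ncol(d)), function(c) {
    denom <- sum((d[, c] - mean(d[, c]))^2)
    if (denom == 0) abort("constant target: NMSE undefined")
    sum((y[, c] - d[, c])^2) / denom
  }, numeric(1))
  if (length(out) == 1L) out[[1L]] else out
}

#' Train a stimulus decoder
#'
#' Fits a Q-KLMS decoder from multiscale windows to the stimulus channels.
#' When `spec` is `NULL`, kernel sizes are set from the training samples with
#' [kernel_size_heuristic()] and the modality rule defaults to the
#' tensor product.
#'
#' @param ds A `decoding_dataset` from [slide_windows()].
#' @param spec A [composite_kernel_spec()], or `NULL` to build one from the
#'   data.
#' @param modality_rule Rule used when `spec` is `NULL`.
#' @param learning_rate,quantization_size,epochs Q-KLMS settings; the default
#'   quantization size 0 merges only repeated windows.
#' @return The trained [qklms()] model, with the learning trace attached as
#'   attribute `"trace"`.
#' @export
train_decoder <- function(ds, spec = NULL,
                          modality_rule = c("product", "sum", "spikes_only",
                                            "lfp_only"),
                          learning_rate = 0.2, quantization_size = 0,
                          epochs = 3) {
  stopifnot(inherits(ds, "decoding_dataset"))
  if (is.null(spec)) {
    modality_rule <- match.arg(modality_rule)
    spec <- composite_kernel_spec(
      sigma_s = kernel_size_heuristic(ds, "spikes"),
      sigma_x = kernel_size_heuristic(ds, "lfp"),
      modality_rule = modality_rule)
  }
  model <- qklms(spec, n_outputs = ncol(ds$targets),
                 learning_rate = learning_rate,
                 quantization_size = quantization_size)
  fit <- qklms_train(model, ds, epochs = epochs)
  out <- fit$model
  attr(out, "trace") <- fit$trace
  out
}

#' Evaluate a decoder on held-out windows
#'
#' Pure evaluation: predictions are computed without any model update and
#' scored channel-wise with [nmse()].
#'
#' @param model A trained [qklms()] decoder.
#' @param ds A test `decoding_dataset` (disjoint from training).
#' @return A tibble with columns `channel` and `nmse`.
#' @export
evaluate_decoder <- function(model, ds) {
  stopifnot(inherits(model, "qklms"), inherits(ds, "decoding_dataset"))
  pred <- predict(model, ds)
  vals <- vapply(seq_len(ncol(ds$targets)), function(ch) {
    if (stats::sd(ds$targets[, ch]) == 0) return(NA_real_)
    nmse(pred[, ch], ds$targets[, ch])
  }, numeric(1))
  if (anyNA(vals)) warn("constant target channel(s): NMSE reported as NA")
  tibble::tibble(channel = seq_len(ncol(ds$targets)), nmse = vals)
}

bin_counts <- function(spikes, unit, bin_ms, duration_ms) {
  nb <- max(1L, floor(duration_ms / bin_ms + 1e-9))
  tt <- spikes$time_s[spikes$unit == unit] * 1000
  tt <- tt[tt > 0 & tt <= nb * bin_ms]
  tabulate(ceiling(tt / bin_ms), nbins = nb)
}

spikes_of <- function(x) {
  if (inherits(x, "recording")) x$spikes else tibble::as_tibble(x)
}

#' Binned spike-train correlation
#'
#' Pearson correlation of per-bin spike counts (5 ms bins by default),
#' computed per unit and averaged over units. Units whose count vector is
#' constant in either train are dropped with a warning; if every unit is
#' degenerate an error is raised.
#'
#' @param a,b Spike tables (`unit`, `time_s`) or [recording()]s covering the
#'   same span.
#' @param bin_ms Bin width in ms.
#' @param duration_s Observation span in seconds.
#' @param units Units to include; defaults to the union of units present.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
binned_correlation <- function(a, b, bin_ms = 5, duration_s, units = NULL) {
  assert_scalar_pos(bin_ms, "bin_ms")
  sa <- spikes_of(a); sb <- spikes_of(b)
  dur_ms <- duration_s * 1000
  units <- units %||% sort(union(unique(sa$unit), unique(sb$unit)))
  ccs <- vapply(units, function(u) {
    xa <- bin_counts(sa, u, bin_ms, dur_ms)
    xb <- bin_counts(sb, u, bin_ms, dur_ms)
    if (sd(xa) == 0 || sd(xb) == 0) return(NA_real_)
    stats::cor(xa, xb)
  }, numeric(1))
  if (all(is.na(ccs))) abort("zero-variance bin-count vectors for every unit")
  if (anyNA(ccs)) warn("dropping units with constant bin counts")
  mean(ccs, na.rm = TRUE)
}

#' Binned cross-correlation over lags
#'
#' Unit-averaged Pearson correlation of binned spike counts as one train is
#' lagged against the other; a matched, time-locked response peaks at lag 0.
#'
#' @inheritParams binned_correlation
#' @param max_lag_bins Largest lag in bins (both signs are evaluated).
#' @return A tibble with columns `lag_bins`, `lag_ms` and `cc`.
#' @export
binned_crosscorr <- function(a, b, bin_ms = 5, duration_s, max_lag_bins = 10,
                             units = NULL) {
  sa <- spikes_of(a); sb <- spikes_of(b)
  dur_ms <- duration_s * 1000
  units <- units %||% sort(union(unique(sa$unit), unique(sb$unit)))
  xa <- lapply(units, function(u) bin_counts(sa, u, bin_ms, dur_ms))
  xb <- lapply(units, function(u) bin_counts(sb, u, bin_ms, dur_ms))
  lags <- -max_lag_bins:max_lag_bins
  cc <- vapply(lags, function(L) {
    vals <- vapply(seq_along(units), function(i) {
      x <- xa[[i]]; y <- xb[[i]]
      n <- length(x)
      if (L >= 0) {
        xs <- x[(1 + L):n]; ys <- y[1:(n - L)]
      } else {
        xs <- x[1:(n + L)]; ys <- y[(1 - L):n]
      }
      if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
      stats::cor(xs, ys)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(lag_bins = lags, lag_ms = lags * bin_ms, cc = cc)
}
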