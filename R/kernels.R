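#' Estimate a spike-train intensity function by rectangular smoothing
#'
#' Convolves the spike train with the rectangular smoothing function
#' `g(t) = (1/W)(U(t) - U(t - W))` (U the Heaviside step), giving the
#' piecewise-constant intensity estimate
#' `lambda(t) = sum_m (1/W) 1[t_m <= t < t_m + W]`, truncated to the window
#' `[0, T_s]`. The representation is exact: no time grid is involved.
#'
#' @param spikes A [spike_window()].
#' @param smoothing_width Width `W` of the rectangular smoother in ms.
#' @return A tibble of class `intensity_estimate` with columns `start`, `end`
#'   (ms) and `intensity` (1/ms), covering `[0, T_s]` without gaps.
#' @examples
#' estimate_intensity(spike_window(c(2, 3), 9), smoothing_width = 9)
#' @export
estimate_intensity <- function(spikes, smoothing_width) {
  stopifnot(inherits(spikes, "spike_window"))
  assert_scalar_pos(smoothing_width, "smoothing_width")
  Ts <- spikes$window_length
  t <- spikes$times
  bps <- sort(unique(c(0, Ts, t[t < Ts], pmin(t + smoothing_width, Ts))))
  lo <- bps[-length(bps)]
  hi <- bps[-1L]
  level <- vapply(lo, function(x) {
    sum(t <= x & x < t + smoothing_width) / smoothing_width
  }, numeric(1))
  out <- tibble::tibble(start = lo, end = hi, intensity = level)
  attr(out, "window_length") <- Ts
  attr(out, "smoothing_width") <- smoothing_width
  class(out) <- c("intensity_estimate", class(out))
  out
}

# Closed-form integral of lambda_a * lambda_b over [0, Ts] via rectangle
# overlaps; the exact counterpart of the grid oracle used in the tests.
cross_intensity_integral <- function(ta, tb, Ts, W) {
  if (!length(ta) || !length(tb)) return(0)
  ov <- outer(ta, tb, function(a, b) {
    pmax(0, pmin(a + W, b + W, Ts) - pmax(a, b))
  })
  sum(ov) / W^2
}

#' Schoenberg kernel between two spike windows
#'
#' Gaussian-like kernel on smoothed intensity functions:
#' `exp(-int (lambda_a - lambda_b)^2 dt / sigma_s^2)`, the integral running
#' over the shared window `[0, T_s]` and evaluated in closed form from
#' rectangle overlaps.
#'
#' @param a,b [spike_window()] objects with equal `window_length`.
#' @param spec A [composite_kernel_spec()]; uses `sigma_s` and
#'   `smoothing_width`.
#' @return Kernel value in `(0, 1]`.
#' @export
spike_kernel <- function(a, b, spec) {
  stopifnot(inherits(a, "spike_window"), inherits(b, "spike_window"))
  if (a$window_length != b$window_length) {
    abort("window-mismatch: spike windows must share window_length")
  }
  Ts <- a$window_length
  W <- smoothing_width_for(spec, Ts)
  d2 <- cross_intensity_integral(a$times, a$times, Ts, W) +
    cross_intensity_integral(b$times, b$times, Ts, W) -
    2 * cross_intensity_integral(a$times, b$times, Ts, W)
  exp(-max(0, d2) / spec$sigma_s^2)
}

#' Direct-sum kernel over spiking units
#'
#' Sum of single-unit Schoenberg kernels with units matched by index;
#' divided by the unit count when `spec$normalize_channels` is `TRUE` so that
#' self-similarity is 1.
#'
#' @param a,b [multiunit_spike_window()] objects with equal unit counts.
#' @param spec A [composite_kernel_spec()].
#' @return Kernel value in `(0, N]`, or `(0, 1]` when normalized.
#' @export
multiunit_spike_kernel <- function(a, b, spec) {
  stopifnot(inherits(a, "multiunit_spike_window"),
            inherits(b, "multiunit_spike_window"))
  if (n_units(a) != n_units(b)) abort("unit-count mismatch")
  if (a$window_length != b$window_length) {
    abort("window-mismatch: spike windows must share window_length")
  }
  Ts <- a$window_length
  W <- smoothing_width_for(spec, Ts)
  k <- sum(vapply(seq_len(n_units(a)), function(u) {
    ta <- a$units[[u]]; tb <- b$units[[u]]
    d2 <- cross_intensity_integral(ta, ta, Ts, W) +
      cross_intensity_integral(tb, tb, Ts, W) -
      2 * cross_intensity_integral(ta, tb, Ts, W)
    exp(-max(0, d2) / spec$sigma_s^2)
  }, numeric(1)))
  if (spec$normalize_channels) k / n_units(a) else k
}

#' Schoenberg kernel between two LFP windows
#'
#' `exp(-||x_a - x_b||^2 / sigma_x^2)` with the squared distance approximated
#' by the left Riemann sum `sum_k (x_a[k] - x_b[k])^2 * sample_period`, so
#' `sigma_x^2` has time-integral units and the value is stable under
#' resampling in the fine-grid limit.
#'
#' @param a,b [lfp_window()] objects with equal length and sampling period.
#' @param spec A [composite_kernel_spec()]; uses `sigma_x`.
#' @return Kernel value in `(0, 1]`.
#' @export
lfp_kernel <- function(a, b, spec) {
  stopifnot(inherits(a, "lfp_window"), inherits(b, "lfp_window"))
  if (length(a$samples) != length(b$samples) ||
      a$sample_period != b$sample_period) {
    abort("shape mismatch: LFP windows must share length and sample_period")
  }
  d2 <- sum((a$samples - b$samples)^2) * a$sample_period
  exp(-d2 / spec$sigma_x^2)
}

#' Direct-sum kernel over LFP channels
#'
#' @param a,b [multichannel_lfp_window()] objects with congruent shapes.
#' @param spec A [composite_kernel_spec()].
#' @return Kernel value in `(0, C]`, or `(0, 1]` when normalized.
#' @export
multichannel_lfp_kernel <- function(a, b, spec) {
  stopifnot(inherits(a, "multichannel_lfp_window"),
            inherits(b, "multichannel_lfp_window"))
  if (!identical(dim(a$samples), dim(b$samples)) ||
      a$sample_period != b$sample_period) {
    abort("shape mismatch: LFP windows must share shape and sample_period")
  }
  C <- ncol(a$samples)
  d2 <- colSums((a$samples - b$samples)^2) * a$sample_period
  k <- sum(exp(-d2 / spec$sigma_x^2))
  if (spec$normalize_channels) k / C else k
}

#' Joint kernel on multiscale samples
#'
#' Combines the multiunit spike kernel and the multichannel LFP kernel
#' according to `spec$modality_rule`: the tensor-product (`"product"`) is a
#' strict joint similarity -- if either factor is near zero the joint kernel
#' is near zero -- while `"sum"` averages the evidence, and the single-modality
#' rules pass one factor through. All rules yield positive-definite kernels.
#'
#' @param a,b [multiscale_sample()] objects.
#' @param spec A [composite_kernel_spec()].
#' @return Kernel value (scalar).
#' @export
joint_kernel <- function(a, b, spec) {
  stopifnot(inherits(a, "multiscale_sample"), inherits(b, "multiscale_sample"))
  switch(spec$modality_rule,
    product = multiunit_spike_kernel(a$spikes, b$spikes, spec) *
      multichannel_lfp_kernel(a$lfp, b$lfp, spec),
    sum = multiunit_spike_kernel(a$spikes, b$spikes, spec) +
      multichannel_lfp_kernel(a$lfp, b$lfp, spec),
    spikes_only = multiunit_spike_kernel(a$spikes, b$spikes, spec),
    lfp_only = multichannel_lfp_kernel(a$lfp, b$lfp, spec))
}

#' RKHS distance from kernel evaluations
#'
#' `d = sqrt(k(a,a) + k(b,b) - 2 k(a,b))`; the argument of the square root is
#' clipped at zero against round-off. For normalized kernels this reduces to
#' `sqrt(2 - 2k)`.
#'
#' @param k_aa,k_bb Self-similarities.
#' @param k_ab Cross kernel value. All three may be vectors.
#' @return Non-negative distance(s).
#' @export
rkhs_distance <- function(k_aa, k_bb, k_ab) {
  sqrt(pmax(0, k_aa + k_bb - 2 * k_ab))
}

# Modality kernel matrices for packed samples. `pb = NULL` gives the
# symmetric Gram over `pa` alone.
modal_grams <- function(pa, pb, spec) {
  W <- smoothing_width_for(spec, pa$window_length)
  if (is.null(pb)) {
    Ks <- cpp_spike_gram(pa$times, pa$starts, pa$counts, pa$window_length, W,
                         spec$sigma_s, spec$normalize_channels)
    Kl <- cpp_lfp_gram(pa$X, pa$len, pa$n_channels, pa$sample_period,
                       spec$sigma_x, spec$normalize_channels)
  } else {
    Ks <- cpp_spike_cross(pa$times, pa$starts, pa$counts,
                          pb$times, pb$starts, pb$counts,
                          pa$window_length, W, spec$sigma_s,
                          spec$normalize_channels)
    Kl <- cpp_lfp_cross(pa$X, pb$X, pa$len, pa$n_channels, pa$sample_period,
                        spec$sigma_x, spec$normalize_channels)
  }
  list(spikes = Ks, lfp = Kl)
}

combine_modalities <- function(grams, rule) {
  switch(rule,
    product = grams$spikes * grams$lfp,
    sum = grams$spikes + grams$lfp,
    spikes_only = grams$spikes,
    lfp_only = grams$lfp)
}

#' Gram matrix of multiscale samples
#'
#' Batch evaluation of the joint kernel over all sample pairs. The result is
#' symmetric and positive semidefinite up to numerical tolerance.
#'
#' @param samples A list of [multiscale_sample()] objects (or a
#'   `decoding_dataset`, whose samples are used).
#' @param spec A [composite_kernel_spec()].
#' @return An `n x n` numeric matrix with the spec attached as attribute
#'   `"kernel_spec"`.
#' @export
gram_matrix <- function(samples, spec) {
  if (inherits(samples, "decoding_dataset")) samples <- samples$samples
  if (!length(samples)) abort("need at least one sample")
  pa <- pack_samples(samples)
  K <- combine_modalities(modal_grams(pa, NULL, spec), spec$modality_rule)
  attr(K, "kernel_spec") <- spec
  K
}

#' Kernel size heuristic
#'
#' Sets the Schoenberg kernel size from the spread of the training samples:
#' `sigma^2` is the mean over all unordered sample pairs of the
#' pre-exponential squared distance (the intensity-function integral for
#' spikes, the Riemann LFP integral for LFPs), averaged over units/channels.
#' Using the pre-exponential distance avoids the circularity of defining
#' `sigma` through an RKHS distance that itself depends on `sigma`.
#'
#' @param samples A list of [multiscale_sample()] objects, or bare
#'   spike/LFP windows of the requested modality, or a `decoding_dataset`.
#' @param modality `"spikes"` or `"lfp"`.
#' @param smoothing_width Intensity smoothing width in ms; defaults to the
#'   spike window length.
#' @param max_samples For long window sequences the pair mean is estimated on
#'   an evenly spaced subsample of at most this many windows (default 600,
#'   i.e. ~180k pairs), which stabilizes the estimate at a fraction of the
#'   quadratic cost; set to `Inf` for the exact all-pairs mean.
#' @return `sigma > 0`.
#' @export
kernel_size_heuristic <- function(samples, modality = c("spikes", "lfp"),
                                  smoothing_width = NULL, max_samples = 600) {
  modality <- match.arg(modality)
  if (inherits(samples, "decoding_dataset")) samples <- samples$samples
  if (length(samples) < 2L) abort("need at least two samples")
  if (is.finite(max_samples) && length(samples) > max_samples) {
    idx <- unique(round(seq(1L, length(samples), length.out = max_samples)))
    samples <- samples[idx]
  }
  first <- samples[[1L]]

  if (modality == "spikes") {
    wins <- lapply(samples, function(s) {
      if (inherits(s, "multiscale_sample")) s$spikes
      else if (inherits(s, "multiunit_spike_window")) s
      else if (inherits(s, "spike_window")) multiunit_spike_window(list(s))
      else abort("unsupported sample type")
    })
    Ts <- wins[[1L]]$window_length
    U <- n_units(wins[[1L]])
    counts <- t(vapply(wins, function(w) vapply(w$units, length, integer(1)),
                       integer(U)))
    counts <- matrix(as.integer(counts), nrow = length(wins))
    flat <- unlist(lapply(wins, function(w) unlist(w$units, use.names = FALSE)),
                   use.names = FALSE) %||% numeric(0)
    starts <- matrix(0L, length(wins), U)
    off <- 0L
    for (i in seq_len(length(wins))) for (u in seq_len(U)) {
      starts[i, u] <- off; off <- off + counts[i, u]
    }
    W <- smoothing_width %||% Ts
    s2 <- cpp_spike_mean_sqdist(as.numeric(flat), starts, counts, Ts, W)
  } else {
    mats <- lapply(samples, function(s) {
      if (inherits(s, "multiscale_sample")) s$lfp
      else if (inherits(s, "multichannel_lfp_window")) s
      else if (inherits(s, "lfp_window")) {
        multichannel_lfp_window(matrix(s$samples, ncol = 1),
                                sample_period = s$sample_period)
      } else abort("unsupported sample type")
    })
    len <- nrow(mats[[1L]]$samples)
    C <- ncol(mats[[1L]]$samples)
    V <- vapply(mats, function(m) as.vector(m$samples), numeric(len * C))
    X <- if (is.matrix(V)) t(V) else matrix(V, ncol = 1)
    s2 <- cpp_lfp_mean_sqdist(X, len, C, mats[[1L]]$sample_period)
  }
  if (s2 <= .Machine$double.eps) {
    abort("degenerate-scale: all samples are identical in this modality")
  }
  sqrt(s2)
}
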