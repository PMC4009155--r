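# Builders for random windows and samples, plus the fine-grid numerical
# oracle for the intensity-function integrals.

rand_spike_window <- function(Ts = 9, n = NULL) {
  n <- n %||% rpois(1, 2)
  # event timestamps at microsecond resolution (aligns with the 0.001 ms
  # oracle grid, which is then an exact integrator for the step functions)
  spike_window(sort(unique(round(runif(n, 0, Ts), 3))), Ts)
}

rand_sample <- function(n_units = 3, n_channels = 2, len = 20, Ts = 9,
                        tau = 1) {
  spk <- multiunit_spike_window(
    lapply(seq_len(n_units), function(u) sort(runif(rpois(1, 2), 0, Ts))),
    window_length = Ts)
  lfp <- multichannel_lfp_window(matrix(rnorm(len * n_channels), len),
                                 sample_period = tau)
  multiscale_sample(spk, lfp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rectangular-smoothing intensity on a fine midpoint grid (independent of
# the closed-form rectangle-overlap path).
grid_intensity <- function(times, Ts, W, h = 0.001) {
  tg <- seq(h / 2, Ts, by = h)
  if (!length(times)) return(numeric(length(tg)))
  rowSums(outer(tg, times, function(t, tm) t >= tm & t < tm + W)) / W
}

grid_spike_kernel <- function(a, b, sigma, W = NULL, h = 0.001) {
  W <- W %||% a$window_length
  la <- grid_intensity(a$times, a$window_length, W, h)
  lb <- grid_intensity(b$times, b$window_length, W, h)
  exp(-sum((la - lb)^2) * h / sigma^2)
}

# Single-output LFP-only model whose kernel values can be prescribed through
# plain Euclidean geometry (2-sample windows, unit sample period).
lfp_point_sample <- function(xy, Ts = 9) {
  multiscale_sample(
    multiunit_spike_window(list(numeric(0)), window_length = Ts),
    multichannel_lfp_window(matrix(xy, ncol = 1), sample_period = 1))
}

# Inverse model with prescribed kernel values: lfp-only geometry as in the
# qklms tests.
two_center_inverse <- function() {
  spec <- composite_kernel_spec(1, 1, modality_rule = "lfp_only")
  a <- sqrt(log(1 / 0.8))
  c1 <- lfp_point_sample(c(0, 0))
  p <- a / 2
  q <- sqrt(log(2) - p^2)
  c2 <- lfp_point_sample(c(p, q))
  z <- lfp_point_sample(c(a, 0))
  m <- qklms(spec, 1, learning_rate = 0.5)
  m$centers <- list(c1, c2)
  m$self_sim <- c(1, 1)
  m$coefficients <- matrix(c(1, 2), 1)
  list(model = m, x = c1, z = z)
}

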