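toy_recording <- function(duration_s = 1, spikes = NULL, n_units = 1,
                          lfp_fs = 1000, stim_fs = 200, stim = NULL) {
  n_lfp <- round(duration_s * lfp_fs)
  n_stim <- round(duration_s * stim_fs)
  recording(spikes = spikes %||% tibble::tibble(unit = integer(0),
                                                time_s = numeric(0)),
            lfp = matrix(0, n_lfp, 2), lfp_fs = lfp_fs,
            stimulus = stim %||% matrix(0, n_stim, 1), stim_fs = stim_fs,
            duration_s = duration_s, n_units = n_units)
}

test_that("sliding windows have the expected count, alignment and shift", {
  rec <- toy_recording(1, spikes = tibble::tibble(unit = 1L, time_s = 0.0115))
  ds <- slide_windows(rec, 9, 20, 5)
  expect_length(ds, floor((1000 - 20) / 5) + 1)  # 197
  expect_equal(ds$times_ms[1], 20)

  # the spike at 11.5 ms lands at 5.5 ms in the window ending at 15 ms
  ds2 <- slide_windows(rec, 9, 9, 3)
  k <- which(ds2$times_ms == 15)
  expect_equal(ds2$samples[[k]]$spikes$units[[1]], 5.5)

  # a step beyond the usable span leaves a single window
  ds3 <- slide_windows(rec, 9, 20, 2000)
  expect_length(ds3, 1L)
  expect_error(slide_windows(toy_recording(0.01), 9, 20, 5), "longer")
})

test_that("windows at step = window length tile the recording exactly", {
  set.seed(3)
  spk <- tibble::tibble(unit = sample(3, 200, TRUE),
                        time_s = runif(200, 0, 2))
  rec <- toy_recording(2, spikes = spk, n_units = 3)
  ds <- slide_windows(rec, 20, 20, 20)
  counted <- sum(vapply(ds$samples,
                        function(s) sum(lengths(s$spikes$units)), numeric(1)))
  in_span <- sum(spk$time_s > 0 & spk$time_s <= max(ds$times_ms) / 1000)
  expect_equal(counted, in_span)
})

test_that("delayed targets index the stimulus target_delay_ms earlier", {
  stim <- matrix(seq_len(200), ncol = 1)  # stimulus value = sample index
  rec <- toy_recording(1, stim = stim)
  d0 <- slide_windows(rec, 9, 20, 5)
  d20 <- slide_windows(rec, 9, 20, 5, target_delay_ms = 20)
  expect_equal(d20$targets[5, 1], d0$targets[1, 1])
})

test_that("autocorrelation matches the defining formula and stats::acf", {
  y <- rep(c(1, -1), 50)
  ac <- autocorr(y, 3)
  expect_equal(ac$acf[1], 1)
  expect_equal(ac$acf[2], -99 / 100)
  set.seed(5)
  z <- rnorm(500)
  expect_equal(autocorr(z, 10)$acf,
               drop(stats::acf(z, lag.max = 10, plot = FALSE,
                               demean = TRUE)$acf),
               tolerance = 1e-12)
  set.seed(6)
  w <- rnorm(1e4)
  expect_lt(abs(autocorr(w, 1)$acf[2]), 0.05)
  expect_error(autocorr(rep(1, 50), 3), "zero-variance")
  # a lag-5 periodic signal peaks at multiples of 5
  p <- rep(c(3, 0, 1, 0, -1), 40)
  acp <- autocorr(p, 12)$acf[-1]
  expect_equal(which(acp > 0.9), c(5L, 10L))
})

test_that("autocorrelation confidence bounds follow Bartlett's formula", {
  expect_equal(autocorr_bounds(numeric(0), 1e4, 1), c(-0.02, 0.02))
  expect_equal(autocorr_bounds(c(0.5), 100, 2),
               c(-1, 1) * 2 * sqrt(1.5 / 100), tolerance = 1e-9)
  expect_equal(autocorr_bounds(numeric(0), 4, 1), c(-1, 1))
})

test_that("window-length estimation finds where correlation dies out", {
  set.seed(10)
  wn <- rnorm(1e4)
  est <- estimate_window_length(wn, 20, 1)
  expect_lte(as.numeric(est), 3)
  expect_true(attr(est, "converged"))
  expect_equal(as.numeric(estimate_window_length(wn, 1, 1)), 1)

  set.seed(9)
  ar <- sapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.9), 1e4)))
  est2 <- estimate_window_length(ar, 50, 1)
  expect_gte(as.numeric(est2), 25)
  expect_lte(as.numeric(est2), 50)
})

test_that("NMSE has its defining values and invariances", {
  d <- c(1, -1, 2, 0)
  expect_equal(nmse(d, d), 0)
  expect_equal(nmse(rep(mean(d), 4), d), 1)
  expect_equal(nmse(c(0, 0), c(1, -1)), 1)
  y <- c(0.5, 0.2, 1.4, -0.3)
  expect_equal(nmse(y + 3, d + 3), nmse(y, d), tolerance = 1e-12)
  expect_equal(nmse(d + 2 * (y - d), d), 4 * nmse(y, d), tolerance = 1e-12)
  expect_error(nmse(c(1, 2), c(3, 3)), "constant")
})

test_that("decoders train, interpolate and stay below the mean predictor", {
  cfg <- synthetic_plant_config(seed = 99)
  dd <- make_decoding_dataset("touch", cfg, c(6, 2), seed = 31)
  model <- train_decoder(dd$train, learning_rate = 0.2, epochs = 3)
  ev <- evaluate_decoder(model, dd$test)
  expect_lt(ev$nmse[1], 1)
  # all-zero targets give an all-zero model
  z <- qklms_train(qklms(composite_kernel_spec(0.3, 1.2), 1, 0.2, 0),
                   dd$train$samples[1:30],
                   targets = matrix(0, 30, 1), epochs = 1)
  expect_true(all(z$model$coefficients == 0))
  # single-sample exact interpolation
  one <- dd$train[1]
  m1 <- qklms_train(qklms(composite_kernel_spec(0.3, 1.2), 1, 1, 0),
                    one$samples, targets = matrix(2, 1, 1), epochs = 1)
  expect_equal(predict(m1$model, one$samples[[1]]), 2, tolerance = 1e-12)
})

test_that("binned correlation scores identity, anti-alignment and independence", {
  a <- tibble::tibble(unit = 1L, time_s = (2.5 + 10 * (0:9)) / 1000)
  b <- tibble::tibble(unit = 1L, time_s = (7.5 + 10 * (0:9)) / 1000)
  expect_equal(binned_correlation(a, a, 5, duration_s = 0.1), 1)
  expect_equal(binned_correlation(a, b, 5, duration_s = 0.1), -1)
  set.seed(12)
  p1 <- tibble::tibble(unit = 1L, time_s = sort(runif(600, 0, 60)))
  p2 <- tibble::tibble(unit = 1L, time_s = sort(runif(600, 0, 60)))
  expect_lt(abs(binned_correlation(p1, p2, 5, duration_s = 60)), 0.05)
  # zero-variance counts error out
  e1 <- tibble::tibble(unit = 1L, time_s = numeric(0))
  expect_error(binned_correlation(e1, e1, 5, duration_s = 0.1, units = 1L),
               "zero-variance")
})

test_that("binned cross-correlation peaks at the imposed lag", {
  a <- tibble::tibble(unit = 1L, time_s = (2.5 + 50 * (0:30)) / 1000 + 0.2)
  b <- tibble::tibble(unit = 1L, time_s = a$time_s - 0.015)  # a lags b by 15 ms
  xc <- binned_crosscorr(a, b, 5, duration_s = 2, max_lag_bins = 6)
  expect_equal(xc$lag_ms[which.max(xc$cc)], 15)
  xc0 <- binned_crosscorr(a, a, 5, duration_s = 2, max_lag_bins = 6)
  expect_equal(xc0$lag_ms[which.max(xc0$cc)], 0)
})
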