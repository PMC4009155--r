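test_that("touch stimulus generation respects rate, width and sites", {
  empty <- generate_touch_stimulus(10, touch_rate = 0, seed = 1)
  expect_equal(nrow(empty$touches), 0L)

  st <- generate_touch_stimulus(60, 0.5, 100, 4, seed = 4)
  expect_gte(nrow(st$touches), 25)
  expect_lte(nrow(st$touches), 35)
  # non-overlap: onsets at least one width apart
  expect_true(all(diff(st$touches$time_s) >= 0.1))

  st2 <- generate_touch_stimulus(120, 0.5, 100, 2, seed = 5)
  expect_setequal(unique(st2$touches$site), 1:2)
  expect_gte(min(table(st2$touches$site)), 10)

  expect_error(generate_touch_stimulus(10, touch_rate = 20, touch_width_ms = 100),
               "config error")
})

test_that("random microstimulation has exponential ISIs over 8 sites x 3 levels", {
  ms <- generate_random_microstim(10, seed = 2)
  expect_gte(nrow(ms), 70)
  expect_lte(nrow(ms), 130)
  expect_true(all(ms$amplitude_uA %in% c(10, 20, 30)))
  expect_true(all(ms$channel %in% 1:8))

  big <- generate_random_microstim(1000, seed = 3)
  h <- table(factor(big$channel, levels = 1:8))
  n <- nrow(big)
  expect_gt(n, 9000)
  sdev <- sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(h - n / 8) <= 3 * sdev))
  # ISI mean near 100 ms
  expect_equal(mean(diff(big$time_ms)), 100, tolerance = 5)
})

test_that("the plant spikes at baseline, is noiseless when told, and replays", {
  cfg <- synthetic_plant_config(n_units = 1, baseline_rate = 5,
                                lfp_noise_sd = 0, seed = 7)
  st <- generate_touch_stimulus(10, touch_rate = 0, seed = 7)
  rec <- simulate_plant(st, cfg, seed = 7, duration_s = 10)
  expect_gte(nrow(rec$spikes), 20)
  expect_lte(nrow(rec$spikes), 80)
  expect_true(all(rec$lfp == 0))
  rec2 <- simulate_plant(st, cfg, seed = 7, duration_s = 10)
  expect_identical(rec, rec2)
})

test_that("spike counts calibrate to the integrated intensity", {
  cfg <- synthetic_plant_config(seed = 11)
  ms <- generate_random_microstim(10, seed = 11)
  for (s in 1:5) {
    rec <- simulate_plant(ms, cfg, seed = s, duration_s = 10)
    D <- neurokernel:::drive_matrix(ms, cfg, 1, 10)
    for (u in c(1L, 5L)) {
      lam <- pmax(0, cfg$baseline_rate + drop(D %*% cfg$gain[u, ]))
      expected <- sum(lam) / 1000
      got <- sum(rec$spikes$unit == u)
      expect_lt(abs(got - expected), 3 * sqrt(expected) + 1)
    }
  }
})

test_that("doubling the gain increases stimulus-locked spiking", {
  cfg1 <- synthetic_plant_config(seed = 13)
  cfg2 <- synthetic_plant_config(seed = 13, gain = 2 * cfg1$gain)
  ms <- generate_random_microstim(10, seed = 13)
  locked <- function(rec) {
    sum(vapply(ms$time_ms / 1000, function(t) {
      sum(rec$spikes$time_s > t & rec$spikes$time_s <= t + 0.03)
    }, numeric(1)))
  }
  r1 <- simulate_plant(ms, cfg1, seed = 14, duration_s = 10)
  r2 <- simulate_plant(ms, cfg2, seed = 14, duration_s = 10)
  expect_gt(locked(r2), locked(r1))
})

test_that("decoding datasets split disjointly and reproducibly", {
  cfg <- synthetic_plant_config(seed = 17)
  dd <- make_decoding_dataset("touch", cfg, c(6, 2), seed = 17)
  expect_length(dd$train, floor((6000 - 20) / 5) + 1)
  expect_length(dd$test, floor((2000 - 20) / 5) + 1)
  expect_equal(ncol(dd$train$targets), 1L)
  dd2 <- make_decoding_dataset("touch", cfg, c(6, 2), seed = 17)
  expect_identical(dd$train$targets, dd2$train$targets)
  expect_identical(dd$train$samples[[10]], dd2$train$samples[[10]])

  dm <- make_decoding_dataset("microstim", cfg, c(6, 2), seed = 18)
  expect_equal(ncol(dm$train$targets), 8L)
  amps <- unique(as.vector(dm$train$targets))
  expect_true(all(amps %in% c(0, 10, 20, 30)))
})
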