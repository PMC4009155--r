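test_that("filtered error is the inverse readout difference (hand plug-in)", {
  tc <- two_center_inverse()
  # kappa(c1,x)=1, kappa(c2,x)=0.5, kappa(c1,z)=0.8, kappa(c2,z)=0.5
  expect_equal(filtered_error(tc$model, tc$x, tc$z), 0.2, tolerance = 1e-9)
  expect_equal(filtered_error(tc$model, tc$x, tc$x), 0)
  expect_equal(filtered_error(tc$model, tc$x, tc$z),
               predict(tc$model, tc$x) - predict(tc$model, tc$z))
  empty <- qklms(composite_kernel_spec(1, 1), 1)
  expect_error(filtered_error(empty, tc$x, tc$z), "empty")
})

test_that("controller updates touch only the matched coefficient column", {
  tc <- two_center_inverse()
  ctrl <- tc$model
  ctrl$frozen <- TRUE
  same <- update_controller(ctrl, tc$x, 0)
  expect_identical(same$coefficients, ctrl$coefficients)

  upd <- update_controller(ctrl, tc$x, 0.2, learning_rate = 0.5)
  expect_equal(upd$coefficients[1, 1], 1 + 0.1, tolerance = 1e-12)
  expect_equal(upd$coefficients[1, 2], 2)
  expect_identical(n_centers(upd), 2L)

  # far-away input still updates the nearest center, size unchanged
  far <- lfp_point_sample(c(50, 50))
  upd2 <- update_controller(ctrl, far, 1)
  expect_identical(n_centers(upd2), 2L)
  expect_error(update_controller(qklms(composite_kernel_spec(1, 1), 1),
                                 tc$x, 1), "empty")
})

test_that("constraint processing reproduces the hand-worked pulse selection", {
  raw <- matrix(0, 2, 19)
  times <- 0:18
  raw[1, times == 2] <- 20
  raw[1, times == 6] <- 25
  raw[1, times == 18] <- 40
  raw[2, times == 6] <- 30
  seqo <- constrain_stimulation(raw, 1, times_ms = times)
  expect_equal(nrow(seqo), 2L)
  expect_equal(seqo$time_ms, c(6, 18))
  expect_equal(seqo$channel, c(2L, 1L))
  expect_equal(seqo$amplitude_uA, c(30, 30))  # 40 clipped to 30

  none <- constrain_stimulation(matrix(0, 3, 10), 5)
  expect_equal(nrow(none), 0L)

  weak <- constrain_stimulation(matrix(c(0, 5, 0), 1), 5)
  expect_equal(weak$amplitude_uA, 8)  # raised to the range floor
})

test_that("constrained sequences always satisfy the delivery invariants", {
  # independent checker, written out in full against the stated rules
  check <- function(seq) {
    ok <- TRUE
    for (ch in unique(seq$channel)) {
      tt <- sort(seq$time_ms[seq$channel == ch])
      if (length(tt) > 1 && any(diff(tt) < 10)) ok <- FALSE
    }
    if (anyDuplicated(seq$time_ms)) ok <- FALSE
    if (nrow(seq) && (min(seq$amplitude_uA) < 8 || max(seq$amplitude_uA) > 30)) {
      ok <- FALSE
    }
    ok
  }
  set.seed(33)
  for (i in 1:200) {
    raw <- matrix(rnorm(4 * 40, sd = 20), 4, 40)
    seqo <- constrain_stimulation(raw, 5)
    expect_true(check(seqo))
    expect_equal(nrow(validate_stimulation(seqo)), 0L)
  }
  # and the package validator flags planted violations
  bad <- stimulation_sequence(
    tibble::tibble(time_ms = c(0, 4, 4), channel = c(1L, 1L, 2L),
                   amplitude_uA = c(8, 50, 10)), 2, 100)
  v <- validate_stimulation(bad)
  expect_setequal(unique(v$type), c("min_interval", "cross_channel",
                                    "amplitude"))
})

test_that("controller initialization trains, freezes and thresholds", {
  cfg <- synthetic_plant_config(seed = 21)
  ms <- generate_random_microstim(6, seed = 21)
  rec <- simulate_plant(ms, cfg, seed = 21, duration_s = 6)
  ids <- slide_windows(rec, target_delay_ms = 20)
  init <- initialize_controller(ids, learning_rate = 0.3,
                                quantization_size = 0.7, epochs = 3)
  expect_true(init$controller$frozen)
  expect_false(init$inverse$frozen)
  expect_identical(n_centers(init$controller), n_centers(init$inverse))
  expect_length(init$controller$output_threshold, 8L)
  em <- trace_epoch_mse(attr(init$inverse, "trace"))
  expect_lt(em$mse[3], em$mse[1])

  # one-sample dataset -> one center each (explicit spec: no heuristic)
  one <- ids[1]
  init1 <- initialize_controller(one, spec = composite_kernel_spec(0.3, 1.2),
                                 learning_rate = 0.5)
  expect_identical(n_centers(init1$inverse), 1L)
  expect_identical(n_centers(init1$controller), 1L)

  # duplicated samples with zero quantization merge to distinct inputs
  dup <- ids[c(1, 1, 2, 2, 3)]
  initd <- initialize_controller(dup, spec = composite_kernel_spec(0.3, 1.2),
                                 quantization_size = 0)
  expect_identical(n_centers(initd$inverse), 3L)
})

test_that("an oracle plant yields zero filtered error from the first epoch", {
  cfg <- synthetic_plant_config(seed = 23)
  ms <- generate_random_microstim(6, seed = 23)
  rec <- simulate_plant(ms, cfg, seed = 23, duration_s = 6)
  ids <- slide_windows(rec, target_delay_ms = 20)
  init <- initialize_controller(ids, learning_rate = 0.3)
  st <- generate_touch_stimulus(3, 0.75, 100, 1, seed = 23)
  target <- simulate_plant(st, cfg, seed = 24, duration_s = 3)
  oracle <- function(seq) target
  loop <- run_control_loop(init$controller, init$inverse, oracle, target,
                           epochs = 1, update_inverse = FALSE)
  expect_lt(loop$trace$mean_abs_error[1], 1e-10)
})

test_that("open-loop mode emits a valid sequence without touching the plant", {
  cfg <- synthetic_plant_config(seed = 25)
  ms <- generate_random_microstim(6, seed = 25)
  rec <- simulate_plant(ms, cfg, seed = 25, duration_s = 6)
  ids <- slide_windows(rec, target_delay_ms = 20)
  init <- initialize_controller(ids, learning_rate = 0.3)
  st <- generate_touch_stimulus(3, 0.75, 100, 1, seed = 25)
  target <- simulate_plant(st, cfg, seed = 26, duration_s = 3)
  called <- FALSE
  tripwire <- function(seq) { called <<- TRUE; stop("plant must not be called") }
  ol <- run_control_loop(init$controller, init$inverse, tripwire, target,
                         open_loop = TRUE)
  expect_false(called)
  expect_s3_class(ol$stimulation, "stimulation_sequence")
  expect_null(ol$response)
  expect_equal(nrow(validate_stimulation(ol$stimulation)), 0L)
})

test_that("closed-loop filtered error decreases on the synthetic plant", {
  res <- run_control_experiment(301, inv_duration_s = 6,
                                target_duration_s = 4, cc_duration_s = 5,
                                epochs = 3)
  err <- res$trace$mean_abs_error
  expect_lt(err[3], err[1])
  expect_s3_class(res$stimulation, "stimulation_sequence")
  expect_equal(nrow(validate_stimulation(res$stimulation)), 0L)
})
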