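make_spec <- function() composite_kernel_spec(0.3, 1.2)

test_that("prediction is the coefficient-weighted kernel expansion", {
  spec <- make_spec()
  m <- qklms(spec, n_outputs = 1, learning_rate = 0.5)
  u <- lfp_point_sample(c(0, 0))
  expect_equal(predict(m, u), 0)

  # one center, kappa(c, u) = 1 -> coefficient passes through
  res <- qklms_update(m, u, 0.5 / 0.5)  # first update stores eta * d = 0.5
  expect_equal(predict(res$model, u), 0.5)

  # hand matrix-vector product with prescribed kernels 0.5 and 1
  spec1 <- composite_kernel_spec(1, 1, modality_rule = "lfp_only")
  c1 <- lfp_point_sample(c(0, 0))
  c2 <- lfp_point_sample(c(sqrt(log(2)), 0))
  m2 <- qklms(spec1, 1, learning_rate = 0.5)
  m2$centers <- list(c1, c2)
  m2$self_sim <- c(1, 1)
  m2$coefficients <- matrix(c(0.5, 0.875), 1)
  expect_equal(predict(m2, c2), 0.5 * 0.5 + 0.875 * 1, tolerance = 1e-9)
})

test_that("the update recursion reproduces the two-step worked example", {
  # kappa(u1, u2) = 0.5 by construction (lfp-only, unit sigma)
  spec1 <- composite_kernel_spec(1, 1, modality_rule = "lfp_only")
  u1 <- lfp_point_sample(c(0, 0))
  u2 <- lfp_point_sample(c(sqrt(log(2)), 0))
  m <- qklms(spec1, 1, learning_rate = 0.5, quantization_size = 0)

  r1 <- qklms_update(m, u1, 1)
  expect_equal(r1$error, 1)
  expect_equal(r1$model$coefficients, matrix(0.5, 1, 1))

  r2 <- qklms_update(r1$model, u2, 2)
  expect_equal(r2$error, 2 - 0.25, tolerance = 1e-9)
  expect_equal(r2$model$coefficients, matrix(c(0.5, 0.875), 1),
               tolerance = 1e-9)

  # exact repeat merges onto the existing center
  r3 <- qklms_update(r2$model, u2, 2)
  expect_equal(n_centers(r3$model), 2L)
})

test_that("with zero quantization the filter equals a naive KLMS bit for bit", {
  set.seed(7)
  spec <- make_spec()
  inputs <- lapply(1:40, function(i) rand_sample())
  targets <- rnorm(40)
  eta <- 0.3

  # naive KLMS: every input becomes a center, no quantization logic at all
  naive_centers <- list()
  naive_coef <- matrix(0, 1, 0)
  naive_pred <- numeric(40)
  for (j in 1:40) {
    kv <- vapply(naive_centers, function(ci) joint_kernel(ci, inputs[[j]], spec),
                 numeric(1))
    naive_pred[j] <- if (length(kv)) drop(naive_coef %*% kv) else 0
    e <- targets[j] - naive_pred[j]
    naive_centers[[length(naive_centers) + 1L]] <- inputs[[j]]
    naive_coef <- cbind(naive_coef, eta * e)
  }

  m <- qklms(spec, 1, learning_rate = eta, quantization_size = 0)
  preds <- numeric(40)
  for (j in 1:40) {
    preds[j] <- predict(m, inputs[[j]])
    m <- qklms_update(m, inputs[[j]], targets[j])$model
  }
  expect_identical(preds, naive_pred)
  expect_identical(m$coefficients, naive_coef)
  expect_identical(n_centers(m), 40L)
})

test_that("duplicated inputs merge: dictionary size equals distinct inputs", {
  set.seed(9)
  spec <- make_spec()
  base <- lapply(1:8, function(i) rand_sample())
  inputs <- base[c(1:8, sample(8, 12, replace = TRUE))]
  m <- qklms(spec, 1, learning_rate = 0.2, quantization_size = 0)
  fit <- qklms_train(m, inputs, targets = rnorm(length(inputs)),
                     epochs = 1, engine = "online")
  expect_identical(n_centers(fit$model), 8L)
  # monotone, bounded dictionary growth
  expect_true(all(diff(fit$trace$dictionary_size) >= 0))
  expect_true(all(fit$trace$dictionary_size <= fit$trace$step))
})

test_that("online and gram engines produce the same model", {
  set.seed(13)
  spec <- make_spec()
  inputs <- lapply(1:30, function(i) rand_sample())
  targets <- cbind(rnorm(30), rnorm(30))
  m1 <- qklms_train(qklms(spec, 2, 0.2, 0), inputs, targets, epochs = 2,
                    engine = "online")
  m2 <- qklms_train(qklms(spec, 2, 0.2, 0), inputs, targets, epochs = 2,
                    engine = "gram")
  expect_equal(m1$model$coefficients, m2$model$coefficients,
               tolerance = 1e-12)
  expect_equal(as.matrix(m1$trace$error), as.matrix(m2$trace$error),
               tolerance = 1e-12)
  expect_identical(n_centers(m1$model), n_centers(m2$model))
  # and under nonzero quantization too
  m3 <- qklms_train(qklms(spec, 2, 0.2, 0.8), inputs, targets, epochs = 2,
                    engine = "online")
  m4 <- qklms_train(qklms(spec, 2, 0.2, 0.8), inputs, targets, epochs = 2,
                    engine = "gram")
  expect_equal(m3$model$coefficients, m4$model$coefficients,
               tolerance = 1e-12)
  expect_identical(n_centers(m3$model), n_centers(m4$model))
})

test_that("training converges on a kernel-generated target", {
  set.seed(17)
  spec <- make_spec()
  inputs <- lapply(1:60, function(i) rand_sample())
  cstar <- inputs[[1]]
  y <- vapply(inputs, function(u) 2 * joint_kernel(cstar, u, spec), numeric(1))
  fit <- qklms_train(qklms(spec, 1, 0.2, 0), inputs, y, epochs = 5)
  em <- trace_epoch_mse(fit$trace)
  expect_lt(em$mse[5], em$mse[1])
  # one-sample exact interpolation at eta 1
  one <- qklms_train(qklms(spec, 1, 1, 0), inputs[1], y[1], epochs = 1)
  expect_equal(predict(one$model, inputs[[1]]), y[1], tolerance = 1e-12)
})

test_that("per-epoch training MSE is non-increasing for stable step sizes", {
  set.seed(19)
  spec <- make_spec()
  ok <- 0L
  for (r in 1:20) {
    inputs <- lapply(1:40, function(i) rand_sample())
    cstar <- inputs[[sample(40, 1)]]
    y <- vapply(inputs, function(u) joint_kernel(cstar, u, spec), numeric(1)) +
      rnorm(40, 0, 0.05)
    fit <- qklms_train(qklms(spec, 1, 0.2, 0), inputs, y, epochs = 3)
    em <- trace_epoch_mse(fit$trace)
    if (all(diff(em$mse) <= 1e-12)) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("tidy and glance summarize the fitted filter", {
  set.seed(23)
  spec <- make_spec()
  inputs <- lapply(1:5, function(i) rand_sample())
  fit <- qklms_train(qklms(spec, 2, 0.2, 0), inputs,
                     cbind(rnorm(5), rnorm(5)), epochs = 1,
                     engine = "online")
  td <- tidy(fit$model)
  expect_equal(nrow(td), 2L * n_centers(fit$model))
  expect_named(td, c("center", "output", "coefficient"))
  gl <- glance(fit$model)
  expect_equal(gl$n_centers, n_centers(fit$model))
  expect_equal(gl$modality_rule, "product")
  expect_s3_class(autoplot(fit$trace), "ggplot")
})
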