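test_that("intensity estimation matches the hand-derived piecewise form", {
  # no spikes -> zero intensity everywhere
  e0 <- estimate_intensity(spike_window(numeric(0), 9), 9)
  expect_equal(e0$intensity, 0)
  expect_equal(c(e0$start, e0$end), c(0, 9))

  e1 <- estimate_intensity(spike_window(2, 9), 9)
  expect_equal(e1$intensity[e1$start >= 2], 1 / 9)
  expect_equal(e1$intensity[e1$end <= 2], 0)

  e2 <- estimate_intensity(spike_window(c(2, 3), 9), 9)
  expect_equal(e2$start, c(0, 2, 3))
  expect_equal(e2$intensity, c(0, 1 / 9, 2 / 9))

  # cross-check each piece against the fine-grid construction
  g <- grid_intensity(c(2, 3), 9, 9)
  tg <- seq(0.0005, 9, by = 0.001)
  for (i in seq_len(nrow(e2))) {
    sel <- tg >= e2$start[i] & tg < e2$end[i]
    expect_equal(unique(g[sel]), e2$intensity[i], tolerance = 1e-12)
  }
})

test_that("spike kernel reproduces the closed-form worked example", {
  spec <- composite_kernel_spec(sigma_s = sqrt(1 / 27), sigma_x = 1,
                                smoothing_width = 9)
  a <- spike_window(2, 9)
  b <- spike_window(5, 9)
  expect_equal(spike_kernel(a, b, spec), exp(-1), tolerance = 1e-9)
  expect_equal(spike_kernel(a, a, spec), 1)
  expect_equal(spike_kernel(spike_window(numeric(0), 9),
                            spike_window(numeric(0), 9), spec), 1)
  expect_error(spike_kernel(a, spike_window(1, 12), spec), "window-mismatch")
})

test_that("spike kernel agrees with the grid-integration oracle", {
  set.seed(11)
  spec <- composite_kernel_spec(sigma_s = 0.2, sigma_x = 1)
  for (i in 1:100) {
    a <- rand_spike_window()
    b <- rand_spike_window()
    k <- spike_kernel(a, b, spec)
    ko <- grid_spike_kernel(a, b, 0.2)
    expect_lt(abs(k - ko) / ko, 1e-6)
  }
})

test_that("direct-sum spike kernel pools units as specified", {
  spec_n <- composite_kernel_spec(sqrt(1 / 27), 1, smoothing_width = 9)
  spec_u <- composite_kernel_spec(sqrt(1 / 27), 1, smoothing_width = 9,
                                  normalize_channels = FALSE)
  a <- multiunit_spike_window(list(c(1, 4), c(2)), window_length = 9)
  b <- multiunit_spike_window(list(c(1, 4), c(5)), window_length = 9)
  expect_equal(multiunit_spike_kernel(a, b, spec_u), 1 + exp(-1),
               tolerance = 1e-9)
  expect_equal(multiunit_spike_kernel(a, b, spec_n), (1 + exp(-1)) / 2,
               tolerance = 1e-9)
  id3 <- multiunit_spike_window(list(1, 2, 3), window_length = 9)
  expect_equal(multiunit_spike_kernel(id3, id3, spec_n), 1)
  expect_error(multiunit_spike_kernel(a, id3, spec_n), "unit-count")
})

test_that("LFP kernel uses the Riemann-sum squared distance", {
  spec2 <- composite_kernel_spec(1, sqrt(2))
  a <- lfp_window(c(1, 1), 1)
  b <- lfp_window(c(0, 0), 1)
  expect_equal(lfp_kernel(a, b, spec2), exp(-1), tolerance = 1e-12)
  spec1 <- composite_kernel_spec(1, 1)
  expect_equal(lfp_kernel(lfp_window(c(1, 0), 1), lfp_window(c(0, 1), 1),
                          spec1), exp(-2), tolerance = 1e-12)
  expect_equal(lfp_kernel(a, a, spec2), 1)
  expect_error(lfp_kernel(a, lfp_window(1:3, 1), spec2), "shape mismatch")

  mc_u <- composite_kernel_spec(1, sqrt(2), normalize_channels = FALSE)
  mc_n <- composite_kernel_spec(1, sqrt(2))
  A <- multichannel_lfp_window(cbind(c(1, 1), c(1, 1)), sample_period = 1)
  B <- multichannel_lfp_window(cbind(c(0, 0), c(0, 0)), sample_period = 1)
  expect_equal(multichannel_lfp_kernel(A, B, mc_u), 2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(multichannel_lfp_kernel(A, B, mc_n), exp(-1),
               tolerance = 1e-12)
})

test_that("joint kernel follows the modality rule and is strict for products", {
  set.seed(21)
  a <- rand_sample()
  b <- rand_sample()
  for (rule in c("product", "sum", "spikes_only", "lfp_only")) {
    spec <- composite_kernel_spec(0.2, 1, modality_rule = rule)
    ks <- multiunit_spike_kernel(a$spikes, b$spikes, spec)
    kl <- multichannel_lfp_kernel(a$lfp, b$lfp, spec)
    expected <- switch(rule, product = ks * kl, sum = ks + kl,
                       spikes_only = ks, lfp_only = kl)
    expect_identical(joint_kernel(a, b, spec), expected)
    expect_equal(joint_kernel(a, b, spec), joint_kernel(b, a, spec))
  }
  spec <- composite_kernel_spec(0.2, 1, modality_rule = "product")
  expect_equal(joint_kernel(a, a, spec), 1, tolerance = 1e-12)

  # strict similarity: a vanishing LFP factor kills the product
  far <- a
  far$lfp$samples <- a$lfp$samples + 100
  kl <- multichannel_lfp_kernel(a$lfp, far$lfp, spec)
  expect_lt(kl, 1e-8)
  expect_lt(joint_kernel(a, far, spec), 1e-8)
})

test_that("RKHS distance handles the identity, orthogonal and plug-in cases", {
  expect_equal(rkhs_distance(1, 1, 1), 0)
  expect_equal(rkhs_distance(1, 1, 0), sqrt(2))
  expect_equal(rkhs_distance(2, 2, 1.367879), sqrt(1.264242),
               tolerance = 1e-6)
  # round-off clipping
  expect_equal(rkhs_distance(1, 1, 1 + 1e-16), 0)
  # normalized shortcut
  set.seed(5)
  spec <- composite_kernel_spec(0.2, 1)
  a <- rand_sample(); b <- rand_sample()
  k <- joint_kernel(a, b, spec)
  expect_equal(rkhs_distance(1, 1, k), sqrt(2 - 2 * k), tolerance = 1e-12)
})

test_that("kernel symmetry and unit self-similarity hold for random inputs", {
  set.seed(31)
  spec <- composite_kernel_spec(0.3, 1.2)
  for (i in 1:20) {
    a <- rand_sample(); b <- rand_sample()
    expect_equal(joint_kernel(a, b, spec), joint_kernel(b, a, spec),
                 tolerance = 1e-12)
    expect_equal(joint_kernel(a, a, spec), 1, tolerance = 1e-12)
  }
})

test_that("Gram matrices are symmetric, unit-diagonal and PSD", {
  set.seed(41)
  ss <- lapply(1:20, function(i) rand_sample())
  for (rule in c("product", "sum", "spikes_only", "lfp_only")) {
    spec <- composite_kernel_spec(0.3, 1.2, modality_rule = rule)
    K <- gram_matrix(ss, spec)
    expect_true(isSymmetric(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  spec <- composite_kernel_spec(0.3, 1.2)
  K2 <- gram_matrix(list(ss[[1]], ss[[1]]), spec)
  expect_equal(K2, matrix(1, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  K1 <- gram_matrix(ss[1], spec)
  expect_equal(dim(K1), c(1L, 1L))
  expect_equal(K1[1, 1], 1, tolerance = 1e-12)
})

test_that("Gram matrix agrees with pairwise R kernel evaluations", {
  set.seed(43)
  ss <- lapply(1:6, function(i) rand_sample())
  spec <- composite_kernel_spec(0.3, 1.2, modality_rule = "product")
  K <- gram_matrix(ss, spec)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(K[i, j], joint_kernel(ss[[i]], ss[[j]], spec),
                 tolerance = 1e-12)
  }
})

test_that("kernel size heuristic recovers prescribed pair distances", {
  # one pair with squared distance 4 -> sigma 2
  w1 <- lfp_window(c(0, 0), 1)
  w2 <- lfp_window(c(2, 0), 1)
  expect_equal(kernel_size_heuristic(list(w1, w2), "lfp"), 2)
  # pairwise squared distances {1, 1, 4} -> sigma sqrt(2)
  pts <- list(lfp_window(0, 1), lfp_window(1, 1), lfp_window(2, 1))
  expect_equal(kernel_size_heuristic(pts, "lfp"), sqrt(2))
  expect_error(kernel_size_heuristic(list(w1, w1), "lfp"), "degenerate")
  # spikes modality on bare windows
  s1 <- spike_window(2, 9); s2 <- spike_window(5, 9)
  expect_equal(kernel_size_heuristic(list(s1, s2), "spikes"),
               sqrt(1 / 27), tolerance = 1e-9)
})

test_that("kernel spec serializes to JSON and back", {
  spec <- composite_kernel_spec(0.25, 1.5, smoothing_width = 9,
                                normalize_channels = FALSE,
                                modality_rule = "sum")
  path <- tempfile(fileext = ".json")
  write_kernel_spec(spec, path)
  spec2 <- read_kernel_spec(path)
  expect_equal(spec2, spec)
})
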