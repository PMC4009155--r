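#' Compare single-modality and tensor-product decoders
#'
#' Runs the full synthetic touch-decoding protocol for one seed: generate a
#' plant, simulate disjoint train (20 s) and test (2.5 s) recordings, set the
#' kernel sizes from the training windows, train a Q-KLMS decoder per
#' modality rule (shared kernel matrices, identical presentation order), and
#' report the held-out NMSE of each. This is the synthetic counterpart of
#' comparing a spike decoder, an LFP decoder and the joint spike-and-LFP
#' decoder on one recording session.
#'
#' @param seed Master seed for the trial.
#' @param cfg Optional [synthetic_plant_config()]; defaults to a fresh plant
#'   drawn from `seed`.
#' @param durations_s Train/test durations in seconds.
#' @param rules Modality rules to compare.
#' @param learning_rate,epochs Decoder settings (quantization size 0).
#' @param touch_rate Touch rate per second.
#' @return A tibble with columns `rule`, `nmse`, `n_train`, `n_test`,
#'   `sigma_s`, `sigma_x`.
#' @export
compare_decoders <- function(seed, cfg = NULL, durations_s = c(20, 2.5),
                             rules = c("product", "spikes_only", "lfp_only"),
                             learning_rate = 0.2, epochs = 3,
                             touch_rate = 0.5) {
  cfg <- cfg %||% synthetic_plant_config(seed = substream_seed(seed, "plant_cfg"))
  dd <- make_decoding_dataset("touch", cfg, durations_s, seed = seed,
                              touch_rate = touch_rate)
  tr <- dd$train
  te <- dd$test
  sigma_s <- kernel_size_heuristic(tr, "spikes")
  sigma_x <- kernel_size_heuristic(tr, "lfp")
  spec0 <- composite_kernel_spec(sigma_s, sigma_x)
  ptr <- pack_samples(tr$samples)
  pte <- pack_samples(te$samples)
  g_tr <- modal_grams(ptr, NULL, spec0)
  g_te <- modal_grams(ptr, pte, spec0)
  targets <- as.matrix(tr$targets)

  purrr::map_dfr(rules, function(rule) {
    K <- combine_modalities(g_tr, rule)
    fit <- qklms_gram_fit(K, targets, learning_rate, 0, epochs)
    Kte <- combine_modalities(g_te, rule)[fit$dict, , drop = FALSE]
    pred <- t(fit$coef %*% Kte)
    tibble::tibble(rule = rule, nmse = nmse(pred, te$targets),
                   n_train = length(tr), n_test = length(te),
                   sigma_s = sigma_s, sigma_x = sigma_x)
  })
}

# Unit-averaged Pearson correlation of 5 ms-binned counts in post-onset
# windows, concatenated across touches; x and y may be aligned to different
# onset lists (truncated to the common touch count).
onset_binned_cc <- function(spikes_x, spikes_y, onsets_x_s, onsets_y_s,
                            units, win_ms = 300, bin_ms = 5) {
  n_t <- min(length(onsets_x_s), length(onsets_y_s))
  if (n_t == 0L) abort("no touches to compare")
  nb <- round(win_ms / bin_ms)
  counts_for <- function(spk, onsets) {
    lapply(units, function(u) {
      tt <- spk$time_s[spk$unit == u] * 1000
      unlist(lapply(onsets[seq_len(n_t)] * 1000, function(o) {
        rel <- tt[tt > o & tt <= o + win_ms] - o
        tabulate(ceiling(rel / bin_ms), nbins = nb)
      }), use.names = FALSE)
    })
  }
  cx <- counts_for(spikes_x, onsets_x_s)
  cy <- counts_for(spikes_y, onsets_y_s)
  ccs <- vapply(seq_along(units), function(i) {
    if (sd(cx[[i]]) == 0 || sd(cy[[i]]) == 0) return(NA_real_)
    stats::cor(cx[[i]], cy[[i]])
  }, numeric(1))
  mean(ccs, na.rm = TRUE)
}

#' Run one control trial on the synthetic plant
#'
#' Full "virtual touch" experiment for one seed, mirroring the open-loop
#' adaptive inverse control protocol: pretrain the inverse model on the
#' response to randomly patterned microstimulation, freeze the controller
#' dictionary, adapt the controller coefficients in a closed filtered-error
#' loop against a touch-site class A target (this yields the error
#' trajectory), and separately feed a longer class-A target sequence through
#' the controller in open loop, deliver the constrained microstimulation
#' once, and evaluate the evoked "virtual touch" response.
#'
#' `cc_matched` is the unit-averaged binned (5 ms) correlation between the
#' controlled response and the class-A target response in 300 ms post-onset
#' windows; `cc_unmatched` compares the same controlled response against a
#' class-B target (touches at the other site, with its own onset times);
#' `peak_lag_ms` is the lag at which the full-series binned cross-correlation
#' with the matched target peaks (0 for a time-locked response); `improved`
#' reports whether the mean absolute filtered error fell from the first to
#' the last closed-loop epoch.
#'
#' @param seed Master seed.
#' @param cfg Optional plant config (fresh plant from `seed` by default).
#' @param inv_duration_s Random-microstimulation pretraining duration.
#' @param target_duration_s Duration of the closed-loop adaptation target.
#' @param cc_duration_s Duration of the open-loop virtual-touch targets used
#'   for the correlation evaluation.
#' @param epochs Closed-loop control epochs.
#' @param touch_rate Touch rate of the targets, per second.
#' @param learning_rate_init,learning_rate_ctrl,learning_rate_inv Step sizes.
#' @param quantization_size Control-model quantization radius.
#' @return A list: `trace`, `cc_matched`, `cc_unmatched`, `peak_lag_ms`,
#'   `improved`, `stimulation` (the delivered open-loop sequence),
#'   `response` (its evoked recording), `target` (class-A CC target).
#' @export
run_control_experiment <- function(seed, cfg = NULL, inv_duration_s = 8,
                                   target_duration_s = 5, cc_duration_s = 10,
                                   epochs = 5, touch_rate = 0.75,
                                   learning_rate_init = 0.3,
                                   learning_rate_ctrl = 0.05,
                                   learning_rate_inv = 0.05,
                                   quantization_size = 0.7) {
  cfg <- cfg %||% synthetic_plant_config(seed = substream_seed(seed, "plant_cfg"))

  mstim <- generate_random_microstim(inv_duration_s,
                                     seed = substream_seed(seed, "invstim"),
                                     n_channels = cfg$n_stim_channels)
  mrec <- simulate_plant(mstim, cfg, seed = substream_seed(seed, "invrec"),
                         duration_s = inv_duration_s)
  # inverse-model windows carry the modeling delay (a causal response window
  # is paired with the pulse it contains the response to) and the target is
  # held over the evoked-burst duration so readouts stay on the uA scale
  ids <- slide_windows(mrec, target_delay_ms = 20)
  ids$targets <- rolling_max_rows(ids$targets, 4L)
  init <- initialize_controller(ids, learning_rate = learning_rate_init,
                                quantization_size = quantization_size)

  # two touch-site classes: same plant, touches at site 1 vs site 2
  class_target <- function(site, label, dur) {
    st <- generate_touch_stimulus(dur, touch_rate, touch_width_ms = 100,
                                  n_sites = 1,
                                  seed = substream_seed(seed, label))
    st$n_sites <- 2L
    st$touches$site <- rep(site, nrow(st$touches))
    simulate_plant(st, cfg, seed = substream_seed(seed, paste0(label, "_rec")),
                   duration_s = dur)
  }

  # closed-loop adaptation: filtered-error trajectory
  rec_loop <- class_target(1L, "loop_target", target_duration_s)
  plant <- make_plant(cfg, substream_seed(seed, "plant_run"),
                      duration_s = target_duration_s)
  loop <- run_control_loop(init$controller, init$inverse, plant, rec_loop,
                           epochs = epochs,
                           learning_rate_ctrl = learning_rate_ctrl,
                           learning_rate_inv = learning_rate_inv)

  # open-loop virtual-touch delivery and evaluation
  rec_a <- class_target(1L, "targetA", cc_duration_s)
  rec_b <- class_target(2L, "targetB", cc_duration_s)
  ol <- run_control_loop(init$controller, init$inverse, NULL, rec_a,
                         open_loop = TRUE)
  zrec <- simulate_plant(ol$stimulation, cfg,
                         seed = substream_seed(seed, "deliver"),
                         duration_s = cc_duration_s)

  units <- seq_len(cfg$n_units)
  onsets_a <- rec_a$meta$touches$time_s
  onsets_b <- rec_b$meta$touches$time_s
  cc_matched <- onset_binned_cc(zrec$spikes, rec_a$spikes,
                                onsets_a, onsets_a, units)
  cc_unmatched <- onset_binned_cc(zrec$spikes, rec_b$spikes,
                                  onsets_a, onsets_b, units)
  xc <- binned_crosscorr(zrec$spikes, rec_a$spikes, bin_ms = 5,
                         duration_s = cc_duration_s, max_lag_bins = 10,
                         units = units)
  peak_lag_ms <- xc$lag_ms[which.max(xc$cc)]
  err <- loop$trace$mean_abs_error
  list(trace = loop$trace,
       cc_matched = cc_matched,
       cc_unmatched = cc_unmatched,
       peak_lag_ms = peak_lag_ms,
       improved = err[length(err)] < err[1L],
       stimulation = ol$stimulation,
       response = zrec,
       target = rec_a)
}
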