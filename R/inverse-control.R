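#' Filtered error for adaptive inverse control
#'
#' The overall system error is the RKHS difference between the (delayed)
#' target neural state and the achieved plant output; filtering it through
#' the inverse plant model gives, per stimulation channel,
#' `eps_j = W_j phi(x_delayed) - W_j phi(z)`, i.e. exactly the difference of
#' the inverse model's readouts of the two states.
#'
#' @param inv The inverse plant model (a trained [qklms()]).
#' @param x_delayed Delayed target [multiscale_sample()], aligned with `z`.
#' @param z Achieved plant output sample.
#' @return Numeric error vector of length `n_outputs`.
#' @export
filtered_error <- function(inv, x_delayed, z) {
  stopifnot(inherits(inv, "qklms"))
  if (n_centers(inv) == 0L) abort("empty inverse model")
  predict(inv, x_delayed) - predict(inv, z)
}

#' Update the controller with a filtered error
#'
#' The controller's dictionary is fixed after initialization; only the
#' coefficient matrix adapts. The input is quantized onto the nearest
#' dictionary center (in the intended use, targets repeat exactly and always
#' match a center; for inputs beyond
#' the quantization radius the nearest center is still used) and that
#' center's coefficient column is incremented by `eta * eps`.
#'
#' @param ctrl Controller [qklms()] model (non-empty).
#' @param x Command-input [multiscale_sample()].
#' @param eps Filtered-error vector of length `n_outputs`.
#' @param learning_rate Step size; defaults to the model's.
#' @return The updated controller; dictionary size unchanged.
#' @export
update_controller <- function(ctrl, x, eps, learning_rate = NULL) {
  stopifnot(inherits(ctrl, "qklms"))
  if (n_centers(ctrl) == 0L) abort("empty controller")
  eps <- as.numeric(eps)
  stopifnot(length(eps) == ctrl$n_outputs)
  eta <- learning_rate %||% ctrl$learning_rate
  if (all(eps == 0)) return(ctrl)
  kv <- kernel_vector(ctrl, x)
  self_x <- joint_kernel(x, x, ctrl$kernel_spec)
  dist <- rkhs_distance(self_x, ctrl$self_sim, kv)
  i <- which.min(dist)
  ctrl$coefficients[, i] <- ctrl$coefficients[, i] + eta * eps
  ctrl
}

#' Constrain a raw stimulation matrix to a deliverable pulse sequence
#'
#' Turns the controller's dense per-channel amplitude output into bipolar
#' microstimulation pulses satisfying the delivery restrictions:
#' per channel, candidate pulses are the positive local amplitude maxima with
#' at least `min_interval_ms` separation (greedy non-maximum suppression,
#' descending by amplitude); at each surviving time point only the channel
#' with the largest amplitude keeps its pulse (ties to the lowest channel
#' index); amplitudes are then clipped into `amp_range` (sub-minimum
#' survivors are raised to the range floor, non-positive candidates are
#' discarded).
#'
#' @param raw Numeric matrix, channels by time points.
#' @param sample_period_ms Spacing of the time grid in ms.
#' @param times_ms Optional explicit times of the columns (default
#'   `0, sample_period_ms, ...`).
#' @param min_interval_ms Minimal per-channel inter-pulse interval (default
#'   10 ms).
#' @param amp_range Deliverable amplitude range in uA (default `c(8, 30)`).
#' @param duration_ms Sequence duration; defaults to the last grid time.
#' @return A [stimulation_sequence()] satisfying all delivery invariants.
#' @export
constrain_stimulation <- function(raw, sample_period_ms, times_ms = NULL,
                                  min_interval_ms = 10, amp_range = c(8, 30),
                                  duration_ms = NULL) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) abort("raw amplitudes must be finite")
  M <- nrow(raw); K <- ncol(raw)
  times_ms <- times_ms %||% ((seq_len(K) - 1L) * sample_period_ms)
  stopifnot(length(times_ms) == K)
  duration_ms <- duration_ms %||% max(times_ms, 0)

  kept <- vector("list", M)
  for (ch in seq_len(M)) {
    amps <- raw[ch, ]
    cand <- which(amps > 0)
    if (!length(cand)) {
      kept[[ch]] <- tibble::tibble(time_ms = numeric(0), channel = integer(0),
                                   amplitude_uA = numeric(0))
      next
    }
    ord <- cand[order(-amps[cand], times_ms[cand])]
    kt <- numeric(0)
    ka <- numeric(0)
    for (i in ord) {
      ti <- times_ms[i]
      if (!length(kt) || all(abs(kt - ti) >= min_interval_ms)) {
        kt <- c(kt, ti)
        ka <- c(ka, amps[i])
      }
    }
    kept[[ch]] <- tibble::tibble(time_ms = kt, channel = ch,
                                 amplitude_uA = ka)
  }
  pulses <- dplyr::bind_rows(kept)
  if (nrow(pulses)) {
    # cross-channel exclusivity at grid resolution: keep the max amplitude,
    # ties to the lowest channel index
    pulses <- pulses |>
      dplyr::arrange(.data$time_ms, dplyr::desc(.data$amplitude_uA),
                     .data$channel) |>
      dplyr::distinct(.data$time_ms, .keep_all = TRUE)
    pulses$amplitude_uA <- pmin(pmax(pulses$amplitude_uA, amp_range[1L]),
                                amp_range[2L])
  }
  stimulation_sequence(pulses, n_channels = M, duration_ms = duration_ms)
}

#' Audit a stimulation sequence against the delivery constraints
#'
#' Independent checker for the deliverable-form invariants: per-channel
#' inter-pulse intervals of at least `min_interval_ms`, at most one channel
#' pulsing at any time point, and amplitudes inside `amp_range`.
#'
#' @param seq A [stimulation_sequence()].
#' @param min_interval_ms,amp_range Constraint parameters.
#' @return A tibble of violations (columns `type`, `channel`, `time_ms`);
#'   zero rows means the sequence is deliverable.
#' @export
validate_stimulation <- function(seq, min_interval_ms = 10,
                                 amp_range = c(8, 30)) {
  stopifnot(inherits(seq, "stimulation_sequence"))
  v <- list()
  if (nrow(seq)) {
    for (ch in sort(unique(seq$channel))) {
      tt <- sort(seq$time_ms[seq$channel == ch])
      bad <- which(diff(tt) < min_interval_ms)
      if (length(bad)) {
        v[[length(v) + 1L]] <- tibble::tibble(
          type = "min_interval", channel = ch, time_ms = tt[bad + 1L])
      }
    }
    dup <- seq$time_ms[duplicated(seq$time_ms)]
    if (length(dup)) {
      v[[length(v) + 1L]] <- tibble::tibble(
        type = "cross_channel", channel = NA_integer_, time_ms = unique(dup))
    }
    bad_amp <- seq$amplitude_uA < amp_range[1L] | seq$amplitude_uA > amp_range[2L]
    if (any(bad_amp)) {
      v[[length(v) + 1L]] <- tibble::tibble(
        type = "amplitude", channel = seq$channel[bad_amp],
        time_ms = seq$time_ms[bad_amp])
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(type = character(0), channel = integer(0),
                   time_ms = numeric(0))
  }
}

#' Initialize the inverse model and controller
#'
#' Trains the inverse plant model by supervised Q-KLMS on windows of the
#' neural response to randomly patterned microstimulation (inputs: plant
#' output windows; targets: delivered per-channel amplitudes). The controller
#' starts as a copy of the inverse model with its dictionary frozen:
#' afterwards only its coefficient matrix adapts.
#'
#' @param dataset A `decoding_dataset` mapping plant responses to known
#'   stimulation amplitudes.
#' @param spec Kernel spec; built from the data when `NULL` (tensor-product
#'   rule, heuristic kernel sizes).
#' @param learning_rate Q-KLMS step size.
#' @param quantization_size Quantization radius (RKHS distance units;
#'   normalized kernel distances lie in `[0, sqrt(2)]`); repeats and
#'   near-repeats merge so the controller network stays fixed.
#' @param epochs Training passes.
#' @return A list with `inverse` and `controller` (both [qklms()] models);
#'   the controller additionally carries `output_threshold`, its per-channel
#'   pulse-emission noise floor.
#' @export
initialize_controller <- function(dataset, spec = NULL, learning_rate = 0.2,
                                  quantization_size = 0.7, epochs = 3) {
  stopifnot(inherits(dataset, "decoding_dataset"))
  if (length(dataset$samples) == 0L) abort("empty dataset")
  if (is.null(spec)) {
    spec <- composite_kernel_spec(
      sigma_s = kernel_size_heuristic(dataset, "spikes"),
      sigma_x = kernel_size_heuristic(dataset, "lfp"),
      modality_rule = "product")
  }
  model <- qklms(spec, n_outputs = ncol(dataset$targets),
                 learning_rate = learning_rate,
                 quantization_size = quantization_size)
  fit <- qklms_train(model, dataset, epochs = epochs)
  inverse <- fit$model
  attr(inverse, "trace") <- fit$trace
  controller <- fit$model
  controller$frozen <- TRUE
  # pulse-emission threshold: the inverse decoder's noise floor per channel,
  # taken as a high quantile of its readout on zero-amplitude training
  # windows; controller outputs below it are not delivered
  pred <- predict(inverse, dataset)
  controller$output_threshold <- vapply(seq_len(ncol(pred)), function(ch) {
    zero <- dataset$targets[, ch] == 0
    if (!any(zero)) return(0)
    stats::quantile(pred[zero, ch], 0.95, names = FALSE)
  }, numeric(1))
  list(inverse = inverse, controller = controller)
}

# Kernel vector of one packed sample against a packed center set.
packed_kernel_vector <- function(pc, pu, spec) {
  drop(combine_modalities(modal_grams(pc, pu, spec), spec$modality_rule))
}

#' Run the adaptive inverse control loop
#'
#' Cascade of controller and plant. Each epoch the target neural recording is
#' windowed and fed through the controller; the raw multichannel amplitude
#' output is constrained to a deliverable pulse sequence; the plant responds;
#' the inverse model is updated online on (response window, delivered
#' amplitudes); and the controller coefficients are updated with the filtered
#' error between the inverse model's readout of the delayed target and of the
#' achieved response. In open-loop mode the constrained sequence is emitted
#' after a single controller pass with no plant call and no updates.
#'
#' @param controller,inverse Models from [initialize_controller()].
#' @param plant A callable `function(stimulation_sequence) -> recording`
#'   (see [make_plant()]), or `NULL` for open loop.
#' @param target Target [recording()] to reproduce.
#' @param delay_ms Modeling delay; defaults to `max(T_s, T_x)` so the
#'   controller input window covers the plant response it anticipates.
#' @param delivery_lead_ms Look-ahead applied when scheduling the
#'   controller's output for delivery; defaults to `delay_ms + step_ms`
#'   (the modeling delay plus one step for the evoked-burst rise), which
#'   time-locks the achieved response to the target at lag 0.
#' @param epochs Control epochs (ignored in open loop).
#' @param learning_rate_ctrl,learning_rate_inv Adaptation step sizes.
#' @param spike_window_ms,lfp_window_ms,step_ms Windowing parameters.
#' @param update_inverse Keep adapting the inverse model online (default
#'   `TRUE`).
#' @param target_hold_ms Response-integration window for the inverse-model
#'   target: a window is credited with the largest amplitude delivered
#'   within the trailing `target_hold_ms` before its delayed reference time
#'   (default 15 ms, matching the evoked burst duration). Zero restores the
#'   single-bin sparse target.
#' @param open_loop Emit the constrained stimulation without plant calls.
#' @return A list with `stimulation` (last constrained sequence), `response`
#'   (last plant recording, `NULL` in open loop), `trace` (tibble: `epoch`,
#'   `mean_abs_error`, `n_pulses`, `inverse_centers`), and the final
#'   `controller` and `inverse` models.
#' @export
run_control_loop <- function(controller, inverse, plant, target,
                             delay_ms = NULL, delivery_lead_ms = NULL, epochs = 5,
                             learning_rate_ctrl = 0.1,
                             learning_rate_inv = 0.1,
                             spike_window_ms = 9, lfp_window_ms = 20,
                             step_ms = 5, update_inverse = TRUE,
                             target_hold_ms = 15,
                             open_loop = is.null(plant)) {
  stopifnot(inherits(controller, "qklms"), inherits(inverse, "qklms"),
            inherits(target, "recording"))
  if (n_centers(controller) == 0L || n_centers(inverse) == 0L) {
    abort("controller and inverse model must be initialized")
  }
  spec <- controller$kernel_spec
  tds <- slide_windows(target, spike_window_ms, lfp_window_ms, step_ms)
  xs <- tds$samples
  K <- length(xs)
  times <- tds$times_ms
  delay_ms <- delay_ms %||% max(spike_window_ms, lfp_window_ms)
  dsteps <- max(1L, round(delay_ms / step_ms))
  delivery_lead_ms <- delivery_lead_ms %||% (delay_ms + step_ms)
  lead_steps <- max(dsteps, round(delivery_lead_ms / step_ms))
  if (lead_steps >= K) abort("delay longer than the target recording")

  px <- pack_samples(xs)
  pctrl <- pack_samples(controller$centers)
  Kcx <- combine_modalities(modal_grams(pctrl, px, spec), spec$modality_rule)
  self_x <- joint_kernel(xs[[1L]], xs[[1L]], spec)  # constant across samples
  # nearest controller center for each target window (frozen dictionary)
  nearest_ctrl <- apply(self_x + controller$self_sim - 2 * Kcx, 2, which.min)
  # the controller, as a plant inverse, maps the target window ending at t
  # to the stimulation that causes it, delivered delivery_lead_ms earlier
  # (look-ahead), which keeps the achieved response time-locked to the
  # target at lag 0
  deliver_idx <- seq_len(K - lead_steps)       # delivery time indices
  source_idx <- deliver_idx + lead_steps       # controller input window
  attr_shift <- lead_steps - dsteps            # ctrl attribution offset
  hold_steps <- max(1L, round(target_hold_ms / step_ms) + 1L)
  M <- controller$n_outputs
  thr <- controller$output_threshold %||% numeric(M)

  # growing inverse dictionary state (packed per epoch inside the loop);
  # Kinvx caches kernel rows center-vs-target-window with spare capacity so
  # appends do not copy the whole matrix
  inv_coef <- inverse$coefficients
  inv_centers <- inverse$centers
  inv_self <- inverse$self_sim
  Kinvx <- combine_modalities(
    modal_grams(pack_samples(inv_centers), px, spec), spec$modality_rule)
  Kinvx <- rbind(Kinvx, matrix(0, 256L, K))
  n_kinvx <- length(inv_centers)

  trace <- vector("list", epochs)
  seq_out <- NULL
  zrec <- NULL

  for (ep in seq_len(epochs)) {
    raw <- controller$coefficients %*% Kcx - thr  # M x K, output for window k
    raw_delivered <- raw[, source_idx, drop = FALSE]
    seq_out <- constrain_stimulation(raw_delivered, step_ms,
                                     times_ms = times[deliver_idx],
                                     duration_ms = target$duration_s * 1000)
    if (open_loop) {
      return(list(stimulation = seq_out, response = NULL, trace = NULL,
                  controller = controller, inverse = inverse))
    }
    zrec <- plant(seq_out)
    zds <- slide_windows(zrec, spike_window_ms, lfp_window_ms, step_ms)
    zs <- zds$samples
    if (length(zs) != K) abort("plant returned a recording of different span")

    delivered <- matrix(0, K, M)
    if (nrow(seq_out)) {
      pos <- match(as.integer(round(seq_out$time_ms / step_ms)),
                   as.integer(round(times / step_ms)))
      ok <- !is.na(pos)
      delivered[cbind(pos[ok], seq_out$channel[ok])] <-
        seq_out$amplitude_uA[ok]
    }
    # the inverse model reads window z_k as an estimate of the stimulation
    # driving it: the amplitude delivered within the response-integration
    # window ending delay_ms before the window's right edge
    inv_targets <- rbind(matrix(0, dsteps, M),
                         rolling_max_rows(delivered, hold_steps)[
                           seq_len(K - dsteps), , drop = FALSE])

    pz <- pack_samples(zs)
    # kernels of this epoch's response windows against centers existing at
    # epoch start come from one batch cross-Gram; centers appended within
    # the epoch (pending) are evaluated incrementally. Kinvx caches kernel
    # rows center-vs-target-window; only rows of new centers are computed.
    pinv_main <- pack_samples(inv_centers)
    Kmain_z <- combine_modalities(modal_grams(pinv_main, pz, spec),
                                  spec$modality_rule)
    ppend <- NULL
    abs_err <- 0
    n_err <- 0L
    eps_sum <- matrix(0, M, n_centers(controller))
    eps_n <- integer(n_centers(controller))
    for (k in seq_len(K)) {
      kv <- Kmain_z[, k]
      if (!is.null(ppend)) {
        kv <- c(kv, packed_kernel_vector(ppend, pack_slice(pz, k), spec))
      }
      Ncur <- length(inv_centers)
      pred_z <- drop(inv_coef[, seq_len(Ncur), drop = FALSE] %*% kv)
      # filtered error at this window: inverse readout of the target state
      # minus readout of the achieved state (command input already carried
      # the modeling delay at delivery)
      if (k > dsteps) {
        pred_x <- drop(inv_coef[, seq_len(Ncur), drop = FALSE] %*%
                         Kinvx[seq_len(Ncur), k, drop = TRUE])
        eps_k <- pred_x - pred_z
        i_c <- nearest_ctrl[min(k + attr_shift, K)]
        eps_sum[, i_c] <- eps_sum[, i_c] + eps_k
        eps_n[i_c] <- eps_n[i_c] + 1L
        abs_err <- abs_err + sum(abs(eps_k))
        n_err <- n_err + 1L
      }
      if (update_inverse) {
        e <- inv_targets[k, ] - pred_z
        d2 <- self_x + inv_self - 2 * kv
        i <- which.min(d2)
        if (sqrt(max(0, d2[i])) <= inverse$quantization_size) {
          inv_coef[, i] <- inv_coef[, i] + learning_rate_inv * e
        } else {
          p1 <- pack_slice(pz, k)
          inv_centers[[Ncur + 1L]] <- zs[[k]]
          inv_self <- c(inv_self, self_x)
          if (Ncur + 1L > ncol(inv_coef)) {  # grow capacity geometrically
            inv_coef <- cbind(inv_coef,
                              matrix(0, M, max(64L, ncol(inv_coef))))
          }
          inv_coef[, Ncur + 1L] <- learning_rate_inv * e
          ppend <- pack_append(ppend, p1)
          n_kinvx <- n_kinvx + 1L
          if (n_kinvx > nrow(Kinvx)) {
            Kinvx <- rbind(Kinvx, matrix(0, nrow(Kinvx), K))
          }
          Kinvx[n_kinvx, ] <- combine_modalities(
            modal_grams(p1, px, spec), spec$modality_rule)
        }
      }
    }
    inv_coef <- inv_coef[, seq_len(length(inv_centers)), drop = FALSE]
    # normalized controller update: each matched center moves by the mean
    # filtered error of the windows quantized onto it this epoch, keeping
    # the effective step size independent of how many windows share a center
    upd <- which(eps_n > 0L)
    if (length(upd)) {
      controller$coefficients[, upd] <- controller$coefficients[, upd] +
        learning_rate_ctrl *
        sweep(eps_sum[, upd, drop = FALSE], 2, eps_n[upd], "/")
    }
    trace[[ep]] <- tibble::tibble(epoch = ep,
                                  mean_abs_error = abs_err / (n_err * M),
                                  n_pulses = nrow(seq_out),
                                  inverse_centers = length(inv_centers))
  }

  inverse$centers <- inv_centers
  inverse$self_sim <- inv_self
  inverse$coefficients <- inv_coef
  list(stimulation = seq_out, response = zrec,
       trace = dplyr::bind_rows(trace),
       controller = controller, inverse = inverse)
}

#' Wrap the synthetic plant as a control-loop callable
#'
#' Returns a `function(stimulation_sequence) -> recording` that simulates the
#' plant for `duration_s`; each call uses a fresh seed substream so repeated
#' epochs see new spiking/noise realizations while remaining reproducible
#' from the master seed.
#'
#' @param cfg A [synthetic_plant_config()].
#' @param seed Master seed.
#' @param duration_s Simulated duration per call.
#' @return A closure suitable for [run_control_loop()]'s `plant` argument.
#' @export
make_plant <- function(cfg, seed, duration_s) {
  counter <- 0L
  function(seq) {
    counter <<- counter + 1L
    simulate_plant(seq, cfg, seed = substream_seed(seed, paste0("call_", counter)),
                   duration_s = duration_s)
  }
}
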