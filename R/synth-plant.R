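#' Synthetic neural plant configuration
#'
#' Generative parameters for the stimulus-to-neural-response simulator that
#' stands in for a thalamocortical (VPL -> S1) preparation: stimulus-driven
#' inhomogeneous-Poisson multiunit spiking and LFPs formed by convolving the
#' stimulus drive with damped-sinusoid response kernels plus Gaussian noise.
#'
#' Unspecified matrices are drawn deterministically from `seed`.
#' Thalamic microstimulation recruits the cortical population broadly --
#' every unit responds to every stimulation channel, with one or two
#' preferred units per channel responding strongest (synchronized bursting
#' with a spatial gradient). The touch gain (derived per site count at
#' simulation time) is likewise broad with a somatotopic gradient. LFP
#' response kernels are damped sinusoids with per-channel frequency 20-40 Hz
#' and decay 8-15 ms, matching a ~20 ms field-potential correlation time.
#'
#' @param n_units Number of spiking units.
#' @param n_lfp_channels Number of LFP channels.
#' @param n_stim_channels Number of microstimulation channels M.
#' @param baseline_rate Baseline firing rate, spikes/s per unit.
#' @param stim_gain_rate Peak stimulus-driven extra rate (spikes/s) for a
#'   strongly coupled unit at full drive (30 uA or full touch pressure).
#' @param gain Optional `n_units x n_stim_channels` microstimulation gain
#'   matrix (spikes/s per unit drive).
#' @param lfp_gain Optional `n_lfp_channels x n_stim_channels` LFP coupling
#'   matrix.
#' @param lfp_impulse Optional tibble with columns `amplitude`, `freq_hz`,
#'   `decay_ms`, one row per LFP channel.
#' @param latency_ms Optional per-unit spike response latency (ms).
#' @param spike_response_width_ms Width of the smooth per-pulse rate bump
#'   (ms); default 25, the duration of the burst a thalamic pulse evokes in
#'   cortex under anesthesia.
#' @param phasic_weight For touch drives, the fraction of the spike drive
#'   taken from the rectified positive envelope derivative (onset
#'   transients) rather than the sustained envelope; cortical touch
#'   responses are largely phasic and onset-dominated, so the default
#'   emphasizes onsets (0.6). LFPs always follow the sustained envelope.
#' @param lfp_noise_sd Gaussian noise SD added to each LFP sample.
#' @param lfp_latency_jitter_ms SD (ms) of the per-stimulus latency jitter of
#'   the evoked LFP deflection. Evoked field potentials wander by several ms
#'   from trial to trial, which blurs sub-window timing in the LFP while the
#'   spike volley stays precise; default 10 ms.
#' @param drive_scale Scale mapping a pulse amplitude in uA to unit drive
#'   (default 1/30, so a 30 uA pulse gives full drive).
#' @param seed Seed used for all derived parameters.
#' @return An object of class `synthetic_plant_config`.
#' @export
synthetic_plant_config <- function(n_units = 10, n_lfp_channels = 4,
                                   n_stim_channels = 8, baseline_rate = 5,
                                   stim_gain_rate = 120,
                                   gain = NULL, lfp_gain = NULL,
                                   lfp_impulse = NULL, latency_ms = NULL,
                                   spike_response_width_ms = 25,
                                   phasic_weight = 0.6,
                                   lfp_noise_sd = 0.4,
                                   lfp_latency_jitter_ms = 10,
                                   drive_scale = 1 / 30,
                                   seed = 1) {
  stopifnot(n_units >= 1, n_lfp_channels >= 1, n_stim_channels >= 1,
            baseline_rate >= 0, spike_response_width_ms > 0,
            lfp_noise_sd >= 0)
  seed <- as.integer(seed)
  if (is.null(gain)) {
    gain <- withr::with_seed(substream_seed(seed, "gain"), {
      g <- matrix(runif(n_units * n_stim_channels, 0.1, 0.3) * stim_gain_rate,
                  n_units, n_stim_channels)
      for (j in seq_len(n_stim_channels)) {
        u <- ((j - 1L) %% n_units) + 1L
        g[u, j] <- stim_gain_rate * runif(1, 0.9, 1.2)
        u2 <- (u %% n_units) + 1L
        g[u2, j] <- 0.75 * stim_gain_rate * runif(1, 0.9, 1.2)
      }
      g
    })
  }
  if (is.null(lfp_gain)) {
    lfp_gain <- withr::with_seed(substream_seed(seed, "lfp_gain"), {
      matrix(runif(n_lfp_channels * n_stim_channels, 0.5, 1.5),
             n_lfp_channels, n_stim_channels)
    })
  }
  if (is.null(lfp_impulse)) {
    lfp_impulse <- withr::with_seed(substream_seed(seed, "lfp_impulse"), {
      tibble::tibble(amplitude = 1,
                     freq_hz = runif(n_lfp_channels, 20, 40),
                     decay_ms = runif(n_lfp_channels, 8, 15))
    })
  }
  if (is.null(latency_ms)) {
    latency_ms <- withr::with_seed(substream_seed(seed, "latency"), {
      runif(n_units, 3, 8)
    })
  }
  structure(list(n_units = n_units, n_lfp_channels = n_lfp_channels,
                 n_stim_channels = n_stim_channels,
                 baseline_rate = baseline_rate,
                 stim_gain_rate = stim_gain_rate,
                 gain = gain, lfp_gain = lfp_gain, lfp_impulse = lfp_impulse,
                 latency_ms = latency_ms,
                 spike_response_width_ms = spike_response_width_ms,
                 phasic_weight = phasic_weight,
                 lfp_noise_sd = lfp_noise_sd,
                 lfp_latency_jitter_ms = lfp_latency_jitter_ms,
                 drive_scale = drive_scale,
                 seed = seed),
            class = "synthetic_plant_config")
}

# Touch gain: receptive-field selectivity with surround -- a contiguous
# block of units responds strongly to its preferred site, all other units
# respond weakly (anesthetized S1 keeps some broad recruitment). Derived
# deterministically from the config seed.
touch_gain <- function(cfg, n_sites) {
  withr::with_seed(substream_seed(cfg$seed, paste0("touch_gain_", n_sites)), {
    g <- matrix(runif(cfg$n_units * n_sites, 0.05, 0.2) * cfg$stim_gain_rate,
                cfg$n_units, n_sites)
    block <- ceiling(cfg$n_units / n_sites)
    for (s in seq_len(n_sites)) {
      lo <- (s - 1L) * block + 1L
      hi <- min(cfg$n_units, s * block)
      if (lo > hi) next  # more sites than unit blocks
      g[lo:hi, s] <- cfg$stim_gain_rate * runif(hi - lo + 1L, 0.9, 1.2)
    }
    g
  })
}

touch_lfp_gain <- function(cfg, n_sites) {
  withr::with_seed(substream_seed(cfg$seed, paste0("touch_lfp_gain_", n_sites)), {
    matrix(runif(cfg$n_lfp_channels * n_sites, 0.5, 1.5),
           cfg$n_lfp_channels, n_sites)
  })
}

#' Generate a touch-like stimulus
#'
#' Non-overlapping smooth (raised-cosine) pressure pulses of the stated width
#' at Poisson-thinned onset times, each assigned uniformly to one of
#' `n_sites` touch sites.
#'
#' @param duration_s Duration in seconds.
#' @param touch_rate Mean touch rate per second.
#' @param touch_width_ms Pulse width in ms (default 100, a short touch).
#' @param n_sites Number of touch sites (default 4, one per digit pad).
#' @param seed Seed.
#' @return An object of class `touch_stimulus`: a list with `touches`
#'   (tibble `time_s`, `site`), `duration_s`, `width_ms`, `n_sites`.
#' @export
generate_touch_stimulus <- function(duration_s, touch_rate = 0.5,
                                    touch_width_ms = 100, n_sites = 4,
                                    seed = 1) {
  assert_scalar_pos(duration_s, "duration_s")
  stopifnot(touch_rate >= 0, n_sites >= 1)
  if (touch_rate > 0 && touch_width_ms / 1000 >= 1 / touch_rate) {
    abort("config error: touch width >= mean inter-touch interval")
  }
  onsets <- numeric(0)
  sites <- integer(0)
  if (touch_rate > 0) {
    withr::with_seed(substream_seed(seed, "touch_onsets"), {
      t <- 0
      last <- -Inf
      while (TRUE) {
        t <- t + rexp(1, touch_rate)
        if (t + touch_width_ms / 1000 > duration_s) break
        if (t - last >= touch_width_ms / 1000) {
          onsets <- c(onsets, t)
          last <- t
        }
      }
      sites <- sample.int(n_sites, length(onsets), replace = TRUE)
    })
  }
  structure(list(touches = tibble::tibble(time_s = onsets, site = sites),
                 duration_s = duration_s, width_ms = touch_width_ms,
                 n_sites = n_sites),
            class = "touch_stimulus")
}

#' Stimulation sequence
#'
#' Per-channel microstimulation pulses: a tibble with columns `time_ms`,
#' `channel` and `amplitude_uA`, sorted by time, plus channel count and
#' duration attributes. The constrained deliverable form additionally
#' satisfies the delivery invariants checked by [validate_stimulation()].
#'
#' @param pulses Tibble/data frame with columns `time_ms`, `channel`,
#'   `amplitude_uA`.
#' @param n_channels Number of stimulation channels.
#' @param duration_ms Sequence duration in ms.
#' @return An object of class `stimulation_sequence` (a tibble).
#' @export
stimulation_sequence <- function(pulses, n_channels, duration_ms) {
  pulses <- tibble::as_tibble(pulses)
  stopifnot(all(c("time_ms", "channel", "amplitude_uA") %in% names(pulses)))
  pulses <- dplyr::arrange(pulses, .data$time_ms, .data$channel)
  if (nrow(pulses) && (min(pulses$time_ms) < 0 ||
                       max(pulses$time_ms) > duration_ms)) {
    abort("pulse times must lie within [0, duration_ms]")
  }
  if (nrow(pulses) && (any(pulses$channel < 1) ||
                       any(pulses$channel > n_channels))) {
    abort("channel indices out of range")
  }
  structure(pulses, n_channels = as.integer(n_channels),
            duration_ms = duration_ms,
            class = c("stimulation_sequence", class(pulses)))
}

#' Generate randomly patterned microstimulation
#'
#' Pulse times with exponentially distributed inter-stimulus intervals (mean
#' 100 ms); each pulse lands on one of `n_channels` sites chosen uniformly
#' with an amplitude drawn uniformly from `amplitudes` (10/20/30 uA), i.e.
#' the random 8-site x 3-amplitude stimulation protocol.
#'
#' @param duration_s Duration in seconds.
#' @param seed Seed.
#' @param mean_isi_ms Mean inter-stimulus interval in ms.
#' @param amplitudes Amplitude levels in uA.
#' @param n_channels Number of stimulation sites.
#' @return A [stimulation_sequence()].
#' @export
generate_random_microstim <- function(duration_s, seed = 1, mean_isi_ms = 100,
                                      amplitudes = c(10, 20, 30),
                                      n_channels = 8) {
  assert_scalar_pos(duration_s, "duration_s")
  withr::with_seed(substream_seed(seed, "microstim"), {
    dur_ms <- duration_s * 1000
    t <- cumsum(rexp(ceiling(4 * dur_ms / mean_isi_ms) + 20, 1 / mean_isi_ms))
    while (length(t) && t[length(t)] < dur_ms) {
      t <- c(t, t[length(t)] + rexp(1, 1 / mean_isi_ms))
    }
    t <- t[t <= dur_ms]
    pulses <- tibble::tibble(
      time_ms = t,
      channel = sample.int(n_channels, length(t), replace = TRUE),
      amplitude_uA = sample(amplitudes, length(t), replace = TRUE))
    stimulation_sequence(pulses, n_channels, dur_ms)
  })
}

raised_cosine <- function(width_ms, dt_ms) {
  n <- max(1L, round(width_ms / dt_ms))
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 0.5) / n))
}

causal_filter <- function(x, k) {
  # causal FIR convolution: y_t = sum_s k_s x_{t-s+1}
  out <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  out[seq_along(x) + length(k) - 1L][seq_along(x)]
}

# Drive matrix on the 1 ms simulation grid: one column per stimulus channel,
# peak ~1 at full amplitude.
drive_matrix <- function(stim, cfg, dt_ms, duration_s) {
  nt <- round(duration_s * 1000 / dt_ms)
  if (inherits(stim, "touch_stimulus")) {
    D <- matrix(0, nt, stim$n_sites)
    bump <- raised_cosine(stim$width_ms, dt_ms)
    for (i in seq_len(nrow(stim$touches))) {
      i0 <- round(stim$touches$time_s[i] * 1000 / dt_ms)
      idx <- i0 + seq_along(bump)
      ok <- idx >= 1 & idx <= nt
      D[idx[ok], stim$touches$site[i]] <-
        D[idx[ok], stim$touches$site[i]] + bump[ok]
    }
  } else if (inherits(stim, "stimulation_sequence")) {
    M <- attr(stim, "n_channels")
    D <- matrix(0, nt, M)
    bump <- raised_cosine(cfg$spike_response_width_ms, dt_ms)
    for (i in seq_len(nrow(stim))) {
      i0 <- round(stim$time_ms[i] / dt_ms)
      a <- stim$amplitude_uA[i] * cfg$drive_scale
      idx <- i0 + seq_along(bump)
      ok <- idx >= 1 & idx <= nt
      D[idx[ok], stim$channel[i]] <- D[idx[ok], stim$channel[i]] + a * bump[ok]
    }
  } else {
    abort("invalid stimulus type")
  }
  D
}

# Lewis-Shedler thinning of an inhomogeneous Poisson process whose intensity
# is piecewise constant on the dt grid (rates in spikes/s).
thin_poisson <- function(rate, dt_ms, duration_s) {
  lmax <- max(rate)
  if (lmax <= 0) return(numeric(0))
  n_hom <- rpois(1, lmax * duration_s)
  if (n_hom == 0) return(numeric(0))
  tt <- sort(runif(n_hom, 0, duration_s))
  idx <- pmin(pmax(ceiling(tt * 1000 / dt_ms), 1L), length(rate))
  keep <- runif(n_hom) < rate[idx] / lmax
  tt[keep]
}

#' Simulate the synthetic neural plant
#'
#' Drives the plant with a touch stimulus or a microstimulation sequence and
#' returns the evoked multiscale recording. Unit `n` fires as an
#' inhomogeneous Poisson process (generated by thinning) with rate
#' `baseline + sum_j gain[n, j] drive_j(t - latency_n)`; LFP channel `c` is
#' the drive convolved with that channel's damped-sinusoid response kernel
#' plus Gaussian noise. Deterministic given `seed`.
#'
#' @param stim A [generate_touch_stimulus()] result or a
#'   [stimulation_sequence()].
#' @param cfg A [synthetic_plant_config()].
#' @param seed Seed for the plant-run randomness (spikes, noise); independent
#'   of the config seed that fixes gains.
#' @param duration_s Simulated duration; defaults to the stimulus duration.
#' @param stim_fs Sampling rate (Hz) of the stimulus trace stored in the
#'   recording (default 200, i.e. 5 ms discretization).
#' @return A [recording()]. For a touch stimulus, its `stimulus` matrix holds
#'   one envelope channel per site and `meta$touches` the onset table; for
#'   microstimulation it holds per-channel sparse amplitude series (uA).
#' @export
simulate_plant <- function(stim, cfg, seed = 1, duration_s = NULL,
                           stim_fs = 200) {
  stopifnot(inherits(cfg, "synthetic_plant_config"))
  dt_ms <- 1
  duration_s <- duration_s %||%
    (if (inherits(stim, "touch_stimulus")) stim$duration_s
     else attr(stim, "duration_ms") / 1000)
  nt <- round(duration_s * 1000 / dt_ms)
  D <- drive_matrix(stim, cfg, dt_ms, duration_s)
  is_touch <- inherits(stim, "touch_stimulus")
  # LFP drive: same stimulus with per-event latency jitter (evoked field
  # potentials are temporally sloppier than the afferent spike volley)
  D_lfp <- D
  if (cfg$lfp_latency_jitter_ms > 0) {
    jit_stim <- withr::with_seed(substream_seed(seed, "lfp_jitter"), {
      if (is_touch) {
        st <- stim
        st$touches$time_s <- pmax(0, st$touches$time_s +
                                    rnorm(nrow(st$touches), 0,
                                          cfg$lfp_latency_jitter_ms / 1000))
        st
      } else {
        st <- stim
        st$time_ms <- pmax(0, st$time_ms +
                             rnorm(nrow(st), 0, cfg$lfp_latency_jitter_ms))
        st
      }
    })
    D_lfp <- drive_matrix(jit_stim, cfg, dt_ms, duration_s)
  }
  # spike drive: for touches, mix the sustained envelope with its rectified
  # positive derivative (onset-dominated phasic response, as in RA-type
  # cutaneous pathways); microstimulation bumps are already transient
  D_spk <- D
  if (is_touch && cfg$phasic_weight > 0 && nrow(D) > 1L) {
    ph <- apply(D, 2, function(x) pmax(0, c(0, diff(x))))
    if (max(ph) > 0) ph <- ph / max(ph)
    D_spk <- (1 - cfg$phasic_weight) * D + cfg$phasic_weight * ph
  }
  G <- if (is_touch) touch_gain(cfg, ncol(D)) else cfg$gain
  Wl <- if (is_touch) touch_lfp_gain(cfg, ncol(D)) else cfg$lfp_gain
  if (ncol(D) != ncol(G)) abort("invalid config: gain/stimulus channel mismatch")

  # spikes
  spikes <- vector("list", cfg$n_units)
  for (u in seq_len(cfg$n_units)) {
    shift <- round(cfg$latency_ms[u] / dt_ms)
    drv <- rbind(matrix(0, shift, ncol(D_spk)), D_spk)[seq_len(nt), , drop = FALSE]
    rate <- pmax(0, cfg$baseline_rate + drop(drv %*% G[u, ]))
    tt <- withr::with_seed(substream_seed(seed, paste0("spikes_", u)),
                           thin_poisson(rate, dt_ms, duration_s))
    spikes[[u]] <- tibble::tibble(unit = u, time_s = tt)
  }
  spikes <- dplyr::arrange(dplyr::bind_rows(spikes), .data$time_s)

  # LFPs at 1 kHz
  lfp <- matrix(0, nt, cfg$n_lfp_channels)
  for (c in seq_len(cfg$n_lfp_channels)) {
    imp <- cfg$lfp_impulse[c, ]
    tgrid <- seq(0, 6 * imp$decay_ms, by = dt_ms)
    h <- imp$amplitude * exp(-tgrid / imp$decay_ms) *
      sin(2 * pi * imp$freq_hz * tgrid / 1000)
    resp <- numeric(nt)
    for (j in seq_len(ncol(D_lfp))) {
      resp <- resp + Wl[c, j] * causal_filter(D_lfp[, j], h)
    }
    noise <- withr::with_seed(substream_seed(seed, paste0("lfp_noise_", c)),
                              rnorm(nt, 0, cfg$lfp_noise_sd))
    lfp[, c] <- resp + noise
  }

  # stimulus trace at stim_fs
  step <- round(1000 / stim_fs / dt_ms)
  stim_idx <- seq(step, nt, by = step)
  if (is_touch) {
    stim_mat <- D[stim_idx, , drop = FALSE]
    meta <- list(kind = "touch", touches = stim$touches,
                 touch_width_ms = stim$width_ms)
  } else {
    M <- attr(stim, "n_channels")
    stim_mat <- matrix(0, length(stim_idx), M)
    if (nrow(stim)) {
      si <- pmin(pmax(round(stim$time_ms / (step * dt_ms)), 1L),
                 length(stim_idx))
      for (i in seq_len(nrow(stim))) {
        stim_mat[si[i], stim$channel[i]] <- stim$amplitude_uA[i]
      }
    }
    meta <- list(kind = "microstim")
  }
  recording(spikes = spikes, lfp = lfp, lfp_fs = 1000 / dt_ms,
            stimulus = stim_mat, stim_fs = stim_fs, duration_s = duration_s,
            n_units = cfg$n_units, meta = meta)
}

#' Build train/test decoding datasets from the synthetic plant
#'
#' Generates a stimulus of the requested kind, simulates the plant, and
#' windows the result with the decoding defaults (9 ms spike windows, 20 ms
#' LFP windows, 5 ms step). Train and test segments are simulated as
#' independent recordings (separate seed substreams), so the split is
#' disjoint by construction.
#'
#' For `kind = "touch"` the target is the single-channel overall touch
#' envelope (sum over sites); for `kind = "microstim"` the targets are the
#' 8-channel sparse amplitude series.
#'
#' @param kind `"touch"` or `"microstim"`.
#' @param cfg A [synthetic_plant_config()].
#' @param durations_s Numeric `c(train, test)` in seconds (default 20, 2.5).
#' @param seed Master seed.
#' @param touch_rate,touch_width_ms,n_sites Touch stimulus settings; a
#'   decoding trial touches a single site (one digit pad per trial, driving
#'   the whole recorded population), so `n_sites` defaults to 1.
#' @return A list with `train` and `test` `decoding_dataset`s.
#' @export
make_decoding_dataset <- function(kind = c("touch", "microstim"), cfg,
                                  durations_s = c(20, 2.5), seed = 1,
                                  touch_rate = 0.5, touch_width_ms = 100,
                                  n_sites = 1) {
  kind <- match.arg(kind)
  stopifnot(length(durations_s) == 2L, all(durations_s > 0))
  make_one <- function(dur, label) {
    s <- substream_seed(seed, label)
    stim <- if (kind == "touch") {
      # a stimulus segment must contain at least one touch to define a
      # non-constant decoding target; redraw short empty segments
      st <- generate_touch_stimulus(dur, touch_rate, touch_width_ms, n_sites,
                                    seed = s)
      tries <- 0L
      while (nrow(st$touches) == 0L && tries < 20L) {
        tries <- tries + 1L
        st <- generate_touch_stimulus(dur, touch_rate, touch_width_ms,
                                      n_sites,
                                      seed = substream_seed(s, paste0("redraw_", tries)))
      }
      st
    } else {
      generate_random_microstim(dur, seed = s,
                                n_channels = cfg$n_stim_channels)
    }
    rec <- simulate_plant(stim, cfg, seed = s, duration_s = dur)
    if (kind == "touch") {
      # decoded target: normalized first derivative of the overall touch
      # force envelope (the deliverable "desired stimulation" signal), whose
      # fast deflections are where spike timing complements the LFP envelope
      env <- rowSums(rec$stimulus)
      dv <- c(0, diff(env))
      if (max(abs(dv)) > 0) dv <- dv / max(abs(dv))
      rec$stimulus <- matrix(dv, ncol = 1)
    }
    slide_windows(rec)
  }
  list(train = make_one(durations_s[1L], "train"),
       test = make_one(durations_s[2L], "test"))
}
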