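#' Write or read a recording directory
#'
#' A recording is stored as four plain-text files: `spikes.csv`
#' (`unit,time_s`), `lfp.csv` (wide matrix, header = channel names),
#' `stimulus.csv` (`time_s` plus one column per channel), and `meta.json`
#' (sampling rates, duration, unit count). Times are written in seconds with
#' nine decimal places, so a round trip preserves them to 1e-9 s.
#'
#' @param rec A [recording()].
#' @param dir Directory (created if needed).
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns a [recording()]. Malformed rows are rejected with their line
#'   numbers.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spk <- rec$spikes
  spk$time_s <- sprintf("%.9f", spk$time_s)
  readr::write_csv(spk, file.path(dir, "spikes.csv"))
  lfp <- as.data.frame(rec$lfp)
  names(lfp) <- paste0("ch", seq_len(ncol(rec$lfp)))
  readr::write_csv(lfp, file.path(dir, "lfp.csv"))
  stim <- as.data.frame(rec$stimulus)
  names(stim) <- paste0("ch", seq_len(ncol(rec$stimulus)))
  stim <- cbind(time_s = sprintf("%.9f", seq_len(nrow(stim)) / rec$stim_fs),
                stim)
  readr::write_csv(stim, file.path(dir, "stimulus.csv"))
  jsonlite::write_json(list(lfp_fs_hz = rec$lfp_fs, stim_fs_hz = rec$stim_fs,
                            duration_s = rec$duration_s,
                            n_units = rec$n_units),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  need <- c("spikes.csv", "lfp.csv", "stimulus.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    abort(paste("missing file(s):", paste(missing, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  spikes <- readr::read_csv(file.path(dir, "spikes.csv"),
                            col_types = readr::cols(
                              unit = readr::col_integer(),
                              time_s = readr::col_double()))
  bad <- which(is.na(spikes$time_s) | spikes$time_s < 0 | is.na(spikes$unit))
  if (length(bad)) {
    abort(sprintf("spikes.csv: invalid row(s) at line %s",
                  paste(bad + 1L, collapse = ", ")))
  }
  lfp <- as.matrix(readr::read_csv(file.path(dir, "lfp.csv"),
                                   col_types = readr::cols(.default = readr::col_double())))
  if (anyNA(lfp)) {
    abort(sprintf("lfp.csv: non-numeric or ragged row(s) at line %s",
                  paste(unique(which(rowSums(is.na(lfp)) > 0)) + 1L,
                        collapse = ", ")))
  }
  stim_raw <- readr::read_csv(file.path(dir, "stimulus.csv"),
                              col_types = readr::cols(.default = readr::col_double()))
  tcol <- stim_raw$time_s
  if (is.unsorted(tcol)) abort("stimulus.csv: non-monotone time base")
  stim <- as.matrix(stim_raw[setdiff(names(stim_raw), "time_s")])
  recording(spikes = spikes, lfp = lfp, lfp_fs = meta$lfp_fs_hz,
            stimulus = stim, stim_fs = meta$stim_fs_hz,
            duration_s = meta$duration_s, n_units = meta$n_units)
}

#' Write or read a stimulation sequence CSV
#'
#' Columns `time_s`, `channel`, `amplitude_uA`, sorted by time. The reader
#' validates the delivery invariants with [validate_stimulation()] and
#' reports any violating lines.
#'
#' @param seq A [stimulation_sequence()].
#' @param path CSV path.
#' @param n_channels,duration_ms Sequence attributes for the reader (taken
#'   from the file when `NULL`: max channel, last pulse time).
#' @param validate Check the delivery constraints on read (default `TRUE`).
#' @return The sequence (reader) or `path` invisibly (writer).
#' @export
write_stimulation <- function(seq, path) {
  stopifnot(inherits(seq, "stimulation_sequence"))
  out <- tibble::tibble(time_s = sprintf("%.9f", seq$time_ms / 1000),
                        channel = seq$channel,
                        amplitude_uA = seq$amplitude_uA)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stimulation
#' @export
read_stimulation <- function(path, n_channels = NULL, duration_ms = NULL,
                             validate = TRUE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), channel = readr::col_integer(),
    amplitude_uA = readr::col_double()))
  bad <- which(is.na(df$time_s) | df$time_s < 0 | is.na(df$channel) |
                 df$channel < 1 | is.na(df$amplitude_uA))
  if (length(bad)) {
    abort(sprintf("%s: invalid row(s) at line %s", basename(path),
                  paste(bad + 1L, collapse = ", ")))
  }
  seq <- stimulation_sequence(
    tibble::tibble(time_ms = df$time_s * 1000, channel = df$channel,
                   amplitude_uA = df$amplitude_uA),
    n_channels = n_channels %||% max(df$channel, 1L),
    duration_ms = duration_ms %||% (if (nrow(df)) max(df$time_s) * 1000 else 0))
  if (validate) {
    v <- validate_stimulation(seq)
    if (nrow(v)) {
      lines <- vapply(v$time_ms, function(t) {
        which(abs(df$time_s * 1000 - t) < 1e-6)[1L] + 1L
      }, numeric(1))
      abort(sprintf("%s: constraint violation(s) [%s] at line %s",
                    basename(path), paste(unique(v$type), collapse = ", "),
                    paste(stats::na.omit(lines), collapse = ", ")))
    }
  }
  seq
}

#' Persist a Q-KLMS model as a plain-text directory
#'
#' `model.json` holds the hyperparameters and kernel spec;
#' `coefficients.csv` the outputs-by-centers coefficient matrix;
#' `centers_spikes.csv` (`center,unit,time_ms`) and `centers_lfp.csv`
#' (`center,channel,sample,value`) the dictionary samples.
#'
#' @param model A [qklms()] model with at least one center.
#' @param dir Directory.
#' @return `write_qklms()` returns `dir` invisibly; `read_qklms()` the model.
#' @export
write_qklms <- function(model, dir) {
  stopifnot(inherits(model, "qklms"))
  if (n_centers(model) == 0L) abort("refusing to persist an empty model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  c1 <- model$centers[[1L]]
  jsonlite::write_json(
    list(n_outputs = model$n_outputs, learning_rate = model$learning_rate,
         quantization_size = model$quantization_size, frozen = model$frozen,
         self_sim = model$self_sim,
         spike_window_ms = c1$spikes$window_length,
         lfp_sample_period_ms = c1$lfp$sample_period,
         lfp_len = nrow(c1$lfp$samples), n_lfp_channels = ncol(c1$lfp$samples),
         n_units = n_units(c1$spikes),
         kernel_spec = list(sigma_s = model$kernel_spec$sigma_s,
                            sigma_x = model$kernel_spec$sigma_x,
                            smoothing_width_ms = model$kernel_spec$smoothing_width,
                            normalize_channels = model$kernel_spec$normalize_channels,
                            modality_rule = model$kernel_spec$modality_rule)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(as.data.frame(model$coefficients),
                   file.path(dir, "coefficients.csv"))
  spk <- purrr::imap_dfr(model$centers, function(s, i) {
    purrr::imap_dfr(s$spikes$units, function(tt, u) {
      tibble::tibble(center = i, unit = u, time_ms = tt)
    })
  })
  if (!nrow(spk)) {
    spk <- tibble::tibble(center = integer(0), unit = integer(0),
                          time_ms = numeric(0))
  }
  readr::write_csv(spk, file.path(dir, "centers_spikes.csv"))
  lfp <- purrr::imap_dfr(model$centers, function(s, i) {
    m <- s$lfp$samples
    tibble::tibble(center = i,
                   channel = rep(seq_len(ncol(m)), each = nrow(m)),
                   sample = rep(seq_len(nrow(m)), ncol(m)),
                   value = as.vector(m))
  })
  readr::write_csv(lfp, file.path(dir, "centers_lfp.csv"))
  invisible(dir)
}

#' @rdname write_qklms
#' @export
read_qklms <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- composite_kernel_spec(sigma_s = meta$kernel_spec$sigma_s,
                                sigma_x = meta$kernel_spec$sigma_x,
                                smoothing_width = meta$kernel_spec$smoothing_width_ms,
                                normalize_channels = meta$kernel_spec$normalize_channels,
                                modality_rule = meta$kernel_spec$modality_rule)
  coef <- as.matrix(readr::read_csv(file.path(dir, "coefficients.csv"),
                                    col_types = readr::cols(.default = readr::col_double())))
  dimnames(coef) <- NULL
  spk <- readr::read_csv(file.path(dir, "centers_spikes.csv"),
                         col_types = readr::cols(center = readr::col_integer(),
                                                 unit = readr::col_integer(),
                                                 time_ms = readr::col_double()))
  lfp <- readr::read_csv(file.path(dir, "centers_lfp.csv"),
                         col_types = readr::cols(center = readr::col_integer(),
                                                 channel = readr::col_integer(),
                                                 sample = readr::col_integer(),
                                                 value = readr::col_double()))
  N <- ncol(coef)
  centers <- lapply(seq_len(N), function(i) {
    units <- lapply(seq_len(meta$n_units), function(u) {
      sort(spk$time_ms[spk$center == i & spk$unit == u])
    })
    m <- matrix(0, meta$lfp_len, meta$n_lfp_channels)
    li <- lfp[lfp$center == i, ]
    m[cbind(li$sample, li$channel)] <- li$value
    multiscale_sample(
      multiunit_spike_window(units, window_length = meta$spike_window_ms),
      multichannel_lfp_window(m, sample_period = meta$lfp_sample_period_ms))
  })
  model <- qklms(spec, n_outputs = meta$n_outputs,
                 learning_rate = meta$learning_rate,
                 quantization_size = meta$quantization_size)
  model$centers <- centers
  model$self_sim <- as.numeric(meta$self_sim)
  model$coefficients <- coef
  model$frozen <- isTRUE(meta$frozen)
  model
}

#' Write a Gram matrix to CSV
#'
#' Plain numeric CSV (no header), with the kernel spec stored alongside in
#' `<path>.spec.json`.
#'
#' @param K Gram matrix from [gram_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_gram <- function(K, path) {
  utils::write.table(K, path, sep = ",", row.names = FALSE, col.names = FALSE)
  spec <- attr(K, "kernel_spec")
  if (!is.null(spec)) write_kernel_spec(spec, paste0(path, ".spec.json"))
  invisible(path)
}
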