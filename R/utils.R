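#' @importFrom rlang %||% abort warn
#' @importFrom stats rexp rnorm rpois runif sd
NULL

# Derive a reproducible 31-bit substream seed from a master seed and a label,
# so the stimulus, spike and noise generators can be re-run independently.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_pos <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# Pack a list of multiscale samples into the flat arrays the compiled kernel
# evaluations consume. Layouts are documented at the top of src/kernels.cpp.
pack_samples <- function(samples) {
  n <- length(samples)
  if (n == 0L) {
    return(list(n = 0L))
  }
  first <- samples[[1L]]
  U <- n_units(first$spikes)
  Ts <- first$spikes$window_length
  lfp1 <- first$lfp
  len <- nrow(lfp1$samples)
  C <- ncol(lfp1$samples)
  tau <- lfp1$sample_period

  counts <- matrix(0L, n, U)
  times <- vector("list", n)
  X <- matrix(0, n, len * C)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    if (n_units(s$spikes) != U) abort("unit-count mismatch across samples")
    if (s$spikes$window_length != Ts) abort("window-mismatch: spike window lengths differ")
    if (nrow(s$lfp$samples) != len || ncol(s$lfp$samples) != C ||
        s$lfp$sample_period != tau) {
      abort("shape mismatch across LFP windows")
    }
    counts[i, ] <- vapply(s$spikes$units, length, integer(1))
    times[[i]] <- unlist(s$spikes$units, use.names = FALSE)
    X[i, ] <- as.vector(s$lfp$samples)
  }
  flat <- unlist(times, use.names = FALSE) %||% numeric(0)
  # 0-based start offsets, filled sample-major then unit within sample
  starts <- matrix(0L, n, U)
  off <- 0L
  for (i in seq_len(n)) {
    for (u in seq_len(U)) {
      starts[i, u] <- off
      off <- off + counts[i, u]
    }
  }
  list(n = n, n_units = U, window_length = Ts,
       times = as.numeric(flat), starts = starts, counts = counts,
       X = X, len = len, n_channels = C, sample_period = tau)
}

# Extract sample i of a packed set as a single-sample pack (cheap; avoids
# re-packing R sample lists inside online loops).
pack_slice <- function(p, i) {
  st <- p$starts[i, , drop = TRUE]
  ct <- p$counts[i, , drop = TRUE]
  tt <- numeric(sum(ct))
  starts <- integer(length(ct))
  off <- 0L
  for (u in seq_along(ct)) {
    starts[u] <- off
    if (ct[u] > 0L) {
      tt[(off + 1L):(off + ct[u])] <- p$times[(st[u] + 1L):(st[u] + ct[u])]
      off <- off + ct[u]
    }
  }
  list(n = 1L, n_units = p$n_units, window_length = p$window_length,
       times = tt, starts = matrix(starts, 1L), counts = matrix(as.integer(ct), 1L),
       X = p$X[i, , drop = FALSE], len = p$len, n_channels = p$n_channels,
       sample_period = p$sample_period)
}

# Append one sample (given as a single-sample pack) to a pack in place of a
# full rebuild; O(size of pack) array copies, no per-sample R overhead.
pack_append <- function(p, p1) {
  if (is.null(p) || p$n == 0L) return(p1)
  list(n = p$n + 1L, n_units = p$n_units, window_length = p$window_length,
       times = c(p$times, p1$times),
       starts = rbind(p$starts, p1$starts + length(p$times)),
       counts = rbind(p$counts, p1$counts),
       X = rbind(p$X, p1$X), len = p$len, n_channels = p$n_channels,
       sample_period = p$sample_period)
}

# Trailing rolling maximum over the previous k rows (inclusive), per column.
rolling_max_rows <- function(M, k) {
  if (k <= 1L || nrow(M) == 0L) return(M)
  out <- M
  for (s in seq_len(k - 1L)) {
    shifted <- rbind(matrix(0, s, ncol(M)),
                     M[seq_len(nrow(M) - s), , drop = FALSE])
    out <- pmax(out, shifted)
  }
  out
}
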