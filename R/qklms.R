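#' Quantized kernel least-mean-square model
#'
#' Creates an empty Q-KLMS model: an online kernel adaptive filter whose
#' dictionary of center samples grows only when a new input is farther (in
#' RKHS distance) than `quantization_size` from every existing center;
#' otherwise the learning-rate-scaled error is added to the nearest center's
#' coefficient column, merging repeated inputs. With `quantization_size = 0`
#' only exact repeats merge and the filter behaves like plain KLMS.
#'
#' The stimulus decoder, the inverse plant model and the controller are all
#' instances of this one model type: a multi-output filter
#' `y_m = sum_n a_mn k(c_n, u)` with a shared dictionary.
#'
#' @param kernel_spec A [composite_kernel_spec()].
#' @param n_outputs Number of output channels M.
#' @param learning_rate Step size `eta > 0`.
#' @param quantization_size Quantization radius `eps_q >= 0`, in RKHS
#'   distance units.
#' @return An object of class `qklms`.
#' @export
qklms <- function(kernel_spec, n_outputs, learning_rate = 0.5,
                  quantization_size = 0) {
  stopifnot(inherits(kernel_spec, "composite_kernel_spec"))
  assert_scalar_pos(learning_rate, "learning_rate")
  if (!is_scalar_number(quantization_size) || quantization_size < 0) {
    abort("`quantization_size` must be a single non-negative number")
  }
  n_outputs <- as.integer(n_outputs)
  stopifnot(n_outputs >= 1L)
  structure(list(kernel_spec = kernel_spec,
                 n_outputs = n_outputs,
                 learning_rate = learning_rate,
                 quantization_size = quantization_size,
                 centers = list(),
                 self_sim = numeric(0),
                 coefficients = matrix(0, n_outputs, 0),
                 frozen = FALSE),
            class = "qklms")
}

#' Number of dictionary centers of a Q-KLMS model
#'
#' @param model A [qklms()] model.
#' @return Integer dictionary size.
#' @export
n_centers <- function(model) length(model$centers)

# kappa(c_i, u) for every center; small dictionaries go through the plain R
# kernels (reference path), larger ones through the packed compiled path.
kernel_vector <- function(model, u) {
  N <- n_centers(model)
  if (N == 0L) return(numeric(0))
  if (N <= 64L) {
    vapply(model$centers, function(ci) joint_kernel(ci, u, model$kernel_spec),
           numeric(1))
  } else {
    pc <- pack_samples(model$centers)
    pu <- pack_samples(list(u))
    drop(combine_modalities(modal_grams(pc, pu, model$kernel_spec),
                            model$kernel_spec$modality_rule))
  }
}

#' Predict from a Q-KLMS model
#'
#' Evaluates `y = A [k(c_n, u)]` over the dictionary. An empty model predicts
#' zeros.
#'
#' @param object A [qklms()] model.
#' @param newdata A single [multiscale_sample()] or a list of them (a
#'   `decoding_dataset` is also accepted).
#' @param ... Unused.
#' @return For a single sample, a numeric vector of length `n_outputs`; for a
#'   list, an `n x n_outputs` matrix.
#' @export
predict.qklms <- function(object, newdata, ...) {
  if (inherits(newdata, "decoding_dataset")) newdata <- newdata$samples
  if (inherits(newdata, "multiscale_sample")) {
    if (n_centers(object) == 0L) return(numeric(object$n_outputs))
    return(drop(object$coefficients %*% kernel_vector(object, newdata)))
  }
  stopifnot(is.list(newdata))
  n <- length(newdata)
  if (n_centers(object) == 0L) return(matrix(0, n, object$n_outputs))
  pc <- pack_samples(object$centers)
  pn <- pack_samples(newdata)
  K <- combine_modalities(modal_grams(pc, pn, object$kernel_spec),
                          object$kernel_spec$modality_rule)
  t(object$coefficients %*% K)
}

#' One online Q-KLMS update
#'
#' Computes the prediction error `e = d - y(u)`, finds the nearest dictionary
#' center in RKHS distance (ties broken by lowest center index), and either
#' adjusts that center's coefficient column by `eta e` (distance within the
#' quantization size) or appends `u` as a new center with coefficient column
#' `eta e`.
#'
#' @param model A [qklms()] model.
#' @param u Input [multiscale_sample()].
#' @param d Desired output, numeric of length `n_outputs`.
#' @return A list with elements `model` (updated) and `error` (the a-priori
#'   error `e`).
#' @export
qklms_update <- function(model, u, d) {
  stopifnot(inherits(model, "qklms"))
  d <- as.numeric(d)
  if (length(d) != model$n_outputs || any(!is.finite(d))) {
    abort("`d` must be a finite vector of length n_outputs")
  }
  eta <- model$learning_rate
  if (n_centers(model) == 0L) {
    e <- d
    model$centers <- list(u)
    model$self_sim <- joint_kernel(u, u, model$kernel_spec)
    model$coefficients <- matrix(eta * e, model$n_outputs, 1)
    return(list(model = model, error = e))
  }
  kv <- kernel_vector(model, u)
  e <- d - drop(model$coefficients %*% kv)
  self_u <- joint_kernel(u, u, model$kernel_spec)
  dist <- rkhs_distance(self_u, model$self_sim, kv)
  i <- which.min(dist)
  if (dist[i] <= model$quantization_size) {
    model$coefficients[, i] <- model$coefficients[, i] + eta * e
  } else {
    model$centers[[length(model$centers) + 1L]] <- u
    model$self_sim <- c(model$self_sim, self_u)
    model$coefficients <- cbind(model$coefficients, eta * e)
  }
  list(model = model, error = e)
}

#' Train a Q-KLMS model over a data sequence
#'
#' Presents the inputs in data order (no shuffling), repeating for `epochs`
#' passes; with a quantization size of zero and repeated passes, centers are
#' created only on the first pass and later passes refine the coefficients,
#' which is how the filter converges beyond the first iteration.
#'
#' Two engines produce the same results: `"online"` runs [qklms_update()]
#' step by step; `"gram"` precomputes the kernel matrix of the inputs once
#' (compiled code) and replays the identical recursion against it, which is
#' much faster for datasets of thousands of windows. `"auto"` picks `"gram"`
#' for an empty model with at least 50 inputs.
#'
#' @param model A fresh [qklms()] model (the gram engine requires an empty
#'   dictionary).
#' @param inputs List of [multiscale_sample()]s, or a `decoding_dataset`.
#' @param targets Numeric matrix `n x n_outputs` (a vector is taken as one
#'   channel). Taken from the dataset when `inputs` is a `decoding_dataset`
#'   and `targets` is missing.
#' @param epochs Number of passes, >= 1.
#' @param engine `"auto"`, `"online"` or `"gram"`.
#' @return A list with `model` (trained) and `trace`, a tibble of class
#'   `qklms_trace` with columns `epoch`, `step`, `dictionary_size` and the
#'   per-step error matrix column `error`.
#' @export
qklms_train <- function(model, inputs, targets = NULL, epochs = 1,
                        engine = c("auto", "online", "gram")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "qklms"))
  if (inherits(inputs, "decoding_dataset")) {
    if (is.null(targets)) targets <- inputs$targets
    inputs <- inputs$samples
  }
  n <- length(inputs)
  if (n == 0L) abort("empty training set")
  targets <- as.matrix(targets)
  if (ncol(targets) == 1L && model$n_outputs > 1L) {
    abort("targets have one column but the model has several outputs")
  }
  stopifnot(nrow(targets) == n, ncol(targets) == model$n_outputs)
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 1L)

  if (engine == "auto") {
    engine <- if (n_centers(model) == 0L && n >= 50L) "gram" else "online"
  }
  if (engine == "gram" && n_centers(model) > 0L) {
    abort("gram engine requires an empty model")
  }

  if (engine == "online") {
    E <- matrix(0, n * epochs, model$n_outputs)
    dict_size <- integer(n * epochs)
    r <- 0L
    for (ep in seq_len(epochs)) {
      for (j in seq_len(n)) {
        r <- r + 1L
        res <- qklms_update(model, inputs[[j]], targets[j, ])
        model <- res$model
        E[r, ] <- res$error
        dict_size[r] <- n_centers(model)
      }
    }
  } else {
    pa <- pack_samples(inputs)
    K <- combine_modalities(modal_grams(pa, NULL, model$kernel_spec),
                            model$kernel_spec$modality_rule)
    fit <- qklms_gram_fit(K, targets, model$learning_rate,
                          model$quantization_size, epochs)
    model$centers <- inputs[fit$dict]
    model$self_sim <- diag(K)[fit$dict]
    model$coefficients <- fit$coef
    E <- fit$E
    dict_size <- fit$dict_size
  }

  trace <- tibble::tibble(epoch = rep(seq_len(epochs), each = n),
                          step = rep(seq_len(n), epochs),
                          dictionary_size = dict_size,
                          error = E)
  class(trace) <- c("qklms_trace", class(trace))
  list(model = model, trace = trace)
}

# The Q-KLMS recursion replayed (in compiled code) against a precomputed
# kernel matrix of the training inputs: same decisions as the online path.
# Returns the dictionary (input indices), coefficients and trace arrays.
qklms_gram_fit <- function(K, targets, eta, eps, epochs) {
  cpp_qklms_gram_fit(K, as.matrix(targets), eta, eps, as.integer(epochs))
}

#' Per-epoch mean squared error of a learning trace
#'
#' @param trace A `qklms_trace` as returned by [qklms_train()].
#' @return A tibble with columns `epoch` and `mse` (mean over steps of the
#'   squared error summed across output channels).
#' @export
trace_epoch_mse <- function(trace) {
  se <- rowSums(as.matrix(trace$error)^2)
  tibble::tibble(epoch = unique(trace$epoch),
                 mse = as.numeric(tapply(se, trace$epoch, mean)))
}

#' @export
print.qklms <- function(x, ...) {
  cat(sprintf(
    "<qklms> %d output(s), %d center(s), eta = %g, eps_q = %g, rule = %s%s\n",
    x$n_outputs, n_centers(x), x$learning_rate, x$quantization_size,
    x$kernel_spec$modality_rule, if (x$frozen) " (dictionary frozen)" else ""))
  invisible(x)
}

#' Tidy a Q-KLMS model
#'
#' @param x A [qklms()] model.
#' @param ... Unused.
#' @return A tibble with one row per (center, output) pair and columns
#'   `center`, `output`, `coefficient`.
#' @method tidy qklms
#' @export
tidy.qklms <- function(x, ...) {
  N <- n_centers(x)
  tibble::tibble(center = rep(seq_len(N), each = x$n_outputs),
                 output = rep(seq_len(x$n_outputs), N),
                 coefficient = as.vector(x$coefficients))
}

#' One-row summary of a Q-KLMS model
#'
#' @param x A [qklms()] model.
#' @param ... Unused.
#' @return A one-row tibble with the dictionary size and hyperparameters.
#' @method glance qklms
#' @export
glance.qklms <- function(x, ...) {
  tibble::tibble(n_centers = n_centers(x),
                 n_outputs = x$n_outputs,
                 learning_rate = x$learning_rate,
                 quantization_size = x$quantization_size,
                 modality_rule = x$kernel_spec$modality_rule,
                 frozen = x$frozen)
}

#' Plot a Q-KLMS learning trace
#'
#' Per-epoch mean squared training error, with the dictionary growth as a
#' secondary panel-free annotation in the subtitle.
#'
#' @param object A `qklms_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qklms_trace
#' @export
autoplot.qklms_trace <- function(object, ...) {
  em <- trace_epoch_mse(object)
  ggplot2::ggplot(em, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training MSE",
                  subtitle = sprintf("final dictionary size: %d",
                                     max(object$dictionary_size))) +
    ggplot2::theme_minimal()
}
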