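#' Network architecture specification
#'
#' Both forecasters share the same trunk: the first 200 samples of the
#' exposure (10 s at 20 Hz) feed two fully connected hidden layers of 50
#' and 24 units with leaky-ReLU activations; they differ only in the
#' linear output layer — 6 units when predicting the response-model
#' coefficients, 1 unit when predicting the final value directly.
#'
#' @param output_size 6 (coefficient prediction) or 1 (direct final
#'   value).
#' @param input_size Input window length in samples (default 200).
#' @param hidden_sizes Hidden layer widths (default `c(50, 24)`).
#' @param leaky_slope Negative-side slope of the leaky ReLU (default
#'   0.01).
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(output_size, input_size = 200,
                     hidden_sizes = c(50, 24), leaky_slope = 0.01) {
  if (!output_size %in% c(1L, 6L)) {
    abort("`output_size` must be 1 (final value) or 6 (coefficients).")
  }
  structure(
    list(input_size = as.integer(input_size),
         hidden_sizes = as.integer(hidden_sizes),
         output_size = as.integer(output_size),
         leaky_slope = leaky_slope),
    class = "mlp_spec"
  )
}

#' Training configuration
#'
#' @param epochs Training epochs (default 100).
#' @param learning_rate Initial Adam learning rate (default 2e-4; no
#'   schedule is applied).
#' @param minibatch_size Minibatch size (default 16).
#' @param seed Integer seed covering weight initialisation and minibatch
#'   shuffling; a fixed seed makes training bit-reproducible.
#' @param k_folds Folds for [cross_validate()] (default 5).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 100, learning_rate = 2e-4,
                            minibatch_size = 16, seed = 1, k_folds = 5,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  vals <- c(epochs, learning_rate, minibatch_size, k_folds)
  if (any(vals <= 0)) abort("All training settings must be positive.")
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         minibatch_size = as.integer(minibatch_size),
         seed = as.integer(seed), k_folds = as.integer(k_folds),
         beta1 = beta1, beta2 = beta2, epsilon = epsilon),
    class = "training_config"
  )
}

#' Input scaling factor
#'
#' Predictors are divided by a single factor: the maximum over training
#' instances of the response value at the exposure onset. Computed on the
#' training portion only — test inputs reuse the stored factor, so there
#' is no leakage. If that maximum is not positive (a channel resting below
#' zero), the maximum absolute onset value is used instead, with a
#' warning.
#'
#' @param first_samples Numeric vector of per-instance onset values
#'   `x_{i,0}` over the training set.
#' @return The scalar input factor.
#' @export
compute_input_scaling <- function(first_samples) {
  if (length(first_samples) < 1) abort("Empty training set.")
  f <- max(first_samples)
  if (f <= 0) {
    warn("Max onset value is not positive; falling back to max |x_0|.")
    f <- max(abs(first_samples))
    if (f == 0) {
      warn("All onset values are zero; input scaling set to 1.")
      f <- 1
    }
  }
  f
}

#' Target scaling factors
#'
#' Each target column is divided by its maximum over training instances.
#' Non-positive column maxima fall back to the maximum absolute value
#' (then to 1), with a warning.
#'
#' @param train_targets Numeric matrix, instances by targets.
#' @return Vector of per-column factors.
#' @export
compute_target_scaling <- function(train_targets) {
  train_targets <- as.matrix(train_targets)
  if (nrow(train_targets) < 1) abort("Empty training set.")
  apply(train_targets, 2, function(col) {
    f <- max(col)
    if (f <= 0) {
      warn("Non-positive target column max; falling back to max |y|.")
      f <- max(abs(col))
      if (f == 0) {
        warn("All-zero target column; scaling set to 1.")
        f <- 1
      }
    }
    f
  })
}

target_names_for <- function(mode) {
  if (mode == "parameter") c("a1", "tau1", "beta", "a2", "tau2", "o")
  else "final_value"
}

#' Build scaled training pairs from a dataset
#'
#' Extracts the first `window_samples` post-onset samples of every trace
#' as the input vector and either the six response-model coefficients
#' (order `a1, tau1, beta, a2, tau2, o`) or the scalar true final value as
#' the target. Inputs are divided by the input factor and targets
#' column-wise by the target factors, both computed on the training split
#' only.
#'
#' @param ds A split (optionally augmented) `sensor_dataset`.
#' @param mode `"parameter"` or `"final_value"`.
#' @param window_samples Input window length (default 200 = 10 s at
#'   20 Hz).
#' @return A `forecast_pairs` list with scaled matrices `x_train`,
#'   `y_train`, `x_test`, `y_test`, the scaling factors `f_in` / `f_out`,
#'   and row ids.
#' @export
make_training_pairs <- function(ds, mode = c("parameter", "final_value"),
                                window_samples = 200) {
  mode <- match.arg(mode)
  if (any(is.na(ds$split))) abort("Dataset must be split first.")
  short <- purrr::map_int(ds$trace, nrow) < window_samples
  if (any(short)) {
    abort(sprintf("Trace `%s` has fewer than %d post-onset samples.",
                  ds$trace_id[which(short)[1]], window_samples))
  }
  windows <- t(vapply(ds$trace, function(tr) tr$value[1:window_samples],
                      numeric(window_samples)))
  tn <- target_names_for(mode)
  targets <- as.matrix(tibble::as_tibble(ds)[, tn, drop = FALSE])
  is_train <- ds$split == "train"
  f_in <- compute_input_scaling(windows[is_train, 1])
  f_out <- compute_target_scaling(targets[is_train, , drop = FALSE])
  scale_y <- function(m) sweep(m, 2, f_out, "/")
  structure(
    list(
      x_train = windows[is_train, , drop = FALSE] / f_in,
      y_train = scale_y(targets[is_train, , drop = FALSE]),
      x_test = windows[!is_train, , drop = FALSE] / f_in,
      y_test = scale_y(targets[!is_train, , drop = FALSE]),
      f_in = f_in, f_out = f_out, mode = mode,
      target_names = tn, window_samples = as.integer(window_samples),
      train_ids = ds$trace_id[is_train], test_ids = ds$trace_id[!is_train]
    ),
    class = "forecast_pairs"
  )
}

# ---- network internals ------------------------------------------------------

glorot_init <- function(spec) {
  sizes <- c(spec$input_size, spec$hidden_sizes, spec$output_size)
  purrr::map(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1]
    limit <- sqrt(6 / (fan_in + fan_out))
    list(
      W = matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out),
      b = rep(0, fan_out)
    )
  })
}

lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lrelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

# forward pass; keeps pre-activations for backprop
mlp_forward <- function(weights, x, slope) {
  n_layers <- length(weights)
  zs <- vector("list", n_layers)
  as <- vector("list", n_layers + 1)
  as[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- as[[l]] %*% weights[[l]]$W +
      matrix(weights[[l]]$b, nrow(x), length(weights[[l]]$b), byrow = TRUE)
    zs[[l]] <- z
    as[[l + 1]] <- if (l < n_layers) lrelu(z, slope) else z
  }
  list(output = as[[n_layers + 1]], zs = zs, as = as)
}

mlp_backward <- function(weights, fwd, y, slope) {
  n_layers <- length(weights)
  n <- nrow(y)
  grads <- vector("list", n_layers)
  delta <- 2 * (fwd$output - y) / (n * ncol(y))
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(
      W = crossprod(fwd$as[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1) {
      delta <- (delta %*% t(weights[[l]]$W)) *
        lrelu_grad(fwd$zs[[l - 1]], slope)
    }
  }
  grads
}

#' Mean-squared-error loss of a forecaster on scaled pairs
#'
#' @param model A trained `mlp_forecaster` (or a bare weight list with a
#'   spec, internal use).
#' @param x,y Scaled input and target matrices.
#' @return Scalar MSE over all elements.
#' @export
mlp_loss <- function(model, x, y) {
  out <- mlp_forward(model$weights, x, model$spec$leaky_slope)$output
  mean((out - y)^2)
}

#' Train a forecaster
#'
#' Trains the MLP on the scaled training pairs with minibatch Adam and an
#' MSE loss: seeded Glorot-uniform initialisation, per-epoch reshuffling,
#' no early stopping and no learning-rate schedule. The recorded loss
#' curve is the full-training-set MSE at the end of each epoch.
#'
#' @param pairs A `forecast_pairs` object from [make_training_pairs()].
#' @param spec An [mlp_spec()]; by default derived from the pairs' mode.
#' @param config A [training_config()].
#' @return An `mlp_forecaster` carrying the weights, spec, scaling
#'   factors, mode and loss curve.
#' @export
train_forecaster <- function(pairs, spec = NULL,
                             config = training_config()) {
  if (!inherits(pairs, "forecast_pairs")) {
    abort("`pairs` must come from make_training_pairs().")
  }
  spec <- spec %||% mlp_spec(
    output_size = length(pairs$f_out),
    input_size = pairs$window_samples
  )
  x <- pairs$x_train
  y <- pairs$y_train
  if (ncol(x) != spec$input_size || ncol(y) != spec$output_size) {
    abort("Pair shapes do not match the network spec.")
  }
  fitted <- withr::with_seed(config$seed, {
    weights <- glorot_init(spec)
    adam_m <- purrr::map(weights, ~ list(W = .x$W * 0, b = .x$b * 0))
    adam_v <- adam_m
    step <- 0
    loss_curve <- numeric(config$epochs)
    n <- nrow(x)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      batch_starts <- seq(1, n, by = config$minibatch_size)
      for (s in batch_starts) {
        rows <- idx[s:min(s + config$minibatch_size - 1, n)]
        xb <- x[rows, , drop = FALSE]
        yb <- y[rows, , drop = FALSE]
        fwd <- mlp_forward(weights, xb, spec$leaky_slope)
        grads <- mlp_backward(weights, fwd, yb, spec$leaky_slope)
        step <- step + 1
        bc1 <- 1 - config$beta1^step
        bc2 <- 1 - config$beta2^step
        for (l in seq_along(weights)) {
          for (part in c("W", "b")) {
            g <- grads[[l]][[part]]
            adam_m[[l]][[part]] <- config$beta1 * adam_m[[l]][[part]] +
              (1 - config$beta1) * g
            adam_v[[l]][[part]] <- config$beta2 * adam_v[[l]][[part]] +
              (1 - config$beta2) * g^2
            m_hat <- adam_m[[l]][[part]] / bc1
            v_hat <- adam_v[[l]][[part]] / bc2
            weights[[l]][[part]] <- weights[[l]][[part]] -
              config$learning_rate * m_hat / (sqrt(v_hat) + config$epsilon)
          }
        }
      }
      loss_curve[epoch] <-
        mean((mlp_forward(weights, x, spec$leaky_slope)$output - y)^2)
      if (!is.finite(loss_curve[epoch])) {
        abort(sprintf(
          "Training diverged: non-finite loss at epoch %d (lr = %g).",
          epoch, config$learning_rate
        ))
      }
    }
    list(weights = weights, loss_curve = loss_curve)
  })
  structure(
    list(
      weights = fitted$weights, spec = spec, config = config,
      f_in = pairs$f_in, f_out = pairs$f_out, mode = pairs$mode,
      target_names = pairs$target_names,
      loss_curve = fitted$loss_curve,
      final_loss = tail(fitted$loss_curve, 1),
      n_train = nrow(x)
    ),
    class = "mlp_forecaster"
  )
}

#' @export
print.mlp_forecaster <- function(x, ...) {
  cat(sprintf(
    "<mlp_forecaster: %s mode, %d-%s-%d, final training loss %.4g (%d epochs, n = %d)>\n",
    x$mode, x$spec$input_size,
    paste(x$spec$hidden_sizes, collapse = "-"), x$spec$output_size,
    x$final_loss, x$config$epochs, x$n_train
  ))
  invisible(x)
}

#' Predict raw outputs for new windows
#'
#' @param object A trained `mlp_forecaster`.
#' @param newdata Matrix of raw (unscaled, engineering-unit) input
#'   windows, one row per instance; a single window may be given as a
#'   vector.
#' @param ... Unused.
#' @return Matrix of unscaled outputs: six model coefficients per row in
#'   parameter mode, one final value per row in final-value mode.
#' @export
predict.mlp_forecaster <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$spec$input_size) {
    abort(sprintf("Windows must have %d samples.", object$spec$input_size))
  }
  out <- mlp_forward(object$weights, newdata / object$f_in,
                     object$spec$leaky_slope)$output
  out <- sweep(out, 2, object$f_out, "*")
  colnames(out) <- object$target_names
  out
}

#' Forecast the steady-state value from a 10 s window
#'
#' In final-value mode the network output is the forecast directly. In
#' parameter mode the six predicted coefficients are unscaled and the
#' model's steady-state value — the offset, the exact infinite-time limit
#' — is returned; `at_time` instead evaluates the predicted curve at a
#' finite time. Predicted time constants or stretching exponents outside
#' the fitting bounds are clamped with a warning before evaluation.
#'
#' @param model A trained `mlp_forecaster`.
#' @param window Raw input window(s): vector or matrix of
#'   `input_size`-sample rows, engineering units.
#' @param at_time `Inf` (default) for the exact limit, or a finite time in
#'   seconds at which to evaluate the predicted parameter-mode curve.
#' @return Numeric vector of forecast final values.
#' @export
forecast_final_value <- function(model, window, at_time = Inf) {
  out <- predict(model, window)
  if (model$mode == "final_value") {
    return(drop(out[, 1]))
  }
  b <- default_fit_bounds()
  vapply(seq_len(nrow(out)), function(i) {
    co <- out[i, ]
    taus <- co[c("tau1", "tau2")]
    beta <- co[["beta"]]
    if (any(taus < b$tau[1]) || any(taus > b$tau[2]) ||
        beta < b$beta[1] || beta > b$beta[2]) {
      warn("Predicted coefficients outside bounds; clamping.")
    }
    taus <- pmin(pmax(taus, b$tau[1]), b$tau[2])
    beta <- min(max(beta, b$beta[1]), b$beta[2])
    p <- model_params(c(co[["a1"]], co[["a2"]]), unname(taus),
                      beta = beta, offset = co[["o"]])
    if (is.finite(at_time)) evaluate_response(p, at_time)
    else steady_state_value(p)
  }, numeric(1))
}

#' K-fold cross-validation of a forecaster
#'
#' Partitions the training pairs into `k` seeded folds, trains one model
#' per fold on the remaining folds, and reports each model's final
#' training loss (plus its loss on the held-out fold).
#'
#' @param pairs A `forecast_pairs` object.
#' @param spec Optional [mlp_spec()].
#' @param config A [training_config()]; `config$k_folds` folds by
#'   default.
#' @param k Number of folds.
#' @return Tibble with one row per fold: `fold`, `n_train`, `n_val`,
#'   `train_loss`, `val_loss`.
#' @export
cross_validate <- function(pairs, spec = NULL, config = training_config(),
                           k = config$k_folds) {
  n <- nrow(pairs$x_train)
  if (k > n) abort("More folds than training samples.")
  fold_of <- withr::with_seed(config$seed,
                              sample(rep_len(seq_len(k), n)))
  purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold_of != f
    sub <- pairs
    sub$x_train <- pairs$x_train[tr, , drop = FALSE]
    sub$y_train <- pairs$y_train[tr, , drop = FALSE]
    sub$train_ids <- pairs$train_ids[tr]
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_forecaster(sub, spec = spec, config = cfg)
    tibble::tibble(
      fold = f, n_train = sum(tr), n_val = sum(!tr),
      train_loss = model$final_loss,
      val_loss = mlp_loss(model, pairs$x_train[!tr, , drop = FALSE],
                          pairs$y_train[!tr, , drop = FALSE])
    )
  })
}

#' Glance at a trained forecaster
#'
#' @param x An `mlp_forecaster`.
#' @param ... Unused.
#' @return One-row tibble: mode, architecture, parameter count, final
#'   training loss.
#' @export
glance.mlp_forecaster <- function(x, ...) {
  n_weights <- sum(purrr::map_int(
    x$weights, ~ length(.x$W) + length(.x$b)
  ))
  tibble::tibble(
    mode = x$mode, input_size = x$spec$input_size,
    hidden = paste(x$spec$hidden_sizes, collapse = "-"),
    output_size = x$spec$output_size, n_weights = n_weights,
    epochs = x$config$epochs, n_train = x$n_train,
    final_loss = x$final_loss
  )
}

#' Plot the training-loss curve
#'
#' @param object An `mlp_forecaster`.
#' @param ... Unused.
#' @return A ggplot of training MSE against epoch (log y).
#' @export
autoplot.mlp_forecaster <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_curve),
                       loss = object$loss_curve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#1b9e77") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE (scaled targets)")
}
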