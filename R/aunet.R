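#' Add-skip encoder-decoder topology
#'
#' A symmetric U-shaped encoder-decoder for single-frame hologram
#' inversion. Each level is built from (3x3 convolution -> batch
#' normalization -> ReLU) units; levels are joined by 2x2 max pooling on
#' the way down and learnable 2x2 stride-2 transposed convolutions on the
#' way up. Encoder features reach the decoder through skip connections:
#' in `"add"` mode (the default, the lightweight variant) they are summed
#' with the upsampled features, which requires — and this topology
#' guarantees — equal channel widths at matching scales; in `"cat"` mode
#' they are concatenated, doubling the first decoder convolution's input
#' width and with it the parameter count. A 1x1 convolution with a
#' sigmoid maps the final features to a single channel in `[0, 1]`.
#'
#' The bottleneck width is twice the deepest level width. Input images
#' must be divisible by `2^depth` in both dimensions.
#'
#' @param depth Number of down-sampling levels.
#' @param widths Integer vector of channel widths, one per level.
#' @param convs_per_level Convolution units per level block.
#' @param skip_mode `"add"` or `"cat"`.
#' @param input_shape `c(rows, cols)` the model operates on.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(depth = 3L, widths = c(8L, 16L, 32L),
                         convs_per_level = 1L,
                         skip_mode = c("add", "cat"),
                         input_shape = c(64L, 64L)) {
  skip_mode <- match.arg(skip_mode)
  depth <- as.integer(depth)
  widths <- as.integer(widths)
  input_shape <- as.integer(input_shape)
  if (length(widths) != depth) stop("need one width per level", call. = FALSE)
  if (any(widths < 1L)) stop("widths must be positive", call. = FALSE)
  if (any(input_shape %% 2L^depth != 0L)) {
    stop("input_shape must be divisible by 2^depth", call. = FALSE)
  }
  structure(list(depth = depth, widths = widths,
                 convs_per_level = as.integer(convs_per_level),
                 skip_mode = skip_mode, input_shape = input_shape),
            class = "network_spec")
}

#' Build the network
#'
#' Instantiates the topology with He-normal initial weights drawn from a
#' dedicated generator, so two builds with the same seed have identical
#' parameters.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `aunet_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  ptr <- unet_create(spec$input_shape[1], spec$input_shape[2], spec$depth,
                     spec$widths, spec$convs_per_level,
                     spec$skip_mode == "add", as.integer(seed))
  structure(list(ptr = ptr, spec = spec, seed = as.integer(seed)),
            class = "aunet_model")
}

#' Number of trainable parameters (plus batch-norm statistics)
#' @param model An `aunet_model`.
#' @return Integer-valued parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "aunet_model"))
  unet_nparams(model$ptr)
}

#' @export
print.aunet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "aunet_model: depth %d, widths %s, %s skips, %d x %d input, %s parameters\n",
    s$depth, paste(s$widths, collapse = "/"), s$skip_mode,
    s$input_shape[1], s$input_shape[2],
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Extract / restore model parameters
#'
#' @param model An `aunet_model`.
#' @return A named list of parameter matrices (convolution and transposed
#'   convolution weights, biases, batch-norm affine terms and running
#'   statistics).
#' @export
model_parameters <- function(model) unet_get_params(model$ptr)

#' @rdname model_parameters
#' @param params A list previously returned by [model_parameters()] for a
#'   model with the same topology.
#' @export
set_model_parameters <- function(model, params) {
  unet_set_params(model$ptr, params)
  invisible(model)
}

#' Training configuration
#'
#' The loss is the mean squared error and the optimizer is Adam
#' throughout. Training follows a staged learning-rate schedule, a list of
#' `(lr, cycles)` pairs where one cycle is one pass (epoch) over the
#' training set. The `"paper"` profile is the reference schedule — lr
#' 0.01 for 10 cycles, 0.001 for 40, 0.0001 for 50, then 0.00008 for 200
#' (300 cycles total). The `"desk"` profile keeps the same four stages,
#' compressed to run on one CPU in minutes: 0.01 for 2, 0.001 for 30,
#' 0.0001 for 8, 0.00008 for 4 (44 cycles), with minibatches of 5.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param batch_size Minibatch size.
#' @param seed Integer seed governing shuffling.
#' @param schedule Optional override: data frame with columns `lr` and
#'   `cycles`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper"), batch_size = NULL,
                         seed = 1L, schedule = NULL) {
  profile <- match.arg(profile)
  if (is.null(schedule)) {
    schedule <- if (profile == "paper") {
      data.frame(lr = c(0.01, 0.001, 0.0001, 0.00008),
                 cycles = c(10L, 40L, 50L, 200L))
    } else {
      data.frame(lr = c(0.01, 0.001, 0.0001, 0.00008),
                 cycles = c(2L, 30L, 8L, 4L))
    }
  }
  stopifnot(all(c("lr", "cycles") %in% names(schedule)),
            all(schedule$lr > 0), all(schedule$cycles >= 1))
  if (is.null(batch_size)) batch_size <- if (profile == "paper") 16L else 5L
  structure(list(profile = profile, loss = "mse", optimizer = "adam",
                 schedule = schedule, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the network
#'
#' Runs the staged MSE/Adam schedule over the training pairs (hologram in,
#' reconstruction target out), shuffling each cycle with the configured
#' seed. The history records one row per cycle with the stage learning
#' rate and the mean training loss; when a test set is supplied, the mean
#' test SSIM is evaluated at the end of every stage and at the final
#' cycle.
#'
#' @param model An `aunet_model` (updated in place; also returned).
#' @param data Either the result of [load_dataset()] or a list with
#'   elements `x` and `y`, `H x W x n` arrays in `[0, 1]`.
#' @param config A [train_config()].
#' @param test Optional list with `x` and `y` arrays for monitoring.
#' @param verbose Print a line per cycle.
#' @return A list of class `aunet_training` with elements `model`,
#'   `history` (data frame: cycle, stage, lr, train_loss, test_ssim) and
#'   `config`.
#' @export
train_aunet <- function(model, data, config = train_config(), test = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "aunet_model"), inherits(config, "train_config"))
  if (!is.null(data$train)) {
    if (is.null(test) && !is.null(data$test) && length(data$test$names) > 0) {
      test <- data$test
    }
    data <- data$train
  }
  x <- data$x; y <- data$y
  stopifnot(length(dim(x)) == 3L, identical(dim(x), dim(y)))
  n <- dim(x)[3]
  if (n == 0L) stop("empty training set", call. = FALSE)
  bs <- min(config$batch_size, n)
  history <- list()
  cycle <- 0L
  with_seed(config$seed, {
    for (stage in seq_len(nrow(config$schedule))) {
      lr <- config$schedule$lr[stage]
      for (cyc in seq_len(config$schedule$cycles[stage])) {
        cycle <- cycle + 1L
        ord <- sample.int(n)
        losses <- numeric(0)
        weights <- numeric(0)
        for (start in seq(1L, n, by = bs)) {
          idx <- ord[start:min(start + bs - 1L, n)]
          loss <- unet_train_batch(model$ptr,
                                   x[, , idx, drop = FALSE],
                                   y[, , idx, drop = FALSE], lr)
          losses <- c(losses, loss)
          weights <- c(weights, length(idx))
        }
        train_loss <- sum(losses * weights) / sum(weights)
        at_stage_end <- cyc == config$schedule$cycles[stage]
        test_ssim <- NA_real_
        if (!is.null(test) && at_stage_end) {
          test_ssim <- evaluate_ssim(model, test$x, test$y)
        }
        history[[cycle]] <- data.frame(cycle = cycle, stage = stage, lr = lr,
                                       train_loss = train_loss,
                                       test_ssim = test_ssim)
        if (verbose) {
          message(sprintf("cycle %3d (lr %.5f): loss %.6f%s", cycle, lr,
                          train_loss,
                          if (is.na(test_ssim)) ""
                          else sprintf(", test SSIM %.4f", test_ssim)))
        }
      }
    }
  })
  structure(list(model = model, history = do.call(rbind, history),
                 config = config),
            class = "aunet_training")
}

#' Single-frame inference
#'
#' Runs the trained network in evaluation mode (batch-norm running
#' statistics, no parameter updates). Inputs are expected on the `[0, 1]`
#' scale used in training (holograms normalized by their maximum); an
#' input whose maximum exceeds 1 is normalized by that maximum first.
#' The sigmoid head guarantees outputs in `[0, 1]`.
#'
#' @param model A trained `aunet_model`.
#' @param hologram A matrix, or an `H x W x n` array for a batch.
#' @return Reconstructed image(s), same shape as the input.
#' @export
infer <- function(model, hologram) {
  stopifnot(inherits(model, "aunet_model"))
  single <- length(dim(hologram)) < 3L
  x <- if (single) array(hologram, c(dim(as.matrix(hologram)), 1L)) else hologram
  mx <- max(x)
  if (mx > 1) x <- x / mx
  out <- unet_predict(model$ptr, x)
  if (single) out[, , 1] else out
}

#' Mean SSIM between network outputs and targets
#'
#' @param model A trained `aunet_model`.
#' @param x Hologram array `H x W x n`.
#' @param y Target array `H x W x n`.
#' @param ... Passed to [ssim()].
#' @return Mean SSIM over the `n` pairs.
#' @export
evaluate_ssim <- function(model, x, y, ...) {
  out <- infer(model, x)
  mean(vapply(seq_len(dim(x)[3]),
              function(i) ssim(out[, , i], y[, , i], ...), numeric(1)))
}
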