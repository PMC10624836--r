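#' Specification of the phase-predicting surrogate network
#'
#' A lightweight fully convolutional encoder--decoder that maps one
#' diffraction frame to a same-sized real-space phase patch in a single
#' pass. Each encoder stage applies two 3x3 convolutions (ReLU) and halves
#' the resolution by 2x2 max pooling; the bottleneck applies
#' `bottleneck_convs` further convolutions at the deepest width; each
#' decoder stage upsamples by nearest-neighbour 2x and applies two 3x3
#' convolutions (checkerboard-safe). A final 3x3 convolution with a
#' \eqn{\pi\tanh} activation produces the single phase channel, bounding
#' outputs to \eqn{(-\pi, \pi)}. With the default widths the network has
#' about 0.7M trainable parameters, half the filter count (and no amplitude
#' branch) of its heavier predecessor.
#'
#' @param input_side Frame side in pixels (must be divisible by
#'   `2^length(encoder_widths)`); the parameter count does not depend on it.
#' @param encoder_widths Filter counts of the encoder stages.
#' @param bottleneck_convs Number of convolutions at the deepest width.
#' @param in_channels Input channels (1 for raw intensity frames).
#' @param input_transform `"sqrt"` (default) feeds the network the
#'   amplitude-like square root of the counts, which stabilizes the many
#'   orders of magnitude between the central beam and the information-rich
#'   weak fringes; `"intensity"` feeds raw counts. Recorded with the model
#'   so inference always matches training.
#' @return A `network_spec` list.
#' @examples
#' count_parameters(build_network(network_spec()))  # ~0.7M
#' @export
network_spec <- function(input_side = 128L,
                         encoder_widths = c(16L, 32L, 64L, 128L),
                         bottleneck_convs = 2L, in_channels = 1L,
                         input_transform = c("sqrt", "intensity")) {
  input_side <- as.integer(input_side)
  input_transform <- match.arg(input_transform)
  if (input_side %% (2L^length(encoder_widths)) != 0L)
    stop_invalid("input_side must be divisible by 2^%d", length(encoder_widths))
  if (any(encoder_widths < 1)) stop_invalid("encoder widths must be positive")
  structure(list(input_side = input_side,
                 encoder_widths = as.integer(encoder_widths),
                 bottleneck_convs = as.integer(bottleneck_convs),
                 in_channels = as.integer(in_channels),
                 input_transform = input_transform),
            class = "network_spec")
}

## Layer table: rows (type, cin, cout); 1 conv+relu, 2 conv+tanh*pi,
## 3 maxpool2, 4 upsample2.
build_layers <- function(spec) {
  w <- spec$encoder_widths
  L <- list()
  prev <- spec$in_channels
  for (wi in w) {
    L <- c(L, list(c(1L, prev, wi), c(1L, wi, wi), c(3L, wi, wi)))
    prev <- wi
  }
  for (k in seq_len(spec$bottleneck_convs))
    L <- c(L, list(c(1L, prev, prev)))
  nd <- length(w)
  for (i in rev(seq_len(nd))) {
    if (i > 1) {
      L <- c(L, list(c(4L, w[i], w[i]),
                     c(1L, w[i], w[i - 1]), c(1L, w[i - 1], w[i - 1])))
    } else {
      L <- c(L, list(c(4L, w[1], w[1]), c(2L, w[1], 1L)))
    }
  }
  do.call(rbind, L)
}

conv_param_count <- function(cin, cout) 9L * cin * cout + cout

layer_param_count <- function(layers) {
  sum(apply(layers, 1L, function(l)
    if (l[1] %in% c(1L, 2L)) conv_param_count(l[2], l[3]) else 0L))
}

#' Build (initialize) a surrogate model
#'
#' Weights use He-style initialization, \eqn{N(0, \sqrt{2/(9\,c_{in})})},
#' biases start at zero; initialization is deterministic for a given seed.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return A `ptycho_model`: `spec`, `layers`, `params` (flat numeric
#'   vector of all trainable scalars), `version` (0 until first accepted
#'   training), `norm_const` (input normalization recorded at training),
#'   `training_meta`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  layers <- build_layers(spec)
  npar <- layer_param_count(layers)
  params <- numeric(npar)
  off <- 0L
  with_seed(seed, {
    for (l in seq_len(nrow(layers))) {
      if (layers[l, 1] %in% c(1L, 2L)) {
        cin <- layers[l, 2]; cout <- layers[l, 3]
        nw <- 9L * cin * cout
        params[off + seq_len(nw)] <- stats::rnorm(nw, 0, sqrt(2 / (9 * cin)))
        off <- off + nw + cout  # biases left at zero
      }
    }
  })
  structure(list(spec = spec, layers = layers, params = params,
                 version = 0L, norm_const = 1,
                 training_meta = list(epochs_seen = 0L, corpus_size = 0L,
                                      best_val_loss = NA_real_)),
            class = "ptycho_model")
}

#' Number of trainable parameters
#'
#' @param model A `ptycho_model`.
#' @return Integer count of trainable scalars (weights and biases).
#' @export
count_parameters <- function(model) length(model$params)

#' Normalize diffraction frames for the network
#'
#' Counts are multiplied by `scale_factor` (the intensity-upscaling knob used
#' to feed low-exposure frames to a model trained at higher counts), passed
#' through the model's input transform (square root by default), and divided
#' by the model's recorded normalization constant (the 99.9th percentile of
#' the transformed training corpus). No clipping is applied.
#'
#' @param frames Array (N, N, n) or single matrix of non-negative counts, or
#'   a `diffraction_stack`.
#' @param scale_factor Positive intensity multiplier (applied to counts,
#'   before the transform).
#' @param model Optional `ptycho_model` supplying `norm_const` and the
#'   input transform; when absent the explicit arguments are used.
#' @param norm_const Normalization divisor.
#' @param transform `"sqrt"` or `"intensity"`.
#' @return Array (N, N, n) of normalized network inputs.
#' @export
preprocess_frames <- function(frames, scale_factor = 1, model = NULL,
                              norm_const = 1,
                              transform = c("sqrt", "intensity")) {
  if (scale_factor <= 0) stop_invalid("scale_factor must be positive")
  if (!is.null(model)) {
    norm_const <- model$norm_const
    transform <- model$spec$input_transform
  }
  transform <- match.arg(transform)
  if (inherits(frames, "diffraction_stack")) frames <- frames$frames
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (any(frames < 0)) stop_invalid("negative counts in input frames")
  x <- frames * scale_factor
  if (transform == "sqrt") x <- sqrt(x)
  x / norm_const
}

#' Single-pass phase inference
#'
#' Runs the network in evaluation mode on a batch of preprocessed frames.
#' Outputs are bounded in \eqn{(-\pi, \pi)} by the final activation and
#' deterministic (inference mutates no state).
#'
#' @param model A `ptycho_model`.
#' @param batch Array (N, N, n) of normalized frames, N = spec input side.
#' @return Array (N, N, n) of phase patches in radians.
#' @export
infer <- function(model, batch) {
  if (is.matrix(batch)) batch <- array(batch, dim = c(dim(batch), 1L))
  d <- dim(batch)
  if (d[1] != model$spec$input_side || d[2] != model$spec$input_side)
    stop_invalid("batch side %d does not match spec input side %d",
                 d[1], model$spec$input_side)
  x <- array(batch, dim = c(d[1], d[2], 1L, d[3]))
  y <- nn_forward_cpp(x, model$layers, model$params)
  array(y, dim = c(d[1], d[2], d[3]))
}

## One MAE loss + gradient evaluation on a batch (flat-parameter interface
## used by the Adam loop in train_incremental).
nn_loss_grad <- function(model, x_batch, y_batch) {
  d <- dim(x_batch)
  x <- array(x_batch, dim = c(d[1], d[2], 1L, d[3]))
  t <- array(y_batch, dim = c(d[1], d[2], 1L, d[3]))
  nn_loss_grad_cpp(x, t, model$layers, model$params)
}
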