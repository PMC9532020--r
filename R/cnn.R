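#' Network architecture specification
#'
#' Defines the grouped-convolution CNN: three convolution + ReLU + max-pool
#' stages followed by a single linear layer to two logits and a softmax.
#' The default is the full-scale reference architecture for 19 x 45 x 100 inputs
#' (channels x frequencies x time):
#'
#' | layer | out maps | groups | kernel | output (C x F x T) | parameters |
#' |-------|---------:|-------:|--------|--------------------|-----------:|
#' | conv1 | 950  | 19 | 1 x 5 | 950 x 45 x 96  | 5,700 |
#' | pool1 | -    | -  | 1 x 2 x 2 | 950 x 22 x 48 | - |
#' | conv2 | 1900 | 50 | 5 x 5 | 1900 x 18 x 44 | 904,400 |
#' | pool2 | -    | -  | 1 x 2 x 2 | 1900 x 9 x 22 | - |
#' | conv3 | 150  | 1  | 3 x 3 | 150 x 7 x 20   | 2,565,150 |
#' | pool3 | -    | -  | 1 x 1 x 1 | 150 x 7 x 20 | - |
#' | fc    | -    | -  | -     | 2              | 42,000 |
#'
#' Convolutions are 2-D over (frequency, time) with channel grouping (the
#' first layer convolves each EEG channel separately), stride 1, no padding,
#' and carry biases; pooling kernels written `1 x 2 x 2` pool only the
#' spatial axes; the fully connected layer is bias-free, matching the
#' printed 21,000 x 2 = 42,000 parameter count.
#'
#' @param input_shape `c(channels, frequencies, time)` of the input tensor.
#' @param conv_out output feature maps of the three convolution layers.
#' @param groups channel groups of the three convolution layers.
#' @param kernels list of three `(kf, kt)` kernel sizes.
#' @param pools list of three `(pf, pt)` pooling kernels (stride = kernel).
#' @param n_classes number of output classes.
#' @param fc_bias does the linear layer carry a bias?
#' @return An `arch_spec` object.
#' @export
arch_spec <- function(input_shape = c(19, 45, 100),
                      conv_out = c(950, 1900, 150),
                      groups = c(19, 50, 1),
                      kernels = list(c(1, 5), c(5, 5), c(3, 3)),
                      pools = list(c(2, 2), c(2, 2), c(1, 1)),
                      n_classes = 2, fc_bias = FALSE) {
  spec <- structure(list(input_shape = input_shape, conv_out = conv_out,
                         groups = groups, kernels = kernels, pools = pools,
                         n_classes = n_classes, fc_bias = fc_bias),
                    class = "arch_spec")
  cin <- input_shape[1]
  for (l in 1:3) {
    stop_if_not(cin %% spec$groups[l] == 0,
                "conv", l, ": input maps (", cin,
                ") not divisible by groups (", spec$groups[l], ")",
                class = "eegannot_spec_error")
    stop_if_not(conv_out[l] %% spec$groups[l] == 0,
                "conv", l, ": output maps not divisible by groups",
                class = "eegannot_spec_error")
    cin <- conv_out[l]
  }
  shapes <- layer_output_shapes(spec)   # errors on non-positive dims
  stopifnot(length(shapes) > 0)
  spec
}

#' Reduced architecture for fast demonstrations
#'
#' Same layer structure, grouping pattern and kernel/pooling chain as the
#' full-scale architecture, with fewer feature maps (19 / 38 / 8). Used by the
#' package's examples, tests and the synthetic-data experiments, where the
#' full ~3.5 M-parameter network is unnecessarily large.
#' @return An `arch_spec`.
#' @export
demo_arch_spec <- function() {
  arch_spec(conv_out = c(19, 38, 8), groups = c(19, 19, 1))
}

#' Per-layer output shapes
#'
#' Computes the shape chain of a spec for its input shape, in the
#' channels x frequencies x time convention.
#'
#' @param spec an [arch_spec()].
#' @return Named list of `c(C, F, T)` shapes per layer, ending with the
#'   flattened fully connected input size and the class count.
#' @export
layer_output_shapes <- function(spec) {
  shp <- spec$input_shape
  out <- list()
  for (l in 1:3) {
    k <- spec$kernels[[l]]
    shp <- c(spec$conv_out[l], shp[2] - k[1] + 1, shp[3] - k[2] + 1)
    stop_if_not(all(shp > 0), "conv", l, " produces a non-positive dimension",
                class = "eegannot_spec_error")
    out[[paste0("conv", l)]] <- shp
    p <- spec$pools[[l]]
    shp <- c(shp[1], shp[2] %/% p[1], shp[3] %/% p[2])
    stop_if_not(all(shp > 0), "pool", l, " produces a non-positive dimension",
                class = "eegannot_spec_error")
    out[[paste0("pool", l)]] <- shp
  }
  out$fc_in <- prod(shp)
  out$fc <- spec$n_classes
  out
}

# PyTorch-convention Kaiming-uniform: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
# for both weights and biases (the leaky-ReLU a = sqrt(5) layer default).
kaiming_uniform <- function(n, fan_in) {
  bound <- 1 / sqrt(fan_in)
  stats::runif(n, -bound, bound)
}

#' Instantiate a model from an architecture spec
#'
#' Weights follow Kaiming-uniform initialisation (the standard convolution
#' layer default); construction is deterministic given `seed`.
#'
#' @param spec an [arch_spec()].
#' @param seed integer seed for the initial weights.
#' @return An `eeg_cnn` model object (class labels: column 1 = artifact,
#'   column 2 = nonartifact).
#' @export
build_model <- function(spec = arch_spec(), seed = 1) {
  shapes <- layer_output_shapes(spec)
  with_seed(mix_seed(seed, 55), {
    layers <- list()
    cin <- spec$input_shape[1]
    for (l in 1:3) {
      k <- spec$kernels[[l]]
      cin_g <- cin %/% spec$groups[l]
      fan_in <- cin_g * k[1] * k[2]
      W <- matrix(kaiming_uniform(fan_in * spec$conv_out[l], fan_in),
                  nrow = fan_in, ncol = spec$conv_out[l])
      b <- kaiming_uniform(spec$conv_out[l], fan_in)
      layers[[paste0("conv", l)]] <- list(W = W, b = b, kernel = k,
                                          groups = spec$groups[l])
      cin <- spec$conv_out[l]
    }
    fan_in <- shapes$fc_in
    layers$fc <- list(W = matrix(kaiming_uniform(spec$n_classes * fan_in, fan_in),
                                 nrow = spec$n_classes, ncol = fan_in),
                      b = if (spec$fc_bias) kaiming_uniform(spec$n_classes, fan_in)
                          else NULL)
    structure(list(spec = spec, layers = layers, classes =
                     c("artifact", "nonartifact")),
              class = "eeg_cnn")
  })
}

#' @export
print.eeg_cnn <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<eeg_cnn> input %s, %s trainable parameters\n",
              paste(x$spec$input_shape, collapse = "x"),
              format(pc$total, big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Enumerates the trainable arrays of each layer (pooling layers have none).
#'
#' @param model an `eeg_cnn`.
#' @return List with per-layer counts and `total`.
#' @export
count_parameters <- function(model) {
  counts <- lapply(model$layers, function(l) {
    length(l$W) + length(l$b)
  })
  counts$total <- sum(unlist(counts))
  counts
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' Runs a batch of time-frequency tensors through the network. Input layout
#' is `freq x time x channel x batch` (as produced by
#' [tensorize_recording()]).
#'
#' @param model an `eeg_cnn`.
#' @param x array `F x T x C x N` (a single `F x T x C` tensor is accepted).
#' @param training if `TRUE`, also return the per-layer activations needed
#'   for backpropagation.
#' @return List with `probs` (`N x 2` matrix, columns artifact/nonartifact
#'   summing to 1) and, when `training`, a `cache`.
#' @export
forward_cnn <- function(model, x, training = FALSE) {
  spec <- model$spec
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  stop_if_not(identical(as.integer(d[1:3]),
                        as.integer(spec$input_shape[c(2, 3, 1)])),
              "input tensor shape ", paste(d[1:3], collapse = "x"),
              " does not match the architecture input ",
              paste(spec$input_shape[c(2, 3, 1)], collapse = "x"),
              class = "eegannot_shape_error")
  cache <- list(x = x)
  a <- x
  for (l in 1:3) {
    ly <- model$layers[[paste0("conv", l)]]
    z <- cpp_conv2d_fwd(a, ly$W, ly$b, ly$kernel[1], ly$kernel[2], ly$groups)
    h <- relu(z)
    p <- spec$pools[[l]]
    if (all(p == 1)) {
      pooled <- list(y = h, idx = NULL)
    } else {
      pooled <- cpp_maxpool_fwd(h, p[1], p[2])
    }
    if (training) {
      cache[[paste0("conv", l)]] <- list(input = a, z = z, idx = pooled$idx,
                                         hdim = dim(h))
    }
    a <- pooled$y
  }
  n <- dim(a)[4]
  flat <- t(matrix(a, ncol = n))          # N x fc_in
  fc <- model$layers$fc
  logits <- flat %*% t(fc$W)
  if (!is.null(fc$b)) logits <- sweep(logits, 2, fc$b, "+")
  probs <- softmax_rows(logits)
  colnames(probs) <- model$classes
  if (training) {
    cache$flat <- flat
    cache$pooled_dim <- dim(a)
    list(probs = probs, logits = logits, cache = cache)
  } else {
    list(probs = probs, logits = logits)
  }
}

#' Artifact probability for a batch of tensors
#'
#' @param model an `eeg_cnn`.
#' @param tensors array `F x T x C x N`.
#' @param batch_size forward-pass batch size.
#' @return Numeric vector of artifact probabilities, one per segment.
#' @export
predict_proba <- function(model, tensors, batch_size = 256) {
  if (length(dim(tensors)) == 3) dim(tensors) <- c(dim(tensors), 1)
  n <- dim(tensors)[4]
  p <- numeric(n)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(n, i0 + batch_size - 1)
    p[idx] <- forward_cnn(model, tensors[, , , idx, drop = FALSE])$probs[, 1]
  }
  p
}

# Backward pass; dlogits is N x n_classes. Returns gradients per layer.
backward_cnn <- function(model, fwd, dlogits) {
  spec <- model$spec
  cache <- fwd$cache
  fc <- model$layers$fc
  grads <- list()
  grads$fc <- list(W = t(dlogits) %*% cache$flat,
                   b = if (!is.null(fc$b)) colSums(dlogits) else NULL)
  gflat <- dlogits %*% fc$W               # N x fc_in
  ga <- array(t(gflat), dim = cache$pooled_dim)
  for (l in 3:1) {
    cc <- cache[[paste0("conv", l)]]
    p <- spec$pools[[l]]
    gh <- if (all(p == 1)) ga else cpp_maxpool_bwd(cc$idx, ga, cc$hdim)
    gh[cc$z <= 0] <- 0
    ly <- model$layers[[paste0("conv", l)]]
    bw <- cpp_conv2d_bwd(cc$input, ly$W, gh, ly$kernel[1], ly$kernel[2],
                         ly$groups)
    grads[[paste0("conv", l)]] <- list(W = bw$gw, b = bw$gb)
    ga <- bw$gx
  }
  grads
}
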