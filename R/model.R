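# Single-modal DCNN feature extractors and the concatenation-fused
# multi-modal classifier.
#
# Each single-modal network is three 1-D convolution blocks (32/64/128
# filters of temporal extent 20, the first layer spanning the full channel
# width, valid padding, ReLU then batch normalization) followed by a
# two-hidden-layer fully connected head with dropout before the softmax
# output over the 7 gait classes. The multi-modal classifier concatenates
# the flattened convolutional feature vectors of independently trained
# single-modal networks (conv stacks frozen) and trains a fresh fully
# connected head on top.

#' Output length of a valid 1-D convolution
#'
#' Number of filter positions when a filter of temporal extent `H` slides
#' over `input_len` frames with stride `s` and no padding:
#' `floor((input_len - H) / s) + 1`.
#'
#' @param input_len input length in frames (>= H).
#' @param H filter height (temporal extent).
#' @param s stride (>= 1).
#' @return integer feature count.
#' @export
#' @examples
#' conv_output_length(63, 20, 1)   # 44
conv_output_length <- function(input_len, H, s = 1L) {
  abort_if(H < 1 || s < 1, "H and s must be >= 1")
  abort_if(input_len < H,
           "input length %d is shorter than the filter height %d", input_len, H)
  as.integer((input_len - H) %/% s + 1L)
}

#' Default stride for the first convolution layer
#'
#' Stride 1 for samples of one or two steps, stride 2 for three to five
#' steps (and beyond), applied to the first convolution layer only.
#'
#' @param k steps per sample.
#' @return integer stride.
#' @export
default_stride <- function(k) if (k <= 2) 1L else 2L

#' Training configuration
#'
#' Categorical cross-entropy loss minimized by Adam (adaptive momentum) with
#' learning rate 1e-4 and mini-batches of 32. The epoch budget defaults to
#' 50; optional early stopping monitors a held-out fraction of the training
#' set.
#'
#' @param learning_rate Adam learning rate (> 0; 0 is allowed and performs
#'   no updates, useful for diagnostics).
#' @param batch_size mini-batch size (>= 1).
#' @param epochs maximum training epochs.
#' @param seed integer seed controlling shuffling, dropout and weight
#'   initialization fallback.
#' @param validation_split fraction of training samples held out for the
#'   early-stopping monitor (0 disables).
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (NULL disables).
#' @param verbose print per-epoch losses.
#' @return an object of class `gait_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 32L, epochs = 50L,
                         seed = 1L, validation_split = 0,
                         early_stopping_patience = NULL, verbose = FALSE) {
  abort_if(learning_rate < 0, "learning_rate must be >= 0")
  abort_if(batch_size < 1, "batch_size must be >= 1")
  abort_if(epochs < 1, "epochs must be >= 1")
  structure(list(loss = "categorical_crossentropy", optimizer = "adam",
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 validation_split = validation_split,
                 early_stopping_patience = early_stopping_patience,
                 verbose = verbose),
            class = "gait_train_config")
}

#' Build a single-modal DCNN
#'
#' @param modality which sensor array the network consumes; any modality name
#'   present in the sample container (e.g. `"pressure"`, `"accel"`, `"gyro"`,
#'   or a per-foot split such as `"accel_left"`).
#' @param k steps per sample.
#' @param t normalized step length (input height is `t * k`).
#' @param width number of channels W of the modality (default: 16 for
#'   pressure, 6 otherwise).
#' @param n_filters filters per convolution layer.
#' @param filter_height temporal extent H of every filter.
#' @param stride first-layer stride; default chosen by [default_stride()]
#'   from `k`. Layers 2 and 3 always use stride 1.
#' @param fc_sizes sizes of the two fully connected hidden layers.
#' @param dropout dropout rate applied after the second hidden layer.
#' @param n_classes number of output classes.
#' @param seed seed for the Xavier-uniform weight initialization.
#' @return an object of class `gait_dcnn`.
#' @export
build_single_modal <- function(modality, k = 1L, t = 63L, width = NULL,
                               n_filters = c(32L, 64L, 128L), filter_height = 20L,
                               stride = NULL, fc_sizes = c(256L, 128L),
                               dropout = 0.5, n_classes = 7L, seed = 1L) {
  abort_if(length(n_filters) != 3, "expected three convolution layers")
  width <- width %||% if (identical(modality, "pressure")) N_PRESSURE else N_ACCEL
  stride <- stride %||% default_stride(k)
  in_len <- t * k
  n1 <- conv_output_length(in_len, filter_height, stride)
  n2 <- conv_output_length(n1, filter_height, 1L)
  n3 <- conv_output_length(n2, filter_height, 1L)
  feature_length <- n3 * n_filters[3]
  layers <- with_seed(seed, {
    c(list(new_conv_layer(filter_height, width, n_filters[1], stride),
           new_conv_layer(filter_height, n_filters[1], n_filters[2], 1L),
           new_conv_layer(filter_height, n_filters[2], n_filters[3], 1L),
           new_dense_layer(feature_length, fc_sizes[1]),
           new_dense_layer(fc_sizes[1], fc_sizes[2]),
           new_dropout_layer(dropout),
           new_dense_layer(fc_sizes[2], n_classes, activation = "linear")))
  })
  structure(list(modality = modality, k = as.integer(k), t = as.integer(t),
                 width = as.integer(width), stride = as.integer(stride),
                 feature_lengths = c(n1, n2, n3) * n_filters,
                 feature_length = as.integer(feature_length),
                 n_conv = 3L, layers = layers, n_classes = as.integer(n_classes),
                 fc_sizes = fc_sizes, dropout = dropout, trained = FALSE),
            class = "gait_dcnn")
}

#' @export
print.gait_dcnn <- function(x, ...) {
  cat(sprintf("<gait_dcnn> %s, k=%d, input (%d x %d), conv features %d, %strained\n",
              x$modality, x$k, x$t * x$k, x$width, x$feature_length,
              if (isTRUE(x$trained)) "" else "un"))
  invisible(x)
}

#' Build a concatenation-fused multi-modal DCNN
#'
#' Takes two or three (or more, with per-foot splits) trained single-modal
#' networks, freezes their convolution stacks, and attaches a fresh
#' two-hidden-layer fully connected head over the concatenated flattened
#' feature vectors.
#'
#' @param networks list of trained `gait_dcnn` objects sharing `k` and
#'   `n_classes`.
#' @param fc_sizes,dropout,seed head hyperparameters as in
#'   [build_single_modal()].
#' @return an object of class `gait_dcnn_multi`.
#' @export
build_multi_modal <- function(networks, fc_sizes = c(256L, 128L), dropout = 0.5,
                              seed = 1L) {
  abort_if(length(networks) < 2, "need at least two single-modal networks to fuse")
  abort_if(!all(vapply(networks, inherits, logical(1), "gait_dcnn")),
           "all parts must be single-modal gait_dcnn networks")
  ks <- vapply(networks, function(nw) nw$k, integer(1))
  abort_if(length(unique(ks)) != 1, "fused networks must share k (got %s)",
           paste(ks, collapse = ", "))
  ncl <- vapply(networks, function(nw) nw$n_classes, integer(1))
  abort_if(length(unique(ncl)) != 1, "fused networks must share n_classes")
  feature_length <- sum(vapply(networks, function(nw) nw$feature_length, integer(1)))
  head <- with_seed(seed, {
    list(new_dense_layer(feature_length, fc_sizes[1]),
         new_dense_layer(fc_sizes[1], fc_sizes[2]),
         new_dropout_layer(dropout),
         new_dense_layer(fc_sizes[2], ncl[1], activation = "linear"))
  })
  structure(list(parts = networks,
                 modalities = vapply(networks, function(nw) nw$modality, character(1)),
                 k = ks[1], feature_length = as.integer(feature_length),
                 head = head, n_classes = ncl[1], trained = FALSE),
            class = "gait_dcnn_multi")
}

#' @export
print.gait_dcnn_multi <- function(x, ...) {
  cat(sprintf("<gait_dcnn_multi> %s, k=%d, fused features %d, %strained\n",
              paste(x$modalities, collapse = "+"), x$k, x$feature_length,
              if (isTRUE(x$trained)) "" else "un"))
  invisible(x)
}

get_modality_array <- function(samples, modality) {
  if (inherits(samples, "gait_samples")) {
    abort_if(!modality %in% modality_names(samples),
             "samples do not carry modality '%s'", modality)
    samples[[modality]]
  } else samples
}

get_labels1 <- function(samples, n_classes) {
  abort_if(!inherits(samples, "gait_samples"), "expected a gait_samples object")
  y1 <- samples$label + 1L
  abort_if(any(y1 < 1 | y1 > n_classes), "labels outside 0..%d", n_classes - 1L)
  y1
}

#' Train a network
#'
#' Mini-batch backpropagation with Adam on categorical cross-entropy.
#' Training samples are expected to be standardized (see
#' [standardize_samples()]). For a multi-modal network the frozen
#' single-modal convolution stacks are applied once to extract features and
#' only the fused fully connected head is trained. Deterministic for a fixed
#' seed and platform.
#'
#' @param network a `gait_dcnn` or `gait_dcnn_multi`.
#' @param samples a `gait_samples` with the network's modalit(y/ies).
#' @param config a [train_config()].
#' @return the trained network with `$loss_history` (per-epoch mean training
#'   loss) and, if a validation split was used, `$val_loss_history`.
#' @export
train_model <- function(network, samples, config = train_config()) {
  UseMethod("train_model")
}

#' @export
train_model.gait_dcnn <- function(network, samples, config = train_config()) {
  x <- get_modality_array(samples, network$modality)
  abort_if(dim(x)[1] == 0, "training set is empty")
  abort_if(dim(x)[2] != network$t * network$k || dim(x)[3] != network$width,
           "sample array (%d x %d) does not match the network input (%d x %d)",
           dim(x)[2], dim(x)[3], network$t * network$k, network$width)
  y1 <- get_labels1(samples, network$n_classes)
  res <- with_seed(config$seed, train_layers(network$layers, x, y1, config))
  network$layers <- res$layers
  network$loss_history <- res$history
  network$val_loss_history <- res$val_history
  network$trained <- TRUE
  network
}

#' @export
train_model.gait_dcnn_multi <- function(network, samples, config = train_config()) {
  feats <- do.call(cbind, lapply(network$parts, extract_features, samples = samples))
  y1 <- get_labels1(samples, network$n_classes)
  res <- with_seed(config$seed, train_layers(network$head, feats, y1, config))
  network$head <- res$layers
  network$loss_history <- res$history
  network$val_loss_history <- res$val_history
  network$trained <- TRUE
  network
}

#' Extract flattened convolutional feature vectors
#'
#' Runs the (trained) convolution stack of a single-modal network in
#' inference mode and returns the post-flatten, pre-fully-connected
#' activations.
#'
#' @param network a `gait_dcnn`.
#' @param samples a `gait_samples` (or a raw `(n, t*k, W)` array).
#' @return numeric matrix `n x feature_length`.
#' @export
extract_features <- function(network, samples) {
  abort_if(inherits(network, "gait_dcnn_multi"),
           "features are per-modality; extract from the single-modal parts")
  abort_if(!inherits(network, "gait_dcnn"), "expected a gait_dcnn")
  x <- get_modality_array(samples, network$modality)
  fw <- layers_forward(network$layers[seq_len(network$n_conv)], x, train = FALSE)
  out <- fw$out
  dim(out) <- c(dim(out)[1], dim(out)[2] * dim(out)[3])
  out
}

#' Predict gait classes
#'
#' Forward pass in inference mode (running batch-norm statistics, no
#' dropout). Samples must have been standardized with the training-set
#' transform.
#'
#' @param object a `gait_dcnn` or `gait_dcnn_multi`.
#' @param samples a `gait_samples` (or raw array for single-modal networks).
#' @param ... unused.
#' @return list with `prob` (n x n_classes row-stochastic matrix, columns
#'   named by gait type), `code` (0-based argmax class codes, ties broken by
#'   the lowest code) and `label` (class names).
#' @export
predict.gait_dcnn <- function(object, samples, ...) {
  x <- get_modality_array(samples, object$modality)
  fw <- layers_forward(object$layers, x, train = FALSE)
  finish_prediction(fw$out, object$n_classes)
}

#' @rdname predict.gait_dcnn
#' @export
predict.gait_dcnn_multi <- function(object, samples, ...) {
  feats <- do.call(cbind, lapply(object$parts, extract_features, samples = samples))
  fw <- layers_forward(object$head, feats, train = FALSE)
  finish_prediction(fw$out, object$n_classes)
}

finish_prediction <- function(logits, n_classes) {
  prob <- softmax_rows(logits)
  if (n_classes == 7) colnames(prob) <- gait_types()
  code <- max.col(prob, ties.method = "first") - 1L
  list(prob = prob, code = code,
       label = if (n_classes == 7) gait_label_name(code) else as.character(code))
}
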