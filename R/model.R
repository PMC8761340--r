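#' Multi-view network configuration
#'
#' Architectural hyperparameters of the multi-view CNN. Each of the six
#' branches (3 views x 2 scales) is conv 3x3 (batch norm, ReLU), max pool
#' 2x2, dropout, dense ReLU; branch outputs are concatenated and passed
#' through a dense ReLU layer and a 2-way softmax. Patch geometry (32x32,
#' 3 channels, 3 views, 2 scales) is fixed; hidden widths are configurable
#' with the package defaults below.
#'
#' @param conv_filters convolution filters per branch (default 32).
#' @param dense_units_branch branch dense width (default 64).
#' @param dense_units_head head dense width (default 128).
#' @param dropout_rate dropout fraction after pooling (default 0.25).
#' @return An object of class `mvseg_model_config`.
#' @export
model_config <- function(conv_filters = 32L, dense_units_branch = 64L,
                         dense_units_head = 128L, dropout_rate = 0.25) {
  stopifnot(conv_filters >= 1, dense_units_branch >= 1, dense_units_head >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_units_branch = as.integer(dense_units_branch),
                 dense_units_head = as.integer(dense_units_head),
                 dropout_rate = dropout_rate,
                 kernel = c(3L, 3L), pool = c(2L, 2L), n_classes = 2L,
                 n_views = 3L, n_scales = 2L, n_channels = 3L),
            class = "mvseg_model_config")
}

#' Initialize multi-view CNN parameters
#'
#' He-normal initialization for weights, unit gamma / zero beta for batch
#' norm, zero biases. The six branches are independent (no weight sharing
#' between views or scales). Deterministic under a fixed seed. The
#' convolution carries no bias because batch norm follows it directly.
#'
#' @param cfg an [model_config()].
#' @param seed integer seed.
#' @return An object of class `mvseg_params`: named list of parameter
#'   matrices plus the config as attribute `config`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mvseg_model_config"))
  set.seed(seed)
  F <- cfg$conv_filters; D1 <- cfg$dense_units_branch
  D2 <- cfg$dense_units_head
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  p <- list()
  for (b in 1:6) {
    p[[paste0("Wc", b)]] <- he(F, 27L, 27)
    p[[paste0("gamma", b)]] <- matrix(1, F, 1)
    p[[paste0("beta", b)]] <- matrix(0, F, 1)
    p[[paste0("rmean", b)]] <- matrix(0, F, 1)
    p[[paste0("rvar", b)]] <- matrix(1, F, 1)
    p[[paste0("Wd", b)]] <- he(D1, 256L * F, 256 * F)
    p[[paste0("bd", b)]] <- matrix(0, D1, 1)
  }
  p$Wh <- he(D2, 6L * D1, 6 * D1)
  p$bh <- matrix(0, D2, 1)
  # zero-initialized output layer: the softmax starts at p = 0.5 with
  # balanced gradients, which keeps the soft-dice loss out of its saturated
  # all-positive fixed point during the first optimization steps
  p$Wo <- matrix(0, 2L, D2)
  p$bo <- matrix(0, 2L, 1)
  structure(p, config = cfg, class = "mvseg_params")
}

#' Number of trainable parameters
#'
#' Counts the elements of the trainable tensors (running batch-norm statistics
#' excluded).
#'
#' @param params an [build_model()] result.
#' @return Integer count.
#' @export
n_params <- function(params) {
  train <- grep("^(rmean|rvar)", names(params), invert = TRUE, value = TRUE)
  sum(vapply(train, function(nm) length(params[[nm]]), integer(1)))
}

#' Forward pass on patch sets
#'
#' Computes per-item class probabilities (non-tumor, tumor). In inference
#' mode (default) batch norm uses running statistics and dropout is off, so
#' the output is deterministic and independent of batch composition.
#'
#' @param params an [build_model()] result (possibly trained).
#' @param patchsets a single [extract_patchset()] result or a list of them.
#' @param training_mode if `TRUE`, use batch statistics and active dropout.
#' @param seed dropout seed used only in training mode.
#' @return n x 2 matrix of probabilities, rows summing to 1.
#' @export
forward <- function(params, patchsets, training_mode = FALSE, seed = 1L) {
  stopifnot(inherits(params, "mvseg_params"))
  if (inherits(patchsets, "mvseg_patchset")) patchsets <- list(patchsets)
  X <- patchsets_to_blocks(patchsets)
  cfg <- attr(params, "config")
  pr <- cpp_mvcnn_forward_patches(X, params, cfg, training_mode,
                                  as.double(seed))
  out <- t(pr)
  colnames(out) <- c("non_tumor", "tumor")
  out
}

#' Batch soft-dice loss
#'
#' Differentiable relaxation of 1 - DSC computed over all voxels in a batch:
#' `1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)` with `p` the
#' predicted tumor-class probabilities and `g` the binary labels.
#'
#' @param pred_tumor_probs numeric vector of probabilities in \[0, 1\].
#' @param labels binary vector of the same length.
#' @param epsilon stabilizer; default 1e-7.
#' @return Scalar loss in \[0, 1\].
#' @export
softdice_loss <- function(pred_tumor_probs, labels, epsilon = 1e-7) {
  if (length(pred_tumor_probs) != length(labels))
    stop("probabilities and labels must have equal length")
  if (length(labels) < 1L) stop("batch must be non-empty")
  if (any(pred_tumor_probs < 0 | pred_tumor_probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  1 - (2 * sum(pred_tumor_probs * labels) + epsilon) /
    (sum(pred_tumor_probs) + sum(labels) + epsilon)
}

#' Save or load a model checkpoint
#'
#' One archive per fold holding the parameters (with running statistics), the
#' architecture config, and optionally the loss history; the round trip is
#' exact.
#'
#' @param params an `mvseg_params` object.
#' @param path checkpoint file path.
#' @param history optional numeric loss history.
#' @return `path` (save) or the `mvseg_params` with attribute `history`
#'   (load).
#' @export
save_checkpoint <- function(params, path, history = NULL) {
  stopifnot(inherits(params, "mvseg_params"))
  saveRDS(list(config = attr(params, "config"),
               params = unclass_params(params), history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  p <- ck$params
  attr(p, "config") <- ck$config
  attr(p, "history") <- ck$history
  class(p) <- "mvseg_params"
  p
}

unclass_params <- function(params) {
  out <- unclass(params)
  attr(out, "config") <- NULL
  attr(out, "history") <- NULL
  out
}
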