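#' Architecture configuration for the Patterson-to-density U-net
#'
#' The network has three phases. Encoding: two 7^3 convolutions
#' (1 -> enc_channels[1] -> enc_channels[2]), each with batch normalization
#' and ReLU, then 2^3 stride-2 max pooling. Learning Features:
#' \code{n_res_blocks} residual blocks at \code{enc_channels[2]} channels
#' (7^3 conv + BN + ReLU, 7^3 conv + BN, optional squeeze-and-excitation
#' gate, skip addition, ReLU), then nearest-neighbour 2x upsampling.
#' Decoding: a 5^3 convolution to \code{dec_channels} with BN + ReLU and a
#' final 5^3 convolution to one channel followed by tanh. Encoding and
#' Learning Features convolutions use circular (periodic) same-padding to
#' respect the periodicity of Patterson maps; Decoding uses zero padding.
#'
#' The default widths (23, 25 with seven blocks) give about three million
#' trainable parameters. The enlarged profile used for the all-residue
#' dataset is \code{model_config(enc_channels = c(25, 30), n_res_blocks = 8,
#' use_se = TRUE, dec_channels = 25)}.
#'
#' @param enc_channels Widths of the two Encoding convolutions.
#' @param n_res_blocks Number of residual blocks.
#' @param use_se Add squeeze-and-excitation gates to the residual blocks?
#' @param se_reduction Channel reduction factor inside the SE bottleneck.
#' @param dec_channels Width of the first Decoding convolution.
#' @param kernel_enc,kernel_dec Odd kernel sizes for the Encoding/Learning
#'   Features and Decoding convolutions.
#' @return A \code{model_config} object.
#' @export
model_config <- function(enc_channels = c(23, 25), n_res_blocks = 7,
                         use_se = FALSE, se_reduction = 2,
                         dec_channels = 23, kernel_enc = 7, kernel_dec = 5) {
  stopifnot(length(enc_channels) == 2, all(enc_channels >= 1),
            n_res_blocks >= 1, dec_channels >= 1,
            kernel_enc %% 2 == 1, kernel_dec %% 2 == 1, se_reduction >= 1)
  structure(list(enc_channels = as.integer(enc_channels),
                 res_channels = as.integer(enc_channels[2]),
                 n_res_blocks = as.integer(n_res_blocks),
                 use_se = isTRUE(use_se),
                 se_reduction = as.integer(se_reduction),
                 dec_channels = as.integer(dec_channels),
                 kernel_enc = as.integer(kernel_enc),
                 kernel_dec = as.integer(kernel_dec)),
            class = "model_config")
}

#' Build the 3D residual U-net
#'
#' Convolution weights are drawn with He-normal initialization (sd =
#' sqrt(2 / fan_in)), biases start at zero, batch-normalization scale/shift
#' at 1/0. Construction is deterministic in \code{seed}.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A \code{patterson_model}.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ke <- config$kernel_enc; kd <- config$kernel_dec
  e1 <- config$enc_channels[1]; e2 <- config$enc_channels[2]
  layers <- list(
    .layer_conv(ke, 1L, e1, circular = TRUE),
    .layer_bn(e1),
    .layer_simple("relu"),
    .layer_conv(ke, e1, e2, circular = TRUE),
    .layer_bn(e2),
    .layer_simple("relu"),
    .layer_simple("maxpool"))
  for (i in seq_len(config$n_res_blocks)) {
    layers[[length(layers) + 1L]] <-
      .layer_resblock(ke, e2, config$use_se, config$se_reduction)
  }
  layers[[length(layers) + 1L]] <- .layer_simple("upsample")
  layers[[length(layers) + 1L]] <- .layer_conv(kd, e2, config$dec_channels,
                                               circular = FALSE)
  layers[[length(layers) + 1L]] <- .layer_bn(config$dec_channels)
  layers[[length(layers) + 1L]] <- .layer_simple("relu")
  layers[[length(layers) + 1L]] <- .layer_conv(kd, config$dec_channels, 1L,
                                               circular = FALSE)
  layers[[length(layers) + 1L]] <- .layer_simple("tanh")
  structure(list(config = config, layers = layers, seed = seed),
            class = "patterson_model")
}

#' @export
print.patterson_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<patterson_model: 1->%d->%d enc | %d res blocks @%d%s | dec %d->1 | %s params>\n",
    cfg$enc_channels[1], cfg$enc_channels[2], cfg$n_res_blocks,
    cfg$res_channels, if (cfg$use_se) "+SE" else "",
    cfg$dec_channels, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Includes convolution weights and biases, batch-normalization scale and
#' shift, and squeeze-and-excitation weights; running statistics are not
#' trainable and are not counted.
#'
#' @param model A \code{patterson_model}.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(.model_params(model), length, numeric(1)))
}

# flat named list of all trainable parameter arrays
.layer_params <- function(layer) {
  switch(layer$type,
    conv = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    se = list(W1 = layer$W1, b1 = layer$b1, W2 = layer$W2, b2 = layer$b2),
    resblock = {
      out <- list()
      for (nm in c("conv1", "bn1", "conv2", "bn2", "se")) {
        sub <- layer[[nm]]
        if (is.null(sub)) next
        p <- .layer_params(sub)
        names(p) <- paste0(nm, ".", names(p))
        out <- c(out, p)
      }
      out
    },
    list())
}

.model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    p <- .layer_params(model$layers[[i]])
    if (length(p)) {
      names(p) <- paste0("L", i, ".", names(p))
      out <- c(out, p)
    }
  }
  out
}

.model_set_params <- function(model, params) {
  for (nm in names(params)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^L", "", path[1]))
    if (length(path) == 2L) {
      model$layers[[i]][[path[2]]] <- params[[nm]]
    } else {
      model$layers[[i]][[path[2]]][[path[3]]] <- params[[nm]]
    }
  }
  model
}

# flatten the per-layer gradient structure returned by .model_backward into
# the same naming as .model_params
.flatten_grads <- function(grads_by_layer) {
  out <- list()
  for (i in seq_along(grads_by_layer)) {
    g <- grads_by_layer[[i]]
    if (is.null(g)) next
    if (all(names(g) %in% c("W", "b", "gamma", "beta",
                            "W1", "b1", "W2", "b2"))) {
      names(g) <- paste0("L", i, ".", names(g))
      out <- c(out, g)
    } else {
      for (nm in names(g)) {
        sub <- g[[nm]]
        if (is.null(sub)) next
        names(sub) <- paste0("L", i, ".", nm, ".", names(sub))
        out <- c(out, sub)
      }
    }
  }
  out
}

# full forward pass over a batch (5D array). Returns the output, per-layer
# caches for backprop, and the model with refreshed BN running statistics
# when training.
.model_forward <- function(model, x, training = FALSE, upto = NULL) {
  n_layers <- if (is.null(upto)) length(model$layers) else upto
  caches <- vector("list", n_layers)
  h <- x
  for (i in seq_len(n_layers)) {
    layer <- model$layers[[i]]
    f <- .layer_fwd(layer, h, training)
    caches[[i]] <- list(cache = f$cache, out = if (layer$type == "tanh")
      f$out else NULL)
    if (training && !is.null(f$batch_stats)) {
      if (layer$type == "bn") {
        model$layers[[i]] <- .bn_update_running(layer, f$batch_stats)
      } else if (layer$type == "resblock") {
        model$layers[[i]]$bn1 <- .bn_update_running(layer$bn1,
                                                    f$batch_stats$bn1)
        model$layers[[i]]$bn2 <- .bn_update_running(layer$bn2,
                                                    f$batch_stats$bn2)
      }
    }
    h <- f$out
  }
  list(out = h, caches = caches, model = model)
}

.model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    b <- .layer_bwd(model$layers[[i]], d, caches[[i]]$cache,
                    out = caches[[i]]$out)
    if (!is.null(b$grads)) grads[[i]] <- b$grads
    d <- b$dx
  }
  list(dx = d, grads = .flatten_grads(grads))
}

# validate and stack voxel maps / arrays into a 5D batch c(nx,ny,nz,1,N)
.as_batch <- function(x) {
  if (inherits(x, "voxel_map")) x <- list(x)
  if (is.list(x)) {
    arrs <- lapply(x, function(m) if (inherits(m, "voxel_map")) m$values
                   else as.array(m))
    d <- dim(arrs[[1]])
    batch <- array(0, c(d, 1, length(arrs)))
    for (i in seq_along(arrs)) batch[, , , 1, i] <- arrs[[i]]
    return(batch)
  }
  x <- as.array(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x)[1:3], 1L, dim(x)[4])
  x
}

#' Predict an electron density from a Patterson map
#'
#' Runs the network in evaluation mode (batch normalization uses running
#' statistics), so repeated calls are deterministic. The input grid must
#' have even voxel counts on every axis (required by the 2x pooling) and is
#' propagated to the output map.
#'
#' @param object A \code{patterson_model}.
#' @param patterson A [voxel_map()] (role patterson, normalized to [-1, 1])
#'   or a 3D array.
#' @param ... Unused.
#' @return A [voxel_map()] with role \code{"density"} holding the predicted
#'   density in (-1, 1).
#' @export
predict.patterson_model <- function(object, patterson, ...) {
  grid <- if (inherits(patterson, "voxel_map")) patterson$grid else NULL
  x <- .as_batch(patterson)
  d <- dim(x)
  if (any(d[1:3] %% 2 != 0)) {
    stop("input axes must have even voxel counts (2x pooling)",
         call. = FALSE)
  }
  out <- .model_forward(object, x, training = FALSE)$out
  vals <- array(out[, , , 1, 1], d[1:3])
  if (is.null(grid)) return(vals)
  voxel_map(grid, vals, "density")
}

#' Forward pass through the periodic sub-network
#'
#' Runs only the Encoding and Learning Features phases (through the final
#' upsampling), whose circular padding makes them equivariant to circular
#' shifts of the input by even offsets. Exposed for equivariance checks.
#'
#' @param model A \code{patterson_model}.
#' @param x A 3D array or [voxel_map()].
#' @return A 4D array of feature maps (nx, ny, nz, channels).
#' @export
forward_features <- function(model, x) {
  types <- vapply(model$layers, function(l) l$type, character(1))
  upto <- which(types == "upsample")
  out <- .model_forward(model, .as_batch(x), training = FALSE,
                        upto = upto)$out
  array(out[, , , , 1], dim(out)[1:4])
}

#' Save / load a model checkpoint with its configuration embedded
#' @param model A \code{patterson_model}.
#' @param path File path (RDS).
#' @return \code{path} invisibly, or the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "patterson_model"))
  model
}
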