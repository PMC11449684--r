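# The runtime model keeps feature tensors as (H*W*N) x C matrices whose
# rows enumerate (row h fastest, then column w, then sample n).  A
# convolution is then one GEMM against an im2col patch matrix; batch
# normalization is columnwise; pooling is handled by the C++ kernels.

#' Build a trainable network from a specification
#'
#' Instantiates the declarative [network_spec()] with a concrete
#' activation and seeded initial weights: He (fan-in) normal
#' initialization for convolution and fully connected weights, zero
#' biases, batch-normalization scale 1 / offset 0, running mean 0 /
#' variance 1.  Two builds with the same seed are bit-identical.
#'
#' @param net A [network_spec()].
#' @param act An [activation_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model`.
#' @export
build_network <- function(net, act, seed = 1L) {
  stopifnot(inherits(net, "network_spec"), inherits(act, "activation_spec"))
  shp <- forward_shapes(net)
  layers <- list()
  si <- 1L  # row in shp giving the *input* shape of the next spatial layer
  with_seed_(seed, {
    for (l in net$layers) {
      rt <- list(kind = l$kind, name = l$name)
      if (l$kind == "conv") {
        fan_in <- prod(l$kernel) * l$in_channels
        rt$W <- matrix(rnorm(l$filters * fan_in, 0, sqrt(2 / fan_in)),
                       nrow = l$filters)
        rt$b <- numeric(l$filters)
        rt$k <- l$kernel[1]; rt$stride <- l$stride[1]; rt$pad <- l$padding
        rt$in_shape <- unlist(shp[si, c("H", "W", "C")])
        si <- si + 1L
      } else if (l$kind == "batchnorm") {
        rt$gamma <- rep(1, l$channels); rt$beta <- numeric(l$channels)
        rt$running_mean <- numeric(l$channels)
        rt$running_var <- rep(1, l$channels)
        rt$momentum <- 0.1; rt$eps <- 1e-5
      } else if (l$kind == "maxpool") {
        rt$k <- l$kernel[1]; rt$stride <- l$stride[1]
        rt$in_shape <- unlist(shp[si, c("H", "W", "C")])
        si <- si + 1L
      } else if (l$kind == "fully_connected") {
        rt$W <- matrix(rnorm(l$out_units * l$in_features, 0,
                             sqrt(2 / l$in_features)),
                       nrow = l$out_units)
        rt$b <- numeric(l$out_units)
        rt$in_shape <- unlist(shp[nrow(shp), c("H", "W", "C")])
      }
      layers[[length(layers) + 1L]] <- rt
    }
  })
  structure(list(spec = net, activation = act, layers = layers,
                 seed = as.integer(seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> ", paste(x$spec$input_shape, collapse = "x"),
      " input, activation: ", x$activation$name,
      ", ", n_parameters(x), " trainable parameters\n", sep = "")
  invisible(x)
}

#' Total number of trainable parameters of a built model
#'
#' Counts every element of the convolution and fully connected weights
#' and biases and the batch-normalization scales and offsets (running
#' statistics are excluded: they are state, not learnables).
#'
#' @param model A [build_network()] model.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$layers, function(l) {
    switch(l$kind,
           conv = length(l$W) + length(l$b),
           fully_connected = length(l$W) + length(l$b),
           batchnorm = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
}

# (H, W, C, N) array -> (H*W*N) x C matrix in the canonical row order.
as_feature_matrix_ <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

out_hw_ <- function(hw, k, stride, pad) (hw + 2 * pad - k) %/% stride + 1

# Forward pass over the matrix representation.
# Returns list(logits, probs, caches) where caches is non-NULL only when
# training = TRUE (caches are needed for the backward pass and Grad-CAM).
forward_ <- function(model, x, training = FALSE, keep_cache = training) {
  d <- dim(x)
  in_shape <- model$spec$input_shape
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4 || any(d[1:3] != in_shape))
    stop("input images must be ", paste(in_shape, collapse = "x"),
         " (got ", paste(d, collapse = "x"), ")", call. = FALSE)
  n <- d[4]
  cur <- as_feature_matrix_(x)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    cache <- NULL
    if (l$kind == "conv") {
      hwc <- l$in_shape
      cols <- im2col_nchw(cur, hwc[1], hwc[2], n, l$k, l$stride, l$pad)
      cur <- crossprod(cols, t(l$W))       # L x filters, no big transpose
      for (j in seq_len(ncol(cur))) cur[, j] <- cur[, j] + l$b[j]
      if (keep_cache) cache <- list(cols = cols)
      rm(cols)
    } else if (l$kind == "batchnorm") {
      if (training) {
        bn <- bn_train_cpp(cur, l$gamma, l$beta, l$eps)
        cur <- bn$y
        if (keep_cache) cache <- list(xhat = bn$xhat, inv_sd = bn$inv_sd,
                                      batch_mean = bn$mean,
                                      batch_var = bn$var)
        rm(bn)
      } else {
        cur <- bn_infer_cpp(cur, l$gamma, l$beta, l$running_mean,
                            l$running_var, l$eps)
      }
    } else if (l$kind == "activation") {
      if (keep_cache) cache <- list(x = cur)
      cur <- act_fwd_(model$activation, cur)
    } else if (l$kind == "maxpool") {
      hwc <- l$in_shape
      mp <- maxpool_fwd(cur, hwc[1], hwc[2], n, l$k, l$stride)
      if (keep_cache) cache <- list(idx = mp$idx, in_rows = nrow(cur),
                                    in_dims = c(hwc[1], hwc[2], n))
      cur <- mp$out
    } else if (l$kind == "fully_connected") {
      hwc <- l$in_shape
      a <- cur
      dim(a) <- c(hwc[1], hwc[2], n, hwc[3])
      a <- aperm(a, c(1, 2, 4, 3))
      dim(a) <- c(prod(hwc), n)
      flat <- t(a)                       # n x D
      cur <- flat %*% t(l$W) + matrix(l$b, n, length(l$b), byrow = TRUE)
      if (keep_cache) cache <- list(flat = flat)
    }
    # input/softmax/classification carry no computation here: softmax is
    # applied once below so that the loss can use stable log-softmax.
    if (keep_cache && !is.null(cache)) caches[[li]] <- cache
  }
  logits <- cur
  e <- exp(logits - apply(logits, 1, max))
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, caches = caches, n = n)
}

# Backward pass from d(loss)/d(logits); returns gradients shaped like the
# model's parameters: list per layer with the same field names.
backward_ <- function(model, fw, dlogits) {
  grads <- vector("list", length(model$layers))
  g <- dlogits
  n <- fw$n
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (l$kind == "fully_connected") {
      grads[[li]] <- list(W = t(g) %*% cache$flat, b = colSums(g))
      g <- g %*% l$W                     # n x D
      hwc <- l$in_shape
      a <- t(g)                          # D x n
      dim(a) <- c(hwc[1], hwc[2], hwc[3], n)
      a <- aperm(a, c(1, 2, 4, 3))
      dim(a) <- c(hwc[1] * hwc[2] * n, hwc[3])
      g <- a
    } else if (l$kind == "maxpool") {
      g <- maxpool_bwd(g, cache$idx, cache$in_rows)
    } else if (l$kind == "activation") {
      s <- model$activation
      gm <- act_bwd_mul_cpp(act_code_(s$name), cache$x, g, s$slope,
                            s$ceiling, s$alpha, s$gelu_constant)
      attributes(gm) <- attributes(g)
      g <- gm
      rm(gm)
    } else if (l$kind == "batchnorm") {
      bb <- bn_bwd_cpp(g, cache$xhat, l$gamma, cache$inv_sd)
      grads[[li]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      g <- bb$dx
      rm(bb)
    } else if (l$kind == "conv") {
      hwc <- l$in_shape
      cols <- fw$caches[[li]]$cols
      grads[[li]] <- list(W = t(cols %*% g), b = colSums(g))
      rm(cols)
      if (li > 2L) {  # no input gradient needed below the first conv
        dcols <- tcrossprod(t(l$W), g)    # (k*k*C) x L
        g <- col2im_nchw(dcols, hwc[1], hwc[2], n, hwc[3], l$k, l$stride,
                         l$pad)
        rm(dcols)
      }
    }
  }
  grads
}

#' Class probabilities and predicted labels
#'
#' Runs the model in inference mode (batch normalization uses running
#' statistics) over a stack of preprocessed images.
#'
#' @param object A `cnn_model`.
#' @param images `(H, W, C, N)` array (or a [labeled_image_set()]).
#' @param batch_size Images per forward batch (memory control).
#' @param ... Unused.
#' @return List with `probs` (`N x K` matrix of softmax probabilities,
#'   rows summing to 1) and `labels` (integer predictions in `1..K`,
#'   lowest index winning ties).
#' @export
predict.cnn_model <- function(object, images, batch_size = 32L, ...) {
  if (inherits(images, "labeled_image_set")) images <- images$images
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  k <- object$spec$num_classes
  probs <- matrix(NA_real_, n, k)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    fw <- forward_(object, images[, , , sel, drop = FALSE],
                   training = FALSE, keep_cache = FALSE)
    probs[sel, ] <- fw$probs
  }
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}
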