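#' Grad-CAM class activation heat map
#'
#' Computes a gradient-weighted class activation map from the third
#' (last) convolution block's activation output -- the final spatial
#' representation before pooling into the classifier head.  Channel
#' weights are the spatial means of the gradient of the target class's
#' pre-softmax score with respect to those activation maps; the map is
#' the rectified (ReLU) weighted sum of the maps, upsampled bilinearly to
#' the input size and min-max normalized to `[0, 1]`.  Gradients are
#' taken on the pre-softmax logits (softmax gradients saturate), with
#' batch normalization in inference mode.
#'
#' @param model A trained (or at least initialized) `cnn_model`.
#' @param image A single `(H, W, C)` image matching the model input.
#' @param target_class Integer class index in `1..K`.
#' @return An object of class `heatmap_cam`: list with `values` (an
#'   `H x W` matrix in `[0, 1]` aligned to the input), `target_class`,
#'   and `all_zero` (`TRUE` when the raw rectified map was identically
#'   zero, in which case `values` is all zeros).
#' @export
grad_cam <- function(model, image, target_class) {
  stopifnot(inherits(model, "cnn_model"))
  k <- model$spec$num_classes
  if (!(target_class >= 1 && target_class <= k))
    stop("'target_class' must lie in 1..", k, call. = FALSE)
  if (length(dim(image)) != 3)
    stop("'image' must be a single (H, W, C) array", call. = FALSE)
  x <- image; dim(x) <- c(dim(image), 1L)

  # inference-mode forward with caches kept
  fw <- forward_(model, x, training = FALSE, keep_cache = TRUE)

  layers <- model$layers
  kinds <- vapply(layers, `[[`, "", "kind")
  fc_i <- which(kinds == "fully_connected")
  pool_i <- max(which(kinds == "maxpool"))
  act_i <- max(which(kinds == "activation"))

  # d(logit_c)/d(flattened features) -> through the pooling layer ->
  # gradient with respect to the last activation maps A
  fc <- layers[[fc_i]]
  g <- matrix(fc$W[target_class, ], nrow = 1)        # 1 x D
  hwc <- fc$in_shape
  a <- t(g); dim(a) <- c(hwc[1], hwc[2], hwc[3], 1L)
  a <- aperm(a, c(1, 2, 4, 3)); dim(a) <- c(hwc[1] * hwc[2], hwc[3])
  pc <- fw$caches[[pool_i]]
  dA <- maxpool_bwd(a, pc$idx, pc$in_rows)           # (h*w) x C

  A <- activate(model$activation, fw$caches[[act_i]]$x)  # (h*w) x C
  alpha <- colMeans(dA)                              # channel weights
  raw <- pmax(as.vector(A %*% alpha), 0)
  hw <- layers[[pool_i]]$in_shape
  cam <- matrix(raw, hw[1], hw[2])

  all_zero <- max(cam) == 0
  if (!all_zero) {
    img <- EBImage::resize(EBImage::Image(t(cam)),
                           w = dim(image)[2], h = dim(image)[1])
    cam <- t(EBImage::imageData(img))
    cam <- pmax(cam, 0)
    cam <- (cam - min(cam)) / (max(cam) - min(cam))
  } else {
    cam <- matrix(0, dim(image)[1], dim(image)[2])
  }
  structure(list(values = cam, target_class = as.integer(target_class),
                 all_zero = all_zero),
            class = "heatmap_cam")
}

#' Save a Grad-CAM overlay image
#'
#' Blends the heat map (red channel) over the grayscale input and writes
#' a PNG.
#'
#' @param cam A [grad_cam()] result.
#' @param image The `(H, W, C)` input image it was computed from.
#' @param path Output PNG path.
#' @param alpha Blend weight of the heat map (default 0.5).
#' @return `path`, invisibly.
#' @export
write_cam_overlay <- function(cam, image, path, alpha = 0.5) {
  stopifnot(inherits(cam, "heatmap_cam"))
  gray <- image[, , 1]
  overlay <- array(0, dim = c(dim(gray), 3))
  overlay[, , 1] <- pmin(1, (1 - alpha) * gray + alpha * cam$values)
  overlay[, , 2] <- (1 - alpha) * gray
  overlay[, , 3] <- (1 - alpha) * gray
  a <- aperm(overlay, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}
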