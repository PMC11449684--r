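#' Describe a single network layer
#'
#' Declarative description of one layer of the network.  Only the fields
#' relevant to `kind` are required: convolution layers need `filters`,
#' `kernel`, `stride`, `padding` and `in_channels`; batch normalization
#' needs `channels`; the fully connected layer needs `in_features` and
#' `out_units`.
#'
#' @param kind One of `"input"`, `"conv"`, `"batchnorm"`, `"activation"`,
#'   `"maxpool"`, `"fully_connected"`, `"softmax"`, `"classification"`.
#' @param name Optional display name (e.g. `"conv_1"`).
#' @param ... Layer fields (`filters`, `kernel`, `stride`, `padding`,
#'   `in_channels`, `channels`, `in_features`, `out_units`).
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(kind, name = kind, ...) {
  kinds <- c("input", "conv", "batchnorm", "activation", "maxpool",
             "fully_connected", "softmax", "classification")
  if (!kind %in% kinds)
    stop("unknown layer kind '", kind, "'", call. = FALSE)
  l <- c(list(kind = kind, name = name), list(...))
  if (kind == "conv") {
    stopifnot(l$filters > 0, all(l$kernel >= 1), all(l$stride >= 1),
              l$padding >= 0)
  }
  if (kind == "maxpool") stopifnot(all(l$kernel >= 1), all(l$stride >= 1))
  structure(l, class = "layer_spec")
}

#' Declarative specification of the classification network
#'
#' The network is three convolution blocks (convolution, batch
#' normalization, activation, max pooling) followed by a fully connected
#' layer, softmax and a classification output -- sixteen layers counting
#' the input.  The default geometry follows the published configuration
#' literally: 32, 64, 32 filters of size 3x3 with stride 3 and padding 2
#' in every convolution, and 3x3 stride-1 max pooling.  Every
#' intermediate shape is valid for 224x224x3 inputs; the flattened width
#' this produces is reported against the published one by
#' [audit_table2()].
#'
#' @param input_shape Integer vector `(H, W, C)`; default `c(224, 224, 3)`.
#' @param num_classes Number of output classes (default 4).
#' @param conv_filters Filters per convolution block.
#' @param conv_kernel,conv_stride,conv_padding Convolution geometry,
#'   shared by all three blocks.
#' @param pool_kernel,pool_stride Max-pooling geometry (no padding).
#' @return An object of class `network_spec`: a list with the ordered
#'   `layers` plus the constructor arguments.
#' @export
network_spec <- function(input_shape = c(224L, 224L, 3L),
                         num_classes = 4L,
                         conv_filters = c(32L, 64L, 32L),
                         conv_kernel = 3L, conv_stride = 3L,
                         conv_padding = 2L,
                         pool_kernel = 3L, pool_stride = 1L) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1),
            num_classes >= 2, length(conv_filters) >= 1,
            all(conv_filters >= 1))
  layers <- list(layer_spec("input", "imageinput", shape = input_shape))
  in_ch <- input_shape[3]
  for (b in seq_along(conv_filters)) {
    layers <- c(layers, list(
      layer_spec("conv", paste0("conv_", b), filters = conv_filters[b],
                 kernel = c(conv_kernel, conv_kernel),
                 stride = c(conv_stride, conv_stride),
                 padding = conv_padding, in_channels = in_ch),
      layer_spec("batchnorm", paste0("batchnorm_", b),
                 channels = conv_filters[b]),
      layer_spec("activation", paste0("activation_", b)),
      layer_spec("maxpool", paste0("maxpool_", b),
                 kernel = c(pool_kernel, pool_kernel),
                 stride = c(pool_stride, pool_stride), padding = 0L)))
    in_ch <- conv_filters[b]
  }
  net <- structure(
    list(layers = layers, input_shape = as.integer(input_shape),
         num_classes = as.integer(num_classes),
         conv_filters = as.integer(conv_filters)),
    class = "network_spec")
  shp <- forward_shapes(net)  # validates geometry; errors name the layer
  in_feat <- prod(utils::tail(shp, 1)[, c("H", "W", "C")])
  net$layers <- c(net$layers, list(
    layer_spec("fully_connected", "fc", in_features = as.integer(in_feat),
               out_units = as.integer(num_classes)),
    layer_spec("softmax", "softmax"),
    layer_spec("classification", "classoutput")))
  net
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> input ", paste(x$input_shape, collapse = "x"),
      ", ", length(x$conv_filters), " conv blocks (",
      paste(x$conv_filters, collapse = ", "), " filters), ",
      x$num_classes, " classes\n", sep = "")
  invisible(x)
}

#' Count the learnable parameters of a layer
#'
#' Convolution: `(kh * kw * in_channels + 1) * filters` (weights plus one
#' bias per filter).  Batch normalization: `2 * channels` (scale and
#' offset; running statistics are state, not learnables).  Fully
#' connected: `out_units * in_features + out_units`.  Input, activation,
#' pooling, softmax and classification layers have none.
#'
#' @param layer A [layer_spec()].
#' @return Integer parameter count.
#' @examples
#' count_learnables(layer_spec("conv", filters = 32, kernel = c(3, 3),
#'                             stride = c(1, 1), padding = 0,
#'                             in_channels = 3))  # 896
#' @export
count_learnables <- function(layer) {
  stopifnot(inherits(layer, "layer_spec"))
  switch(layer$kind,
    conv = (prod(layer$kernel) * layer$in_channels + 1) * layer$filters,
    batchnorm = 2 * layer$channels,
    fully_connected = layer$out_units * layer$in_features + layer$out_units,
    input = 0, activation = 0, maxpool = 0, softmax = 0, classification = 0,
    stop("unknown layer kind '", layer$kind, "'", call. = FALSE))
}

#' Spatial output shapes of every layer
#'
#' Applies the standard output-size rule
#' `out = floor((in + 2 * padding - kernel) / stride) + 1` through the
#' convolution and pooling stack.
#'
#' @param net A [network_spec()].
#' @return A data frame with one row per spatial layer (input through the
#'   last pooling layer) and columns `layer`, `H`, `W`, `C`.
#' @export
forward_shapes <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  h <- net$input_shape[1]; w <- net$input_shape[2]; ch <- net$input_shape[3]
  rows <- list(data.frame(layer = "imageinput", H = h, W = w, C = ch))
  for (l in net$layers) {
    if (l$kind %in% c("conv", "maxpool")) {
      if (any(l$kernel > c(h, w) + 2 * l$padding))
        stop("layer '", l$name, "': kernel ", paste(l$kernel, collapse = "x"),
             " exceeds its ", h, "x", w, " input (padding ", l$padding, ")",
             call. = FALSE)
      h <- (h + 2 * l$padding - l$kernel[1]) %/% l$stride[1] + 1
      w <- (w + 2 * l$padding - l$kernel[2]) %/% l$stride[2] + 1
      if (h < 1 || w < 1)
        stop("layer '", l$name, "' produces a non-positive output size",
             call. = FALSE)
      if (l$kind == "conv") ch <- l$filters
      rows <- c(rows, list(data.frame(layer = l$name, H = h, W = w, C = ch)))
    }
  }
  do.call(rbind, rows)
}

# Published per-layer learnable counts and flattened width for the default
# configuration (32/64/32 filters, 3x3 kernels, four classes).
published_table2 <- function() {
  data.frame(
    layer = c("conv_1", "batchnorm_1", "conv_2", "batchnorm_2",
              "conv_3", "batchnorm_3", "fc"),
    published = c(896, 64, 18496, 128, 18464, 64, 10372))
}

#' Audit learnable-parameter counts against the published configuration
#'
#' Recomputes the learnable count of every parameterized layer from the
#' network specification and compares each with the published value.  The
#' fully connected row is audited with the published flattened input
#' width (2592) and the spec's class count, because the published
#' stride/padding configuration does not reproduce that width under the
#' standard output-size rule; the report therefore also carries the
#' flattened width the spec actually produces (`flatten_computed`) next
#' to the published one (`flatten_published`), plus the fully connected
#' count implied by the spec's own width (`fc_actual`).
#'
#' @param net A [network_spec()]; the default audit expects the default
#'   three-block, four-class geometry.
#' @return An object of class `audit_report`: list with `table` (columns
#'   `layer`, `computed`, `published`, `match`), `flatten_computed`,
#'   `flatten_published`, `flatten_match`, `fc_actual`, and
#'   `total_computed`.
#' @export
audit_table2 <- function(net = network_spec()) {
  stopifnot(inherits(net, "network_spec"))
  pub <- published_table2()
  by_name <- setNames(net$layers, vapply(net$layers, `[[`, "", "name"))
  computed <- numeric(nrow(pub))
  for (i in seq_len(nrow(pub))) {
    nm <- pub$layer[i]
    if (nm == "fc") {
      fc <- by_name[["fc"]]
      audited <- layer_spec("fully_connected", "fc", in_features = 2592L,
                            out_units = fc$out_units)
      computed[i] <- count_learnables(audited)
    } else if (!is.null(by_name[[nm]])) {
      computed[i] <- count_learnables(by_name[[nm]])
    } else {
      computed[i] <- NA_real_
    }
  }
  tab <- data.frame(layer = pub$layer, computed = computed,
                    published = pub$published,
                    match = computed == pub$published)
  shp <- forward_shapes(net)
  flat <- prod(utils::tail(shp, 1)[, c("H", "W", "C")])
  fc <- by_name[["fc"]]
  structure(list(
    table = tab,
    flatten_computed = flat,
    flatten_published = 2592,
    flatten_match = flat == 2592,
    fc_actual = count_learnables(fc),
    total_computed = sum(vapply(net$layers, count_learnables, numeric(1)))),
    class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Learnable-parameter audit\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("flattened width: computed %d, published %d (%s)\n",
              x$flatten_computed, x$flatten_published,
              if (x$flatten_match) "match" else "MISMATCH"))
  cat(sprintf("fully connected layer as built: %d learnables\n",
              x$fc_actual))
  cat(sprintf("total learnables in the built network: %d\n",
              x$total_computed))
  invisible(x)
}

#' Write an audit report as CSV
#'
#' @param x An [audit_table2()] report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_audit_csv <- function(x, path) {
  stopifnot(inherits(x, "audit_report"))
  tab <- x$table
  tab <- rbind(tab, data.frame(layer = "flattened_width",
                               computed = x$flatten_computed,
                               published = x$flatten_published,
                               match = x$flatten_match))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
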