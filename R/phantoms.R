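#' Generate a synthetic four-class phantom dataset
#'
#' Produces grayscale head phantoms (replicated to 3 channels) emulating
#' the four classes of the brain-MRI tumor collections: each image is an
#' elliptical "brain" on a dark background, and the class determines the
#' simulated lesion geometry:
#'
#' * class 1 `glioma`: an irregular multi-lobed bright blob in the
#'   interior (union of three jittered disks, biased upper-left);
#' * class 2 `meningioma`: a single bright blob attached to the
#'   right-lateral periphery of the ellipse;
#' * class 3 `notumor`: background anatomy only;
#' * class 4 `pituitary`: a small bright midline blob in the inferior
#'   half.
#'
#' Pixel intensities get additive Gaussian noise of standard deviation
#' `noise_sd` and are clipped to `[0, 1]`.  Generation is fully
#' deterministic given `seed`.  Lesion bounding boxes (rows `h0:h1`,
#' columns `w0:w1`; `NA` for `notumor`) are attached as attribute
#' `"lesion_boxes"` for localization checks.
#'
#' @param n_per_class Images per class (default 100).
#' @param image_size Integer `(H, W)` (default `c(224, 224)`).
#' @param noise_sd Gaussian pixel-noise standard deviation, `< 0.5`
#'   (default 0.05).
#' @param seed Integer seed.
#' @param blob_radius Range (fraction of image half-height) of lesion
#'   disk radii for the glioma- and meningioma-like classes.
#' @param rim_offset How far inside the ellipse boundary the peripheral
#'   blob center sits, as a fraction of the boundary radius.
#' @param jitter Positional jitter (fraction of half-height) applied to
#'   lesion centers.
#' @return A [labeled_image_set()] with provenance `"phantom"` and class
#'   names `glioma`, `meningioma`, `notumor`, `pituitary`.
#' @examples
#' set <- generate_phantoms(n_per_class = 4, image_size = c(64, 64),
#'                          noise_sd = 0, seed = 1)
#' table(set$labels)
#' @export
generate_phantoms <- function(n_per_class = 100L,
                              image_size = c(224L, 224L),
                              noise_sd = 0.05, seed = 1L,
                              blob_radius = c(0.16, 0.24),
                              rim_offset = 0.75,
                              jitter = 0.08) {
  stopifnot(n_per_class >= 1, length(image_size) == 2, all(image_size >= 8))
  if (!(noise_sd >= 0 && noise_sd < 0.5))
    stop("'noise_sd' must be in [0, 0.5)", call. = FALSE)
  h <- image_size[1]; w <- image_size[2]
  classes <- c("glioma", "meningioma", "notumor", "pituitary")
  n <- 4L * n_per_class

  # normalized coordinates: v runs down rows in [-1, 1], u across columns
  v <- matrix(seq(-1, 1, length.out = h), h, w)
  u <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  brain <- (u / 0.78)^2 + (v / 0.92)^2 <= 1
  # mild radial shading so the background is not constant
  shade <- 0.42 + 0.10 * (1 - pmin((u / 0.78)^2 + (v / 0.92)^2, 1))

  disk <- function(cu, cv, r) (u - cu)^2 + (v - cv)^2 <= r^2

  images <- array(0, dim = c(h, w, 3L, n))
  labels <- rep(1:4, each = n_per_class)
  boxes <- vector("list", n)

  with_seed_(seed, {
    for (i in seq_len(n)) {
      img <- ifelse(brain, shade, 0.02)
      lesion <- matrix(FALSE, h, w)
      k <- labels[i]
      if (k == 1L) {
        # multi-lobed interior blob, biased to the upper-left quadrant so
        # the class-conditional mean stays localized
        cu0 <- runif(1, -0.28, 0.02); cv0 <- runif(1, -0.30, 0.00)
        for (lobe in 1:3) {
          r <- runif(1, blob_radius[1], blob_radius[2]) * 0.8
          lesion <- lesion | disk(cu0 + runif(1, -jitter, jitter) * 2,
                                  cv0 + runif(1, -jitter, jitter) * 2, r)
        }
        img[lesion & brain] <- 0.88
      } else if (k == 2L) {
        # bright blob attached to the rim, on a right-lateral arc (a
        # constrained attachment site keeps nearest-centroid separability)
        th <- runif(1, -pi / 4, pi / 4)
        cu0 <- rim_offset * 0.78 * cos(th) + runif(1, -jitter, jitter) / 2
        cv0 <- rim_offset * 0.92 * sin(th) + runif(1, -jitter, jitter) / 2
        r <- runif(1, blob_radius[1], blob_radius[2])
        lesion <- disk(cu0, cv0, r)
        img[lesion & brain] <- 0.97
      } else if (k == 4L) {
        # small midline-inferior blob
        cu0 <- runif(1, -0.05, 0.05)
        cv0 <- 0.55 + runif(1, -jitter, jitter)
        r <- runif(1, 0.07, 0.10)
        lesion <- disk(cu0, cv0, r)
        img[lesion & brain] <- 0.92
      }
      lesion <- lesion & brain
      if (any(lesion)) {
        rows <- range(which(rowSums(lesion) > 0))
        cols <- range(which(colSums(lesion) > 0))
        boxes[[i]] <- c(h0 = rows[1], h1 = rows[2],
                        w0 = cols[1], w1 = cols[2])
      } else {
        boxes[[i]] <- NA
      }
      if (noise_sd > 0) img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
      img <- pmin(pmax(img, 0), 1)
      images[, , , i] <- img  # replicate the gray channel 3x
    }
  })
  out <- labeled_image_set(images, labels, classes, "phantom")
  attr(out, "lesion_boxes") <- boxes
  out
}

#' Materialize a labeled image set as a class-folder tree
#'
#' Writes `<dir>/<class_name>/img_XXXX.png` so that generated phantoms can
#' be re-read with [load_image_folder()] or consumed by external tools.
#'
#' @param set A [labeled_image_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_folder <- function(set, dir) {
  stopifnot(inherits(set, "labeled_image_set"))
  for (k in seq_along(set$class_names)) {
    d <- file.path(dir, set$class_names[k])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in which(set$labels == k)) {
      a <- aperm(set$images[, , , i], c(2, 1, 3))  # (H,W,C) -> EBImage (W,H,C)
      EBImage::writeImage(EBImage::Image(a, colormode = "Color"),
                          file.path(d, sprintf("img_%04d.png", i)))
    }
  }
  invisible(dir)
}
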