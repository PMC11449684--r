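# Internal helper: run code with a temporary RNG state seeded from `seed`,
# restoring the caller's stream afterwards.
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a labeled image set
#'
#' Container for a stack of preprocessed images with integer class labels.
#' Images are stored as a single `H x W x C x N` array of intensities in
#' `[0, 1]`; labels are integers in `1..K` indexing into `class_names`.
#'
#' @param images Numeric array of dimension `(H, W, C, N)` with values in
#'   `[0, 1]`.
#' @param labels Integer vector of length `N` with values in `1..K`.
#' @param class_names Character vector of the `K` class names.
#' @param provenance `"folder"` or `"phantom"`.
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names,
                              provenance = c("folder", "phantom")) {
  provenance <- match.arg(provenance)
  stopifnot(is.array(images), length(dim(images)) == 4)
  labels <- as.integer(labels)
  if (length(labels) != dim(images)[4])
    stop("length(labels) must equal the number of images", call. = FALSE)
  k <- length(class_names)
  if (any(labels < 1L | labels > k))
    stop("labels must lie in 1..", k, call. = FALSE)
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 provenance = provenance),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat("<labeled_image_set> ", d[4], " images of ", d[1], "x", d[2], "x", d[3],
      " (", x$provenance, "), classes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  print(table(factor(x$class_names[x$labels], levels = x$class_names)))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$labels)

#' Subset a labeled image set by image index
#'
#' @param set A [labeled_image_set()].
#' @param idx Integer vector of image indices.
#' @return A [labeled_image_set()] restricted to `idx`.
#' @export
subset_images <- function(set, idx) {
  stopifnot(inherits(set, "labeled_image_set"))
  out <- set
  out$images <- set$images[, , , idx, drop = FALSE]
  out$labels <- set$labels[idx]
  out
}

# Decode one image file to an (H, W, 3) array in [0, 1], or NULL if the
# file cannot be decoded.  EBImage stores images width-first, so the array
# is transposed to row-major (H, W) orientation.
read_one_image_ <- function(path, target_size) {
  img <- tryCatch(EBImage::readImage(path), error = function(e) NULL)
  if (is.null(img)) return(NULL)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] == 1) a <- array(rep(a, 3), dim = c(dim(a)[1:2], 3))
  img <- EBImage::Image(a, colormode = "Color")
  img <- EBImage::resize(img, w = target_size[2], h = target_size[1])
  a <- EBImage::imageData(img)
  a <- aperm(a, c(2, 1, 3))  # (W, H, C) -> (H, W, C)
  pmin(pmax(a, 0), 1)
}

#' Load a class-folder image dataset
#'
#' Reads a directory tree laid out as `<root>/<class_name>/*.{jpg,png,...}`
#' (one subdirectory per class, the layout used by public MRI collections
#' with classes glioma / meningioma / notumor / pituitary).  Several roots
#' may be given (e.g. separate training and testing trees); their images
#' are pooled.  Every image is decoded, converted to 3 channels, resized
#' bilinearly to `target_size` and scaled to `[0, 1]`.  Classes are
#' ordered alphabetically by folder name so label indices are
#' reproducible.
#'
#' @param root Character vector of one or more dataset roots.
#' @param target_size Integer `(H, W)` to resize to; default `c(224, 224)`.
#' @return A [labeled_image_set()] with provenance `"folder"`.  The number
#'   of undecodable files skipped is attached as attribute `"n_skipped"`.
#' @export
load_image_folder <- function(root, target_size = c(224L, 224L)) {
  stopifnot(length(target_size) == 2, all(target_size >= 1))
  for (r in root) if (!dir.exists(r))
    stop("dataset root '", r, "' does not exist", call. = FALSE)
  class_dirs <- sort(unique(unlist(lapply(root, function(r)
    basename(list.dirs(r, recursive = FALSE))))))
  if (length(class_dirs) == 0)
    stop("no class subdirectories under ", paste(root, collapse = ", "),
         call. = FALSE)
  if (length(class_dirs) < 4)
    warning("only ", length(class_dirs), " class folder(s) found (",
            paste(class_dirs, collapse = ", "),
            "); the canonical tumor datasets have 4", call. = FALSE)
  exts <- "\\.(jpg|jpeg|png|tif|tiff)$"
  imgs <- list(); labels <- integer(0); skipped <- 0L
  for (ki in seq_along(class_dirs)) {
    files <- unlist(lapply(root, function(r) {
      d <- file.path(r, class_dirs[ki])
      if (dir.exists(d)) sort(list.files(d, exts, ignore.case = TRUE,
                                         full.names = TRUE)) else character(0)
    }))
    if (length(files) == 0)
      stop("class folder '", class_dirs[ki], "' contains no images",
           call. = FALSE)
    for (f in files) {
      a <- read_one_image_(f, target_size)
      if (is.null(a)) {
        warning("skipping undecodable image: ", f, call. = FALSE)
        skipped <- skipped + 1L
        next
      }
      imgs[[length(imgs) + 1L]] <- a
      labels <- c(labels, ki)
    }
  }
  arr <- array(unlist(imgs), dim = c(target_size[1], target_size[2], 3,
                                     length(imgs)))
  out <- labeled_image_set(arr, labels, class_dirs, "folder")
  attr(out, "n_skipped") <- skipped
  out
}

#' Split a dataset into train / validation / test subsets
#'
#' Deterministic, seeded split into disjoint subsets covering the input.
#' With `stratified = TRUE` (the default) the allocation is done per
#' class by largest-remainder rounding, so each class's subset sizes are
#' within one image of `fraction * class size`.  The conventional split
#' is 70% training, 10% validation, 20% testing.
#'
#' @param set A [labeled_image_set()].
#' @param fractions Numeric vector of 3 split fractions (train, val,
#'   test), each in `(0, 1)`, summing to 1.
#' @param seed Integer seed governing the shuffle.
#' @param stratified Allocate per class (default) or over the pooled set.
#' @return Named list `train`, `val`, `test` of [labeled_image_set()]s;
#'   the index vectors used are attached as attribute `"indices"`.
#' @export
split_dataset <- function(set, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(set, "labeled_image_set"))
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1))
    stop("'fractions' must be 3 values in (0, 1)", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  n <- length(set)
  if (n == 0) stop("empty dataset", call. = FALSE)

  # Largest-remainder apportionment of m items to the three fractions.
  # Remainder ties break toward the split with the largest accumulated
  # deficit, so totals over classes also stay within one of n * fraction.
  deficit <- c(0, 0, 0)
  allocate <- function(m) {
    target <- m * fractions
    base <- floor(target)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(target - base, deficit, 3:1,
                     decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    deficit <<- deficit + target - base
    base
  }

  idx <- vector("list", 3)
  with_seed_(seed, {
    if (stratified) {
      for (ki in seq_along(set$class_names)) {
        members <- which(set$labels == ki)
        if (length(members) < 3)
          stop("class '", set$class_names[ki], "' has fewer images (",
               length(members), ") than splits", call. = FALSE)
        members <- sample(members)
        sizes <- allocate(length(members))
        cuts <- cumsum(sizes)
        idx[[1]] <- c(idx[[1]], members[seq_len(sizes[1])])
        if (sizes[2] > 0)
          idx[[2]] <- c(idx[[2]], members[(cuts[1] + 1):cuts[2]])
        if (sizes[3] > 0)
          idx[[3]] <- c(idx[[3]], members[(cuts[2] + 1):cuts[3]])
      }
    } else {
      shuffled <- sample(n)
      sizes <- allocate(n)
      cuts <- cumsum(sizes)
      idx[[1]] <- shuffled[seq_len(sizes[1])]
      idx[[2]] <- if (sizes[2] > 0) shuffled[(cuts[1] + 1):cuts[2]] else integer(0)
      idx[[3]] <- if (sizes[3] > 0) shuffled[(cuts[2] + 1):cuts[3]] else integer(0)
    }
  })
  idx <- lapply(idx, sort)
  out <- list(train = subset_images(set, idx[[1]]),
              val = subset_images(set, idx[[2]]),
              test = subset_images(set, idx[[3]]))
  attr(out, "indices") <- setNames(idx, c("train", "val", "test"))
  out
}
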