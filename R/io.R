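# Image and label-map I/O.  Label maps use the AV-DRIVE color dialect:
# artery = red (255,0,0), vein = blue (0,0,255), crossing/uncertain =
# green (0,255,0); white (255,255,255) is also accepted on read and mapped
# to the combined crossing/uncertain class; background = black.

LABEL_COLORS <- rbind(
  background       = c(0, 0, 0),
  artery           = c(1, 0, 0),
  crossing_unknown = c(0, 1, 0),
  vein             = c(0, 0, 1)
)

#' Write a labeled image to disk
#'
#' Writes the RGB raster as an 8-bit PNG, the label map as a color-coded PNG
#' (artery red, vein blue, crossing/uncertain green, background black), and a
#' sidecar JSON with the generator configuration.
#'
#' @param li a `labeled_image` from [generate_labeled_image()].
#' @param image_path,label_path output PNG paths.
#' @param config_path optional sidecar JSON path for the configuration.
#' @return invisibly, the paths written.
#' @export
write_labeled_image <- function(li, image_path, label_path, config_path = NULL) {
  png::writePNG(li$image, image_path)
  write_label_image(li$labels, label_path)
  if (!is.null(config_path)) {
    cfg <- li$config
    jsonlite::write_json(unclass(cfg), config_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(c(image_path, label_path, config_path))
}

#' @rdname write_labeled_image
#' @param labels integer label matrix (0..3).
#' @param path output PNG path.
#' @export
write_label_image <- function(labels, path) {
  P <- nrow(labels); Q <- ncol(labels)
  img <- array(0, c(P, Q, 3L))
  for (k in 0:3) {
    sel <- labels == k
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- LABEL_COLORS[k + 1L, ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a color-coded label map
#'
#' Accepts the AV-DRIVE dialect; white pixels are mapped to the combined
#' crossing/uncertain class.  Any other color is an error.
#'
#' @param path PNG path.
#' @return integer label matrix (0 = background, 1 = artery,
#'   2 = crossing/unknown, 3 = vein).
#' @export
read_label_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) stop("label image must be RGB, got grayscale: ", path)
  img <- img[, , 1:3, drop = FALSE]
  r <- round(img[, , 1L]); g <- round(img[, , 2L]); b <- round(img[, , 3L])
  labels <- matrix(NA_integer_, nrow(r), ncol(r))
  labels[r == 0 & g == 0 & b == 0] <- LBL_BACKGROUND
  labels[r == 1 & g == 0 & b == 0] <- LBL_ARTERY
  labels[r == 0 & g == 1 & b == 0] <- LBL_CROSSING
  labels[r == 1 & g == 1 & b == 1] <- LBL_CROSSING  # "uncertain" coding
  labels[r == 0 & g == 0 & b == 1] <- LBL_VEIN
  if (anyNA(labels)) {
    stop("unrecognized label colors in ", path,
         " (expected black/red/green/blue/white)")
  }
  labels
}

#' Read an RGB image as a P x Q x 3 array in [0, 1]
#'
#' @param path PNG path.
#' @return numeric array.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  img[, , 1:3, drop = FALSE]
}

#' Read an AV-DRIVE style directory
#'
#' Pairs fundus images with color-coded artery/vein label maps by shared
#' numeric prefix in the file names (e.g. `21_training.png` with
#' `21_training_av.png`).  Only PNG files are supported; users of the
#' original TIFF distribution should convert the images first.  Nothing is
#' ever downloaded.
#'
#' @param images_dir directory of fundus PNGs.
#' @param labels_dir directory of color-coded label PNGs.
#' @return list of `labeled_image`-like lists (`image`, `labels`, `name`).
#' @export
read_av_dataset <- function(images_dir, labels_dir) {
  imgs <- sort(list.files(images_dir, pattern = "\\.png$", full.names = TRUE))
  labs <- sort(list.files(labels_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(imgs) == 0L) stop("no PNG images found in ", images_dir)
  key <- function(p) sub("^([0-9]+).*$", "\\1", basename(p))
  lab_by_key <- stats::setNames(labs, vapply(labs, key, ""))
  out <- list()
  for (p in imgs) {
    k <- key(p)
    lp <- lab_by_key[[k]]
    if (is.null(lp)) stop("no label map found for image ", basename(p))
    out[[length(out) + 1L]] <- list(
      image = read_rgb_image(p),
      labels = read_label_image(lp),
      name = basename(p)
    )
  }
  out
}
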