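#' Labeled instance mask
#'
#' Thin container for a 2D integer instance-label image: 0 is background,
#' each positive integer is one object. Labels need not be consecutive;
#' downstream phenotyping is invariant to relabeling.
#'
#' @param labels integer matrix with values >= 0.
#' @param channel_name label for the source channel.
#' @param pixel_size physical pixel size in micrometers.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, channel_name = "unknown", pixel_size = NA_real_) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix", call. = FALSE)
  if (any(labels < 0)) stop("labels must be >= 0", call. = FALSE)
  if (any(labels != round(labels))) {
    stop("labels must be integer-valued", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, channel_name = channel_name,
                 pixel_size = pixel_size),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("label_mask [%s]: %d x %d px, %d objects\n", x$channel_name,
              nrow(x$labels), ncol(x$labels), length(ids)))
  invisible(x)
}

mask_ids <- function(mask) {
  sort(setdiff(unique(as.vector(mask$labels)), 0L))
}

# Shared post-processing: drop objects below min_area pixels.
filter_min_area <- function(labels, min_area) {
  if (min_area <= 1) return(labels)
  tab <- tabulate(labels[labels > 0L])
  small <- which(tab > 0L & tab < min_area)
  if (length(small)) labels[labels %in% small] <- 0L
  labels
}

#' Segment nuclei from a nuclear-counterstain channel
#'
#' Classical instance segmentation: Gaussian smoothing, Otsu thresholding,
#' Euclidean distance transform and a peak-seeded watershed, followed by a
#' minimum-area filter. Any instance segmenter honoring the [label_mask()]
#' contract (e.g. externally produced deep-learning masks imported with
#' [import_mask()]) can replace this stand-in.
#'
#' @param image non-negative numeric matrix of intensities.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param min_area objects smaller than this many pixels are removed.
#' @param tolerance watershed tolerance (minimum object-separating depth of
#'   the distance transform).
#' @param min_contrast images whose dynamic range is below this value (on
#'   the input intensity scale) are treated as containing no stain at all
#'   and return an empty mask, instead of letting the automatic threshold
#'   slice pure background noise.
#' @param channel_name,pixel_size metadata stored on the result.
#' @return a [label_mask()].
#' @export
segment_nuclei <- function(image, sigma = 2, min_area = 20, tolerance = 1,
                           min_contrast = 0.2,
                           channel_name = "nuclear", pixel_size = NA_real_) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("'image' must be finite and non-negative", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    stop("cannot segment a constant image: the foreground threshold is undefined",
         call. = FALSE)
  }
  if (diff(rng) < min_contrast) {
    return(label_mask(matrix(0L, nrow(image), ncol(image)),
                      channel_name, pixel_size))
  }
  sm <- EBImage::gblur(image, sigma = sigma)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  binary <- sm > thr
  if (!any(binary)) {
    return(label_mask(matrix(0L, nrow(image), ncol(image)),
                      channel_name, pixel_size))
  }
  dist <- EBImage::distmap(EBImage::Image(binary * 1))
  labels <- EBImage::imageData(EBImage::watershed(dist, tolerance = tolerance))
  labels <- filter_min_area(matrix(as.integer(labels), nrow(image)), min_area)
  label_mask(labels, channel_name, pixel_size)
}

#' Segment a membrane-marker channel into filled cell objects
#'
#' As [segment_nuclei()], but membrane staining forms rings: after
#' thresholding, the binary image is morphologically closed and holes are
#' filled so each ring becomes one solid cell object before labeling
#' (8-connectivity).
#'
#' @inheritParams segment_nuclei
#' @param closing_size diameter (pixels) of the disc brush used for
#'   morphological closing of the ring.
#' @inheritParams segment_nuclei
#' @return a [label_mask()].
#' @export
segment_marker <- function(image, channel_name, sigma = 2, min_area = 20,
                           closing_size = 5, min_contrast = 0.2,
                           pixel_size = NA_real_) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("'image' must be finite and non-negative", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    stop("cannot segment a constant image: the foreground threshold is undefined",
         call. = FALSE)
  }
  if (diff(rng) < min_contrast) {
    return(label_mask(matrix(0L, nrow(image), ncol(image)),
                      channel_name, pixel_size))
  }
  sm <- EBImage::gblur(image, sigma = sigma)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  binary <- sm > thr
  if (!any(binary)) {
    return(label_mask(matrix(0L, nrow(image), ncol(image)),
                      channel_name, pixel_size))
  }
  brush <- EBImage::makeBrush(max(3L, closing_size %/% 2L * 2L + 1L),
                              shape = "disc")
  closed <- EBImage::closing(EBImage::Image(binary * 1), brush)
  filled <- EBImage::fillHull(closed)
  labels <- EBImage::imageData(EBImage::bwlabel(filled))
  labels <- filter_min_area(matrix(as.integer(labels), nrow(image)), min_area)
  label_mask(labels, channel_name, pixel_size)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask a [label_mask()] with labels `<= 65535`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) {
    stop("labels exceed the 16-bit range", call. = FALSE)
  }
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Import a label mask from an integer TIFF
#'
#' Round-trips exactly with [write_mask()]. Externally produced instance
#' masks (e.g. deep-learning segmenter exports) can enter the workflow here.
#'
#' @param path path to a single-channel integer TIFF.
#' @param channel_name,pixel_size metadata stored on the result.
#' @return a [label_mask()].
#' @export
import_mask <- function(path, channel_name = "imported",
                        pixel_size = NA_real_) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(raw)) raw <- raw[[1]]
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] != 1L) stop("expected a single-channel TIFF", call. = FALSE)
    raw <- raw[, , 1]
  }
  if (any(raw != round(raw))) {
    stop("mask TIFF has non-integer pixel values", call. = FALSE)
  }
  if (any(raw < 0)) stop("mask TIFF has negative pixel values", call. = FALSE)
  label_mask(matrix(as.integer(round(raw)), nrow(raw)), channel_name,
             pixel_size)
}
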