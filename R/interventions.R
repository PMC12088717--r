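# Region-localization interventions: crop tightly around the heart, or blur
# the heart out, leaving everything else untouched.

#' Tight bounding box of the heart foreground
#'
#' @param mask Integer label matrix; foreground is labels \{1,2,3\}.
#' @return List `row_min`, `row_max`, `col_min`, `col_max`: 0-based,
#'   half-open pixel index ranges `[min, max)`.
#' @export
heart_bbox <- function(mask) {
  fg <- which(mask > 0L, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("mask has no foreground pixels")
  list(row_min = min(fg[, 1]) - 1L, row_max = max(fg[, 1]),
       col_min = min(fg[, 2]) - 1L, col_max = max(fg[, 2]))
}

#' Common crop size: the largest heart in a set of masks
#'
#' Per-axis maximum of the individual bounding-box extents, so every heart in
#' the set fits in one window of this size.
#'
#' @param masks List of label matrices.
#' @return Integer vector `c(height, width)`.
#' @export
global_crop_size <- function(masks) {
  stopifnot(length(masks) >= 1)
  boxes <- lapply(masks, heart_bbox)
  c(height = max(vapply(boxes, function(b) b$row_max - b$row_min, numeric(1))),
    width = max(vapply(boxes, function(b) b$col_max - b$col_min, numeric(1))))
}

#' Crop an image (and mask) to a fixed-size window around the heart
#'
#' The window of exactly `size` is centred on the subject's heart bounding
#' box and shifted (not shrunk) when it would be clipped by the image edge,
#' so all heart foreground is always contained and every crop in an
#' experiment shares an identical shape.
#'
#' @param image Greyscale matrix.
#' @param mask Label matrix defining the heart location.
#' @param size `c(height, width)`; must cover the subject's own bbox and fit
#'   in the image.
#' @param bbox Optional precomputed bounding box (e.g. the union box over a
#'   subject's ED and ES frames, so both frames share one window).
#' @return List with cropped `image` and `mask`.
#' @export
crop_to_heart <- function(image, mask, size, bbox = NULL) {
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h > nrow(image) || w > ncol(image))
    stop("crop size larger than the image")
  if (is.null(bbox)) bbox <- heart_bbox(mask)
  if (h < bbox$row_max - bbox$row_min || w < bbox$col_max - bbox$col_min)
    stop("crop size smaller than the subject's heart bounding box")
  ctr_r <- floor((bbox$row_min + bbox$row_max) / 2)
  ctr_c <- floor((bbox$col_min + bbox$col_max) / 2)
  r0 <- min(max(ctr_r - floor(h / 2), 0), nrow(image) - h)
  c0 <- min(max(ctr_c - floor(w / 2), 0), ncol(image) - w)
  rows <- (r0 + 1):(r0 + h); cols <- (c0 + 1):(c0 + w)
  list(image = image[rows, cols], mask = mask[rows, cols],
       origin = c(row = r0, col = c0))
}

#' Union bounding box over a subject's ED and ES masks
#' @param subject A `phantom_subject`.
#' @return A bounding box (see [heart_bbox()]).
#' @export
subject_bbox <- function(subject) {
  boxes <- lapply(subject$masks, heart_bbox)
  list(row_min = min(vapply(boxes, `[[`, numeric(1), "row_min")),
       row_max = max(vapply(boxes, `[[`, numeric(1), "row_max")),
       col_min = min(vapply(boxes, `[[`, numeric(1), "col_min")),
       col_max = max(vapply(boxes, `[[`, numeric(1), "col_max")))
}

#' Blur out the heart with a Gaussian filter
#'
#' A Gaussian-smoothed version of the image is computed on the full grid and
#' written only at foreground (LVBP, LVM, RVBP) pixels; background pixels are
#' bit-identical to the input.
#'
#' @param image Greyscale matrix.
#' @param mask Label matrix; labels \{1,2,3\} are blurred.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Matrix with the heart blurred.
#' @export
blur_heart <- function(image, mask, sigma = 4) {
  stopifnot(sigma > 0)
  rad <- max(1, ceiling(3 * sigma))
  ax <- (-rad):rad
  k1 <- exp(-ax^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  blurred <- as.matrix(EBImage::filter2(image, kern, boundary = "replicate"))
  out <- image
  fg <- mask > 0L
  out[fg] <- blurred[fg]
  out
}
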