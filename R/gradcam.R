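# GradCAM attribution for the group classifier, plus an automated taxonomy of
# where each image's peak attribution falls (heart / non-heart body /
# artefact / other), replacing visual inspection with the generator's
# ground-truth masks.

# Core GradCAM arithmetic: channel weights are the spatial means of the
# gradients, the map is the rectified weighted sum of activation maps.
.gradcam_core <- function(activations, gradients) {
  w <- apply(gradients, 3, mean)
  m <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (c in seq_along(w)) m <- m + w[c] * activations[, , c]
  m[m < 0] <- 0
  m
}

.upsample_bilinear <- function(m, out_dim) {
  if (all(dim(m) == out_dim)) return(m)
  as.matrix(EBImage::resize(m, w = out_dim[1], h = out_dim[2],
                            filter = "bilinear"))
}

#' GradCAM attribution map for a classifier input
#'
#' Computes the gradient of the target-class score with respect to the last
#' convolutional layer's activations, spatially averages it into channel
#' weights, forms the rectified weighted sum of the activation maps,
#' bilinearly upsamples to the input grid, and max-normalizes. For the binary
#' group classifier the group-B score is the logit and the group-A score its
#' negative.
#'
#' @param model A `cmr_classifier` (or a [toy_gap_model()]).
#' @param sample `H x W x 3` input array.
#' @param target_class `"B"` (positive class) or `"A"`.
#' @return List with `map` (matrix on the input grid, max 1 unless all-zero)
#'   and `layer` (identifier of the source layer).
#' @export
gradcam_map <- function(model, sample, target_class = "B") {
  UseMethod("gradcam_map")
}

#' @export
gradcam_map.cmr_classifier <- function(model, sample, target_class = "B") {
  cs <- .clf_forward(model$par, sample, cache = TRUE)
  sgn <- if (target_class == "B") 1 else -1
  bk <- .clf_backward(model$par, cs, sgn)
  m <- .gradcam_core(cs$a4, bk$da4)
  # the forward pass may have padded the input to a multiple of 8; upsample
  # to the padded grid, then cut the original region back out
  pad <- .pad_to_multiple(.as_cube(sample), 8)
  m <- .upsample_bilinear(m, dim(pad$x)[1:2])
  m <- m[pad$r0 + seq_len(pad$h), pad$c0 + seq_len(pad$w)]
  m[m < 0] <- 0  # bilinear interpolation can undershoot at edges
  if (max(m) > 0) m <- m / max(m)
  list(map = m, layer = "conv2")
}

#' Toy one-conv-layer model with a global-average-pool linear head
#'
#' A minimal model (conv -> GAP -> linear score) whose GradCAM map has a
#' closed form, used to validate the attribution arithmetic end to end.
#'
#' @param conv A conv layer weight list as produced internally; simplest is
#'   identity kernels. Supply `W` ((k*k*cin) x cout matrix), `b`, `k`,
#'   `stride`, `pad`.
#' @param v Linear head weights (length cout).
#' @return An object of class `toy_gap_model`.
#' @export
toy_gap_model <- function(conv, v) {
  structure(list(conv = conv, v = v), class = "toy_gap_model")
}

#' @export
gradcam_map.toy_gap_model <- function(model, sample, target_class = "B") {
  a <- .conv_fwd(sample, model$conv)
  hw <- prod(dim(a)[1:2])
  sgn <- if (target_class == "B") 1 else -1
  grads <- array(rep(sgn * model$v / hw, each = hw), dim = dim(a))
  m <- .gradcam_core(a, grads)
  m <- .upsample_bilinear(m, dim(sample)[1:2])
  m[m < 0] <- 0
  if (max(m) > 0) m <- m / max(m)
  list(map = m, layer = "conv")
}

#' Classify the peak of an attribution map by anatomical region
#'
#' The argmax pixel of the heatmap is labelled by mask membership with
#' precedence artefact > heart > non-heart body > other; ties among
#' equal-valued pixels are broken in row-major order (first by row, then by
#' column). An all-zero map is labelled `"other"`.
#'
#' @param map Attribution matrix.
#' @param heart_mask,body_mask,ghost_mask Logical matrices on the same grid.
#' @return One of `"artefact"`, `"heart"`, `"non-heart body"`, `"other"`.
#' @export
peak_region_label <- function(map, heart_mask, body_mask, ghost_mask) {
  if (max(map) <= 0) return("other")
  hits <- which(map == max(map), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  r <- hits[1, 1]; cc <- hits[1, 2]
  if (ghost_mask[r, cc]) return("artefact")
  if (heart_mask[r, cc]) return("heart")
  if (body_mask[r, cc] && !heart_mask[r, cc]) return("non-heart body")
  "other"
}

# mass-fraction alternative: first region (same precedence) holding at least
# `threshold` of the total heatmap mass
.mass_region_label <- function(map, heart_mask, body_mask, ghost_mask,
                               threshold = 0.5) {
  total <- sum(map)
  if (total <= 0) return("other")
  shares <- c(artefact = sum(map[ghost_mask]),
              heart = sum(map[heart_mask & !ghost_mask]),
              `non-heart body` = sum(map[body_mask & !heart_mask & !ghost_mask])) / total
  for (nm in names(shares)) if (shares[nm] >= threshold) return(nm)
  "other"
}

#' Cohort-level attribution-region taxonomy
#'
#' Runs GradCAM over a set of samples and aggregates the per-image peak
#' region labels into cohort fractions.
#'
#' @param model A trained `cmr_classifier`.
#' @param samples List of classifier inputs.
#' @param masks List (parallel to `samples`) of lists with logical `heart`,
#'   `body`, `ghost` matrices.
#' @param target_class `"predicted"` (default; each image is attributed with
#'   respect to its own predicted class, the standard GradCAM convention) or
#'   a fixed class `"B"` / `"A"`.
#' @param method `"peak"` (argmax pixel) or `"mass"` (>= 50% of heatmap mass).
#' @return List with `labels` (per image) and `fractions` (named, sums to 1)
#'   over \{heart, non-heart body, artefact, other\}.
#' @export
region_attribution_summary <- function(model, samples, masks,
                                       target_class = c("predicted", "B", "A"),
                                       method = c("peak", "mass")) {
  method <- match.arg(method)
  target_class <- match.arg(target_class)
  stopifnot(length(samples) >= 1, length(samples) == length(masks))
  pred <- NULL
  if (target_class == "predicted")
    pred <- classifier_predict(model, samples) >= 0.5
  labels <- character(length(samples))
  for (i in seq_along(samples)) {
    tgt <- if (is.null(pred)) target_class else if (pred[i]) "B" else "A"
    m <- gradcam_map(model, samples[[i]], tgt)$map
    labels[i] <- if (method == "peak")
      peak_region_label(m, masks[[i]]$heart, masks[[i]]$body, masks[[i]]$ghost)
    else
      .mass_region_label(m, masks[[i]]$heart, masks[[i]]$body, masks[[i]]$ghost)
  }
  lev <- c("heart", "non-heart body", "artefact", "other")
  fr <- table(factor(labels, levels = lev)) / length(labels)
  list(labels = labels, fractions = as.numeric(fr) |> stats::setNames(lev))
}
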