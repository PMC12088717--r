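# Per-group segmentation performance auditing: Dice similarity, per-subject
# aggregation, between-group Mann-Whitney tests, and the training-set
# imbalance sweep (original and cropped inputs).

#' Dice similarity coefficient for one label
#'
#' `2|P n G| / (|P| + |G|)`; 1 is perfect overlap, 0 none. By convention the
#' DSC is 1 when the label is absent from both masks.
#'
#' @param pred,gt Integer label matrices on the same grid.
#' @param label Label code to score.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(pred, gt, label) {
  if (!all(dim(pred) == dim(gt))) stop("mask grids do not match")
  p <- pred == label; g <- gt == label
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Subject-level DSC: mean over foreground labels and frames
#'
#' @param model A `cmr_segmenter`.
#' @param subject A `phantom_subject`.
#' @param transform Optional `(image, mask, subject) -> list(image, mask)`
#'   applied before normalization/prediction (e.g. cropping).
#' @return Mean of the 6 label-frame DSCs (labels 1..3 x frames ED/ES).
#' @export
subject_dsc <- function(model, subject, transform = NULL) {
  vals <- numeric()
  for (ph in names(subject$frames)) {
    img <- subject$frames[[ph]]; msk <- subject$masks[[ph]]
    if (!is.null(transform)) {
      tr <- transform(img, msk, subject)
      img <- tr$image; msk <- tr$mask
    }
    pred <- predict_mask(model, normalize_image(img))
    vals <- c(vals, vapply(1:3, function(l) dice(pred, msk, l), numeric(1)))
  }
  mean(vals)
}

#' Per-group subject-level DSC lists on a test set
#'
#' @param model A `cmr_segmenter`.
#' @param test_subjects List of `phantom_subject`s (both groups present).
#' @param transform Optional per-frame transform (see [subject_dsc()]).
#' @return Named list `A`, `B` of per-subject DSC vectors (named by id).
#' @export
per_group_dsc <- function(model, test_subjects, transform = NULL) {
  out <- list(A = numeric(), B = numeric())
  for (s in test_subjects)
    out[[s$group]][s$id] <- subject_dsc(model, s, transform)
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (the default behaviour of [stats::wilcox.test()]).
#'
#' @param dsc_a,dsc_b Nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(dsc_a, dsc_b) {
  if (length(dsc_a) == 0 || length(dsc_b) == 0) stop("empty DSC list")
  suppressWarnings(stats::wilcox.test(dsc_a, dsc_b)$p.value)
}

#' Significance stars for a p-value
#'
#' `****` for p <= 0.0001, `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#' p <= 0.05, `ns` otherwise.
#'
#' @param p A p-value.
#' @return Character string.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 0.0001) "****"
  else if (p <= 0.001) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else "ns"
}

# assemble normalized training images/masks for a set of subject ids,
# optionally cropped to a common window
.training_set <- function(cohort, ids, transform = NULL) {
  images <- list(); masks <- list()
  for (id in ids) {
    s <- cohort$subjects[[id]]
    for (ph in names(s$frames)) {
      img <- s$frames[[ph]]; msk <- s$masks[[ph]]
      if (!is.null(transform)) {
        tr <- transform(img, msk, s)
        img <- tr$image; msk <- tr$mask
      }
      images[[length(images) + 1]] <- normalize_image(img)
      masks[[length(masks) + 1]] <- msk
    }
  }
  list(images = images, masks = masks)
}

#' Crop transform shared by training and test
#'
#' Builds a `(image, mask, subject) -> list(image, mask)` closure that crops
#' every frame to the common window size computed from the supplied training
#' masks (so the test set reuses the training geometry and no information
#' leaks the other way). Each subject's window is the union bbox over its ED
#' and ES frames, so both frames share one window.
#'
#' @param cohort A `cmr_cohort`.
#' @param train_ids Ids whose masks define the common crop size.
#' @param margin Extra pixels added to each axis of the common size.
#' @return A transform function.
#' @export
make_crop_transform <- function(cohort, train_ids, margin = 2) {
  all_masks <- unlist(lapply(cohort$subjects[train_ids], `[[`, "masks"),
                      recursive = FALSE)
  size <- global_crop_size(all_masks) + margin
  # round up to a multiple of 4 (the segmenter's pooling depth); keeping the
  # window tight matters more than classifier alignment, which zero-pads
  size <- pmin(ceiling(size / 4) * 4, cohort$img_size)
  force(size)
  function(image, mask, subject)
    crop_to_heart(image, mask, size, bbox = subject_bbox(subject))
}

#' Train segmenters across imbalance fractions and audit per-group DSC
#'
#' For every imbalance split, trains one segmenter on that split's subjects
#' and evaluates subject-level DSC separately per group on the fixed test
#' set, with a two-sided Mann-Whitney U test between the groups. With
#' `intervention = "cropped"`, the crop transform (geometry from the training
#' pools) is applied identically to training and test frames.
#'
#' @param cohort A `cmr_cohort`.
#' @param splits List of `imbalance_split`s (see [imbalance_subsets()]).
#' @param test_ids Fixed test subject ids (both groups).
#' @param intervention `"original"` or `"cropped"`.
#' @param hyper See [segmenter_hyper()].
#' @param seed Base seed; split k trains with `seed + k - 1`.
#' @param keep_models Retain fitted segmenters (needed for latent probing).
#' @return A `sweep_result`: per-fraction rows (fraction, per-group medians,
#'   p-value, stars), per-fraction DSC lists, intervention tag, models.
#' @export
run_imbalance_sweep <- function(cohort, splits, test_ids,
                                intervention = c("original", "cropped"),
                                hyper = segmenter_hyper(), seed = 1,
                                keep_models = FALSE) {
  intervention <- match.arg(intervention)
  transform <- NULL
  if (intervention == "cropped") {
    pool_ids <- unique(unlist(lapply(splits, function(s) c(s$train_a, s$train_b))))
    transform <- make_crop_transform(cohort, pool_ids)
  }
  test_subjects <- cohort$subjects[test_ids]
  rows <- list(); dsc_lists <- list(); models <- list()
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    ids <- c(sp$train_a, sp$train_b)
    tr <- .training_set(cohort, ids, transform)
    model <- train_segmenter(tr$images, tr$masks, hyper, seed = seed + k - 1)
    dsc <- per_group_dsc(model, test_subjects, transform)
    rows[[k]] <- data.frame(
      fraction_b = sp$fraction_b, n_train_a = sp$n_a, n_train_b = sp$n_b,
      median_a = stats::median(dsc$A), median_b = stats::median(dsc$B),
      p_value = mann_whitney(dsc$A, dsc$B))
    dsc_lists[[k]] <- dsc
    if (keep_models) models[[k]] <- model
  }
  tab <- do.call(rbind, rows)
  tab$stars <- vapply(tab$p_value, significance_stars, character(1))
  structure(list(table = tab, dsc = dsc_lists, intervention = intervention,
                 test_ids = test_ids, models = models, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result (%s inputs):\n", x$intervention))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Box plot of per-group DSC across imbalance fractions
#' @param sweep A `sweep_result`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_sweep <- function(sweep, ...) {
  dat <- list(); nm <- character()
  for (k in seq_along(sweep$dsc)) {
    f <- sweep$table$fraction_b[k]
    dat <- c(dat, list(sweep$dsc[[k]]$A, sweep$dsc[[k]]$B))
    nm <- c(nm, sprintf("A f=%.2f", f), sprintf("B f=%.2f", f))
  }
  graphics::boxplot(dat, names = nm, las = 2, ylab = "DSC",
                    col = rep(c("grey80", "grey40"), length(sweep$dsc)), ...)
  invisible(sweep)
}
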