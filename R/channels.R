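#' Min-max normalize an image to \[0, 1\]
#'
#' @param image Numeric matrix.
#' @return Matrix rescaled so min = 0 and max = 1.
#' @export
normalize_image <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("degenerate input: constant image has zero range")
  (image - rng[1]) / diff(rng)
}

#' Encode a label mask as a greyscale channel
#'
#' Labels \{0,1,2,3\} map to equispaced intensities \{0, 1/3, 2/3, 1\}.
#'
#' @param mask Integer label matrix.
#' @return Numeric matrix in \[0, 1\].
#' @export
encode_mask_channel <- function(mask) {
  if (!all(mask %in% 0:3)) stop("unknown label code in mask")
  mask / 3
}

#' Decode a greyscale channel back to labels (nearest level)
#' @param channel Numeric matrix in \[0, 1\].
#' @return Integer label matrix.
#' @export
decode_mask_channel <- function(channel) {
  m <- round(channel * 3)
  storage.mode(m) <- "integer"
  m
}

#' The four channel combinations of the classification audit
#' @return Named list of length-3 character vectors over \{"Im", "Seg"\}.
#' @export
channel_combos <- function() {
  list(iii = c("Im", "Im", "Im"), iis = c("Im", "Im", "Seg"),
       iss = c("Im", "Seg", "Seg"), sss = c("Seg", "Seg", "Seg"))
}

#' Compose a 3-channel classifier input from an image and/or its mask
#'
#' `Im` channels receive the min-max normalized image, `Seg` channels the
#' encoded mask.
#'
#' @param image Greyscale matrix (raw intensities).
#' @param mask Integer label matrix, required when the combo uses `Seg`.
#' @param combo Length-3 character vector over \{"Im", "Seg"\}, or one of the
#'   short codes `"iii"`, `"iis"`, `"iss"`, `"sss"`.
#' @return `H x W x 3` numeric array.
#' @export
compose_channels <- function(image, mask = NULL, combo = c("Im", "Im", "Im")) {
  if (is.character(combo) && length(combo) == 1)
    combo <- channel_combos()[[combo]]
  stopifnot(length(combo) == 3, all(combo %in% c("Im", "Seg")))
  if (any(combo == "Seg") && is.null(mask))
    stop("combo requires a segmentation mask but none was given")
  im <- if (any(combo == "Im")) normalize_image(image) else NULL
  sg <- if (any(combo == "Seg")) encode_mask_channel(mask) else NULL
  out <- array(0, c(dim(image), 3))
  for (ch in 1:3) out[, , ch] <- if (combo[ch] == "Im") im else sg
  out
}

# build per-frame samples and labels from a list of phantom subjects
.subject_samples <- function(subjects, combo, transform = NULL) {
  samples <- list(); labels <- integer(); owner <- character()
  for (s in subjects) {
    for (ph in names(s$frames)) {
      img <- s$frames[[ph]]; msk <- s$masks[[ph]]
      if (!is.null(transform)) {
        tr <- transform(img, msk, s)
        img <- tr$image; msk <- tr$mask
      }
      samples[[length(samples) + 1]] <- compose_channels(img, msk, combo)
      labels <- c(labels, as.integer(s$group == "B"))
      owner <- c(owner, s$id)
    }
  }
  list(samples = samples, labels = labels, owner = owner)
}

#' Repeat-run classification audit for one channel combination
#'
#' Trains the group classifier `n_runs` times with different seeds and
#' train/validation resampling (subject-atomic), evaluating each run on the
#' fixed test subjects, and reports mean (SD) accuracy/sensitivity/
#' specificity over the runs.
#'
#' @param train_subjects,test_subjects Lists of `phantom_subject`s.
#' @param combo Channel combination (see [compose_channels()]).
#' @param n_runs Number of repeat runs (default 10).
#' @param base_seed Seed for run r is `base_seed + r - 1`.
#' @param hyper See [classifier_hyper()].
#' @param transform Optional function `(image, mask, subject) -> list(image,
#'   mask)` applied to every frame before channel composition (used by the
#'   crop/blur interventions).
#' @param keep_models Retain the per-run fitted models (memory-heavy).
#' @return An `audit_summary`: per-run metric data frame plus mean/SD fields.
#' @export
repeat_audit <- function(train_subjects, test_subjects, combo = "iii",
                         n_runs = 10, base_seed = 1,
                         hyper = classifier_hyper(), transform = NULL,
                         keep_models = FALSE) {
  stopifnot(n_runs >= 1)
  test <- .subject_samples(test_subjects, combo, transform)
  runs <- data.frame(run = seq_len(n_runs), accuracy = NA_real_,
                     sensitivity = NA_real_, specificity = NA_real_)
  models <- list()
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r - 1
    set.seed(seed)
    n_tr <- length(train_subjects)
    val_idx <- sample.int(n_tr, max(1, round(hyper$val_fraction * n_tr)))
    tr <- .subject_samples(train_subjects[-val_idx], combo, transform)
    model <- train_group_classifier(tr$samples, tr$labels, hyper, seed = seed)
    ev <- evaluate_classifier(model, test$samples, test$labels)
    runs[r, -1] <- c(ev$accuracy, ev$sensitivity, ev$specificity)
    if (keep_models) models[[r]] <- model
  }
  structure(list(combo = combo, runs = runs,
                 accuracy_mean = mean(runs$accuracy),
                 accuracy_sd = if (n_runs > 1) stats::sd(runs$accuracy) else 0,
                 sensitivity_mean = mean(runs$sensitivity),
                 sensitivity_sd = if (n_runs > 1) stats::sd(runs$sensitivity) else 0,
                 specificity_mean = mean(runs$specificity),
                 specificity_sd = if (n_runs > 1) stats::sd(runs$specificity) else 0,
                 models = models),
            class = "audit_summary")
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(sprintf("audit_summary [%s]: accuracy %.3f (%.3f), sensitivity %.3f (%.3f), specificity %.3f (%.3f) over %d runs\n",
              paste(x$combo, collapse = "-"), x$accuracy_mean, x$accuracy_sd,
              x$sensitivity_mean, x$sensitivity_sd, x$specificity_mean,
              x$specificity_sd, nrow(x$runs)))
  invisible(x)
}

#' Two-tailed Student's t-test between two sets of per-run accuracies
#'
#' @param runs_a,runs_b Numeric vectors of per-run accuracies (>= 2 each).
#' @return Two-sided p-value.
#' @export
compare_audits_ttest <- function(runs_a, runs_b) {
  if (length(runs_a) < 2 || length(runs_b) < 2)
    stop("need at least 2 runs per arm")
  if (stats::sd(runs_a) == 0 && stats::sd(runs_b) == 0) {
    if (mean(runs_a) == mean(runs_b))
      stop("zero pooled variance: accuracies are constant and equal")
    return(0)  # t -> +/-Inf as the pooled variance vanishes with distinct means
  }
  stats::t.test(runs_a, runs_b, var.equal = TRUE)$p.value
}

#' Per-group histogram of per-image mean intensities
#'
#' A diagnostic for global intensity shifts between groups: the mean raw
#' intensity of every frame, binned on common edges per group.
#'
#' @param cohort A `cmr_cohort`.
#' @param n_bins Number of histogram bins.
#' @return List with `breaks`, `counts` (named list per group) and `means`
#'   (per-image mean intensities per group).
#' @export
mean_intensity_histogram <- function(cohort, n_bins = 30) {
  means <- list(A = numeric(), B = numeric())
  for (s in cohort$subjects)
    for (ph in names(s$frames))
      means[[s$group]] <- c(means[[s$group]], mean(s$frames[[ph]]))
  rng <- range(unlist(means))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- lapply(means, function(m)
    graphics::hist(m, breaks = breaks, plot = FALSE)$counts)
  list(breaks = breaks, counts = counts, means = means)
}
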