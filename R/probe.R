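# Latent-space demographic probing: can group membership be linearly decoded
# from a trained segmenter's encoder representations?

#' Extract encoder latents for a set of subjects
#'
#' One vector per frame: the bottleneck feature maps, spatially
#' average-pooled (see [extract_latent()]).
#'
#' @param model A `cmr_segmenter`.
#' @param subjects List of `phantom_subject`s.
#' @param transform Optional per-frame transform applied before
#'   normalization (use the same intervention as at training time).
#' @return List with `vectors` (n x d matrix), `labels` (1 = group B) and
#'   `provenance` (data frame of subject id and frame).
#' @export
cohort_latents <- function(model, subjects, transform = NULL) {
  vecs <- list(); labels <- integer(); prov <- list()
  for (s in subjects) {
    for (ph in names(s$frames)) {
      img <- s$frames[[ph]]; msk <- s$masks[[ph]]
      if (!is.null(transform)) {
        tr <- transform(img, msk, s)
        img <- tr$image
      }
      vecs[[length(vecs) + 1]] <- extract_latent(model, normalize_image(img))
      labels <- c(labels, as.integer(s$group == "B"))
      prov[[length(prov) + 1]] <- data.frame(subject_id = s$id, frame = ph)
    }
  }
  list(vectors = do.call(rbind, vecs), labels = labels,
       provenance = do.call(rbind, prov))
}

#' PCA dimensionality reduction of latent vectors
#'
#' Centred projection onto the top principal components.
#'
#' @param vectors n x d numeric matrix.
#' @param n_components Number of components (<= min(n, d)).
#' @return List with `scores` (n x n_components), `explained_variance_ratio`
#'   (non-increasing), and the fitted `center`/`rotation`.
#' @export
pca_reduce <- function(vectors, n_components = 10) {
  if (n_components > min(dim(vectors)))
    stop("n_components exceeds min(n_samples, dim)")
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance_ratio = evr[seq_len(k)],
       center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Cross-validated logistic-regression probe accuracy
#'
#' Stratified k-fold cross-validation of a logistic-regression classifier on
#' reduced latent vectors; reports pooled held-out accuracy. When `groups`
#' is given (e.g. subject ids), folds are assigned at group level so that
#' correlated vectors from one subject (its ED and ES frames) never straddle
#' a fold — otherwise the probe can retrieve a subject's label through its
#' other frame and report above-chance accuracy even on null data.
#'
#' @param scores n x k numeric matrix (e.g. `pca_reduce(...)$scores`).
#' @param labels Binary labels (both classes present).
#' @param cv_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param groups Optional vector of group/subject identifiers per row.
#' @return Accuracy in \[0, 1\].
#' @export
probe_accuracy <- function(scores, labels, cv_folds = 5, seed = 1,
                           groups = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  stopifnot(cv_folds >= 2)
  set.seed(seed)
  if (is.null(groups)) groups <- seq_along(labels)
  ug <- !duplicated(groups)
  gfold <- integer(sum(ug))
  glab <- labels[ug]
  for (cl in unique(glab)) {
    idx <- which(glab == cl)
    gfold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  fold <- gfold[match(groups, groups[ug])]
  correct <- 0
  dat <- data.frame(y = labels, scores)
  for (f in seq_len(cv_folds)) {
    tr <- dat[fold != f, , drop = FALSE]
    te <- dat[fold == f, , drop = FALSE]
    if (nrow(te) == 0) next
    if (length(unique(tr$y)) < 2) {
      # degenerate training fold: predict its constant class
      correct <- correct + sum(te$y == tr$y[1])
      next
    }
    fit <- suppressWarnings(stats::glm(y ~ ., data = tr, family = stats::binomial()))
    pred <- as.integer(suppressWarnings(
      stats::predict(fit, newdata = te, type = "response")) >= 0.5)
    correct <- correct + sum(pred == te$y)
  }
  correct / length(labels)
}

#' Latent probe across imbalance-sweep segmenters
#'
#' For every trained segmenter of a sweep (run with `keep_models = TRUE`),
#' extracts test-set latents, reduces them with PCA, and reports the
#' cross-validated probe accuracy, mirroring a per-imbalance-fraction
#' accuracy table.
#'
#' @param sweep A `sweep_result` with retained models.
#' @param cohort The `cmr_cohort` the sweep was run on.
#' @param n_components PCA components (default 10).
#' @param cv_folds Stratified CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return Data frame with `fraction_b` and probe `accuracy`.
#' @export
probe_sweep <- function(sweep, cohort, n_components = 10, cv_folds = 5,
                        seed = 1) {
  if (length(sweep$models) == 0)
    stop("sweep has no retained models; rerun with keep_models = TRUE")
  transform <- NULL
  if (sweep$intervention == "cropped") {
    pool <- setdiff(names(cohort$subjects), sweep$test_ids)
    transform <- make_crop_transform(cohort, pool)
  }
  subjects <- cohort$subjects[sweep$test_ids]
  rows <- lapply(seq_along(sweep$models), function(k) {
    lat <- cohort_latents(sweep$models[[k]], subjects, transform)
    k_comp <- min(n_components, dim(lat$vectors))
    red <- pca_reduce(lat$vectors, k_comp)
    data.frame(fraction_b = sweep$table$fraction_b[k],
               accuracy = probe_accuracy(red$scores, lat$labels, cv_folds,
                                         seed,
                                         groups = lat$provenance$subject_id))
  })
  do.call(rbind, rows)
}
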