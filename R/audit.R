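# End-to-end orchestration of the audit: cohort generation, channel-combo
# classification, crop/blur interventions, attribution taxonomy, imbalance
# sweep (original + cropped), latent probes, and confounder regression.

#' Configuration for a full audit
#'
#' All sample sizes, hyperparameters and seeds for [run_full_audit()] in one
#' serializable object. Defaults are desk-scale.
#'
#' @param n_per_group Subjects per group in the generated cohort.
#' @param shift A [shift_config()].
#' @param img_size Phantom grid size for the classification cohort.
#' @param seg_img_size Phantom grid size for the segmentation sweep cohort.
#' @param n_test_pairs Matched pairs held out as the test set.
#' @param classifier_runs Repeat runs per channel combination.
#' @param combos Channel combinations to audit.
#' @param sweep_n_per_group,sweep_pool,sweep_test_per_group Sweep cohort
#'   sizes: subjects per group, training pool per group, test subjects per
#'   group.
#' @param fractions Imbalance fractions.
#' @param clf_hyper,seg_hyper Hyperparameter lists.
#' @param blur_sigma Gaussian sigma (pixels) of the blur-heart intervention.
#' @param probe_components,probe_folds Latent-probe settings.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An `audit_config` list.
#' @export
audit_config <- function(n_per_group = 100,
                         shift = shift_config_shifted(),
                         img_size = 96, seg_img_size = 64,
                         n_test_pairs = 20,
                         classifier_runs = 5,
                         combos = c("iii", "sss"),
                         sweep_n_per_group = 32, sweep_pool = 20,
                         sweep_test_per_group = 12,
                         fractions = c(1, 0.75, 0.5, 0.25, 0),
                         clf_hyper = classifier_hyper(),
                         seg_hyper = segmenter_hyper(),
                         blur_sigma = 2,
                         probe_components = 10, probe_folds = 5,
                         seed = 1) {
  structure(as.list(environment()), class = "audit_config")
}

.stage_seed <- function(config, offset) (config$seed * 1000L + offset) %% .Machine$integer.max

#' Run the full bias audit end to end
#'
#' Generates a cohort, builds matched pairs and a pair-preserving split, runs
#' the channel-combination classification audit, the crop and blur
#' interventions, the GradCAM attribution-region taxonomy, the imbalance
#' sweep on original and cropped inputs (on a second, smaller cohort), the
#' latent probe per sweep model, cohort-characteristics tests, and the
#' confounder regression. Every stage records its seed; rerunning with the
#' same config reproduces all numbers exactly.
#'
#' @param config An [audit_config()].
#' @param stages Character vector to restrict which stages run; any of
#'   `"classify"`, `"intervene"`, `"saliency"`, `"sweep"`, `"probe"`,
#'   `"confound"`.
#' @param verbose Print stage progress.
#' @return A named list (report bundle) with one element per stage plus the
#'   `config` and per-stage `seeds` used.
#' @export
run_full_audit <- function(config = audit_config(),
                           stages = c("classify", "intervene", "saliency",
                                      "sweep", "probe", "confound"),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- Sys.time()
  report <- list(config = config, seeds = list())

  say("generating cohort (n=%d/group, %dx%d) ...", config$n_per_group,
      config$img_size, config$img_size)
  report$seeds$cohort <- .stage_seed(config, 1)
  cohort <- generate_cohort(config$n_per_group, config$shift,
                            seed = report$seeds$cohort,
                            img_size = config$img_size)
  mp <- match_pairs(cohort$covariates)
  report$seeds$split <- .stage_seed(config, 2)
  sp <- split_pairs(mp$pairs, min(config$n_test_pairs, nrow(mp$pairs) - 1),
                    seed = report$seeds$split)
  train_subj <- cohort$subjects[sp$train_ids]
  test_subj <- cohort$subjects[sp$test_ids]
  report$cohort_summary <- list(
    n_subjects = nrow(cohort$covariates), n_pairs = nrow(mp$pairs),
    n_unmatched = length(mp$unmatched),
    n_train = length(sp$train_ids), n_test = length(sp$test_ids))
  report$intensity_histogram <- mean_intensity_histogram(cohort)

  if ("classify" %in% stages) {
    report$seeds$classify <- .stage_seed(config, 3)
    report$classify <- list()
    for (cb in config$combos) {
      say("channel audit [%s], %d runs ...", cb, config$classifier_runs)
      report$classify[[cb]] <- repeat_audit(
        train_subj, test_subj, combo = cb, n_runs = config$classifier_runs,
        base_seed = report$seeds$classify, hyper = config$clf_hyper)
    }
    if (all(c("iii", "sss") %in% names(report$classify)) &&
        config$classifier_runs >= 2)
      report$classify_p_iii_vs_sss <- tryCatch(
        compare_audits_ttest(report$classify$iii$runs$accuracy,
                             report$classify$sss$runs$accuracy),
        error = function(e) NA_real_)
  }

  if ("intervene" %in% stages) {
    say("crop / blur intervention audits ...")
    report$seeds$intervene <- .stage_seed(config, 4)
    crop_tr <- make_crop_transform(cohort, sp$train_ids)
    blur_tr <- function(image, mask, subject)
      list(image = blur_heart(image, mask, sigma = config$blur_sigma),
           mask = mask)
    report$intervene <- list(
      cropped = repeat_audit(train_subj, test_subj, combo = "iii",
                             n_runs = config$classifier_runs,
                             base_seed = report$seeds$intervene,
                             hyper = config$clf_hyper, transform = crop_tr),
      blurred = repeat_audit(train_subj, test_subj, combo = "iii",
                             n_runs = config$classifier_runs,
                             base_seed = report$seeds$intervene,
                             hyper = config$clf_hyper, transform = blur_tr))
  }

  if ("saliency" %in% stages) {
    say("GradCAM attribution-region taxonomy ...")
    report$seeds$saliency <- .stage_seed(config, 5)
    model <- train_group_classifier_on(train_subj, combo = "iii",
                                       hyper = config$clf_hyper,
                                       seed = report$seeds$saliency)
    sm <- .subject_samples(test_subj, channel_combos()$iii)
    masks <- .subject_region_masks(test_subj)
    report$saliency <- region_attribution_summary(model, sm$samples, masks)
  }

  if (any(c("sweep", "probe", "confound") %in% stages)) {
    say("generating sweep cohort (n=%d/group, %dx%d) ...",
        config$sweep_n_per_group, config$seg_img_size, config$seg_img_size)
    report$seeds$sweep_cohort <- .stage_seed(config, 6)
    seg_cohort <- generate_cohort(config$sweep_n_per_group, config$shift,
                                  seed = report$seeds$sweep_cohort,
                                  img_size = config$seg_img_size)
    ids <- split(seg_cohort$covariates$subject_id, seg_cohort$covariates$group)
    report$seeds$sweep_split <- .stage_seed(config, 7)
    set.seed(report$seeds$sweep_split)
    test_ids <- c(sample(ids$A, config$sweep_test_per_group),
                  sample(ids$B, config$sweep_test_per_group))
    train_pool <- list(A = setdiff(ids$A, test_ids),
                       B = setdiff(ids$B, test_ids))
    splits <- imbalance_subsets(train_pool, config$fractions,
                                pool_per_group = config$sweep_pool,
                                seed = report$seeds$sweep_split)
    report$seeds$sweep <- .stage_seed(config, 8)
    if (any(c("sweep", "probe") %in% stages)) {
      say("imbalance sweep, original inputs (%d fractions) ...",
          length(splits))
      report$sweep_original <- run_imbalance_sweep(
        seg_cohort, splits, test_ids, "original", config$seg_hyper,
        seed = report$seeds$sweep, keep_models = TRUE)
      say("imbalance sweep, cropped inputs ...")
      report$sweep_cropped <- run_imbalance_sweep(
        seg_cohort, splits, test_ids, "cropped", config$seg_hyper,
        seed = report$seeds$sweep)
    }
    if ("probe" %in% stages) {
      say("latent probes ...")
      report$seeds$probe <- .stage_seed(config, 9)
      report$probe <- probe_sweep(report$sweep_original, seg_cohort,
                                  config$probe_components,
                                  config$probe_folds,
                                  seed = report$seeds$probe)
    }
    if ("sweep" %in% stages)
      report$sweep_original$models <- list()  # drop weights from the bundle
    if ("confound" %in% stages) {
      say("confounder statistics ...")
      report$characteristics <- cohort_characteristic_tests(seg_cohort$covariates)
      if (!is.null(report$sweep_original)) {
        bal <- which(report$sweep_original$table$fraction_b == 0.5)[1]
        if (!is.na(bal)) {
          dsc <- report$sweep_original$dsc[[bal]]
          report$confounders <- lapply(c(A = "A", B = "B"), function(g) {
            ids_g <- names(dsc[[g]])
            covs <- seg_cohort$covariates[
              match(ids_g, seg_cohort$covariates$subject_id), ]
            # joint OLS needs n > p + 1; small test sets fall back to the
            # per-covariate univariate mode
            n_num <- sum(vapply(covs, is.numeric, logical(1)))
            mode <- if (length(ids_g) > n_num + 1) "joint" else "univariate"
            tryCatch(fit_dsc_regression(dsc[[g]], covs, mode = mode),
                     error = function(e) conditionMessage(e))
          })
        }
      }
    }
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  say("audit complete in %.1f s", report$elapsed_s)
  report
}

#' Train one group classifier directly from phantom subjects
#'
#' Convenience wrapper: composes per-frame samples for a channel combination
#' and trains the classifier once.
#'
#' @param subjects List of `phantom_subject`s.
#' @param combo Channel combination.
#' @param hyper See [classifier_hyper()].
#' @param seed Integer seed.
#' @param transform Optional per-frame transform.
#' @return A `cmr_classifier`.
#' @export
train_group_classifier_on <- function(subjects, combo = "iii",
                                      hyper = classifier_hyper(), seed = 1,
                                      transform = NULL) {
  sm <- .subject_samples(subjects, if (is.character(combo) &&
                                        length(combo) == 1)
    channel_combos()[[combo]] else combo, transform)
  train_group_classifier(sm$samples, sm$labels, hyper, seed = seed)
}

# region masks (heart/body/ghost) for each frame of each subject, parallel to
# the sample list built by .subject_samples
.subject_region_masks <- function(subjects) {
  masks <- list()
  for (s in subjects)
    for (ph in names(s$frames))
      masks[[length(masks) + 1]] <- list(heart = heart_foreground(s$masks[[ph]]),
                                         body = s$aux$body,
                                         ghost = s$aux$ghost)
  masks
}
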