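# Shared fixtures, memoised so expensive objects (cohorts, trained models)
# are built once per session and reused across test files.

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fx_env)) assign(name, maker(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# covariate parameters with all SDs zero: every subject identical to the
# group means (degenerate cohort, useful for deterministic render tests)
degenerate_covariates <- function() {
  d <- covariate_defaults()
  for (g in c("A", "B")) {
    for (nm in c("age", "height", "bmi", "heart_rate", "lvsv", "lvef", "lvedm"))
      d[[g]][[nm]][2] <- 0
    for (nm in c("diabetes", "hypertension", "hypercholesterolaemia", "smoking"))
      d[[g]][[nm]] <- 0
    yr <- d[[g]]$mri_year
    d[[g]]$mri_year <- stats::setNames(c(1, rep(0, length(yr) - 1)), names(yr))
  }
  d
}

# a trivially learnable segmentation task: identical noiseless subjects
trivial_seg_cohort <- function() {
  fixture("trivial_seg_cohort", function() {
    sh <- shift_config(noise_sigma = 0)
    generate_cohort(3, sh, seed = 3, covariate_params = degenerate_covariates(),
                    img_size = 48)
  })
}

trivial_segmenter <- function() {
  fixture("trivial_segmenter", function() {
    coh <- trivial_seg_cohort()
    images <- list(); masks <- list()
    for (s in coh$subjects) for (ph in c("ED", "ES")) {
      images[[length(images) + 1]] <- normalize_image(s$frames[[ph]])
      masks[[length(masks) + 1]] <- s$masks[[ph]]
    }
    train_segmenter(images, masks, segmenter_hyper(epochs = 60, batch = 2),
                    seed = 5)
  })
}

relabel_group <- function(subject, group) {
  subject$group <- group
  subject
}

# tiny two-class constant-intensity classification task
toy_separable_samples <- function(n_per_class = 12, size = 16, seed = 9) {
  set.seed(seed)
  samples <- list(); labels <- integer()
  for (i in seq_len(2 * n_per_class)) {
    y <- as.integer(i > n_per_class)
    base <- if (y == 1) 0.8 else 0.2
    samples[[i]] <- array(base + rnorm(size * size * 3, 0, 0.02),
                          c(size, size, 3))
    labels[i] <- y
  }
  list(samples = samples, labels = labels)
}
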