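test_that("Dice agrees with brute-force set arithmetic on random masks", {
  # stated examples
  a <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(dice(a, a, 1), 1)
  b <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(dice(a, b, 1), 0)
  p <- matrix(0L, 3, 3); p[1, 1:2] <- 1L
  g <- matrix(0L, 3, 3); g[1, 2:3] <- 1L
  expect_equal(dice(p, g, 1), 0.5)
  expect_equal(dice(matrix(0L, 2, 2), matrix(0L, 2, 2), 1), 1)  # both empty
  expect_error(dice(matrix(0L, 2, 2), matrix(0L, 3, 3), 1), "grids")

  set.seed(14)
  for (i in 1:100) {
    pm <- matrix(sample(0:3, 36, TRUE), 6, 6)
    gm <- matrix(sample(0:3, 36, TRUE), 6, 6)
    lab <- sample(1:3, 1)
    # oracle: explicit coordinate-set arithmetic
    ps <- which(pm == lab); gs <- which(gm == lab)
    oracle <- if (length(ps) + length(gs) == 0) 1 else
      2 * length(intersect(ps, gs)) / (length(ps) + length(gs))
    expect_identical(dice(pm, gm, lab), oracle)
  }
})

test_that("Mann-Whitney p-values are exact for small samples and stars map correctly", {
  p <- mann_whitney(c(0.1, 0.2, 0.3, 0.4, 0.5), c(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_equal(p, 2 / 252, tolerance = 1e-12)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(mann_whitney(numeric(0), 1), "empty")

  expect_equal(significance_stars(0.00005), "****")
  expect_equal(significance_stars(0.0001), "****")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.2), "ns")
})

test_that("the segmenter memorizes a trivial noiseless task", {
  coh <- trivial_seg_cohort()
  m <- trivial_segmenter()
  # loss decreases over the first 5 epochs
  expect_lt(m$loss[5], m$loss[1])
  s <- coh$subjects[[1]]
  pred <- predict_mask(m, normalize_image(s$frames$ED))
  expect_true(all(pred %in% 0:3))
  dscs <- vapply(1:3, function(l) dice(pred, s$masks$ED, l), numeric(1))
  expect_gte(mean(dscs), 0.9)
  # deterministic predictions for a fixed model and input
  pred2 <- predict_mask(m, normalize_image(s$frames$ED))
  expect_identical(pred, pred2)
  expect_error(train_segmenter(list(), list()), "at least 2")
})

test_that("subject-level DSC is the mean of the six label-frame scores", {
  coh <- trivial_seg_cohort()
  m <- trivial_segmenter()
  s <- coh$subjects[[2]]
  manual <- mean(unlist(lapply(c("ED", "ES"), function(ph) {
    pred <- predict_mask(m, normalize_image(s$frames[[ph]]))
    vapply(1:3, function(l) dice(pred, s$masks[[ph]], l), numeric(1))
  })))
  expect_equal(subject_dsc(m, s), manual)
})

test_that("per-group DSC lists are split by group with one entry per subject", {
  coh <- trivial_seg_cohort()
  m <- trivial_segmenter()
  d <- per_group_dsc(m, coh$subjects)
  expect_length(d$A, 3)
  expect_length(d$B, 3)
  expect_true(all(unlist(d) >= 0 & unlist(d) <= 1))
})

test_that("segmenter training is reproducible for a fixed seed", {
  coh <- trivial_seg_cohort()
  imgs <- lapply(coh$subjects[1:2], function(s) normalize_image(s$frames$ED))
  msks <- lapply(coh$subjects[1:2], function(s) s$masks$ED)
  h <- segmenter_hyper(epochs = 2)
  m1 <- train_segmenter(imgs, msks, h, seed = 4)
  m2 <- train_segmenter(imgs, msks, h, seed = 4)
  expect_identical(m1$par, m2$par)
  expect_identical(predict_mask(m1, imgs[[1]]), predict_mask(m2, imgs[[1]]))
})
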