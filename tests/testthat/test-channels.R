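test_that("min-max normalization rescales to [0,1] and rejects constant images", {
  img <- matrix(c(10, 12, 15, 20), 2, 2)
  out <- normalize_image(img)
  expect_equal(out[1, 2], 0.5)  # (15-10)/(20-10)
  expect_equal(range(out), c(0, 1))
  already <- matrix(c(0, 0.3, 0.7, 1), 2, 2)
  expect_identical(normalize_image(already), already)
  expect_error(normalize_image(matrix(5, 3, 3)), "constant")
})

test_that("mask channels encode to equispaced levels and decode exactly", {
  expect_identical(encode_mask_channel(matrix(0L, 2, 2)), matrix(0, 2, 2))
  expect_equal(encode_mask_channel(matrix(3L, 1, 1))[1, 1], 1)
  set.seed(2)
  m <- matrix(sample(0:3, 64, TRUE), 8, 8)
  expect_identical(decode_mask_channel(encode_mask_channel(m)), m)
  expect_error(encode_mask_channel(matrix(7L, 2, 2)), "unknown label")
})

test_that("channel composition fills the three channels per combo", {
  set.seed(3)
  img <- matrix(runif(64, 1, 2), 8, 8)
  msk <- matrix(sample(0:3, 64, TRUE), 8, 8)
  sss <- compose_channels(img, msk, "sss")
  expect_identical(sss[, , 1], sss[, , 2])
  expect_identical(sss[, , 2], sss[, , 3])
  iii <- compose_channels(img, msk, "iii")
  expect_identical(iii[, , 1], iii[, , 3])
  iss <- compose_channels(img, msk, "iss")
  expect_false(identical(iss[, , 1], iss[, , 2]))
  expect_identical(iss[, , 2], iss[, , 3])
  expect_error(compose_channels(img, NULL, "iss"), "mask")
})

test_that("confusion-matrix metrics match hand arithmetic", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[1:3]), c(accuracy = 1, sensitivity = 1, specificity = 1))
  allpos <- classification_metrics(rep(1, 10), rep(c(1, 0), each = 5))
  expect_equal(unlist(allpos[1:3]), c(accuracy = 0.5, sensitivity = 1, specificity = 0))
  mixed <- classification_metrics(c(rep(1, 30), rep(0, 12), rep(0, 38), rep(1, 4)),
                                  c(rep(1, 42), rep(0, 42)))
  expect_equal(mixed$accuracy, 68 / 84)
  expect_equal(mixed$sensitivity, 30 / 42)
  expect_equal(mixed$specificity, 38 / 42)
})

test_that("the repeat-run t-test handles identical, separated and degenerate arms", {
  expect_equal(compare_audits_ttest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)), 1)
  expect_lt(compare_audits_ttest(c(0.9, 0.91, 0.92), c(0.5, 0.51, 0.52)), 0.001)
  expect_error(compare_audits_ttest(0.9, c(0.5, 0.6)), "at least 2")
  expect_error(compare_audits_ttest(c(0.5, 0.5), c(0.5, 0.5)), "constant")
  expect_equal(compare_audits_ttest(c(0.9, 0.9), c(0.5, 0.5)), 0)
})

test_that("mean-intensity histograms conserve counts and detect a fat intensity shift", {
  # identical groups give identical histograms
  cov <- sample_covariates("A", "M", degenerate_covariates(), id = "A0001")
  set.seed(5); s <- render_subject(cov, shift_config(noise_sigma = 0), img_size = 48)
  fake <- list(subjects = list(a = s, b = relabel_group(s, "B")), img_size = 48)
  h <- mean_intensity_histogram(fake)
  expect_identical(h$counts$A, h$counts$B)
  expect_equal(sum(h$counts$A), 2)  # two frames per subject

  # a positive fat intensity delta shifts group-B mean intensities upward
  sh <- shift_config(fat_intensity_delta = 0.1)
  coh <- generate_cohort(100, sh, seed = 31, img_size = 48)
  hh <- mean_intensity_histogram(coh)
  expect_equal(sum(hh$counts$A), 200)
  expect_equal(sum(hh$counts$B), 200)
  p <- t.test(hh$means$B, hh$means$A, alternative = "greater")$p.value
  expect_lt(p, 0.05)
})
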