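test_that("covariate sampling follows the per-group tables and stays consistent", {
  set.seed(1)
  deg <- degenerate_covariates()
  cov <- sample_covariates("B", "F", deg, id = "B0001")
  expect_equal(cov$bmi, 28.6)
  expect_equal(cov$age, 58.8)
  expect_equal(cov$height, 169.4)
  # derived weight consistent with bmi and height
  expect_equal(cov$weight, cov$bmi * (cov$height / 100)^2)

  set.seed(2)
  cov2 <- sample_covariates("A", "M")
  expect_equal(cov2$weight, cov2$bmi * (cov2$height / 100)^2, tolerance = 1e-12)
  expect_gt(cov2$lvef, 0); expect_lt(cov2$lvef, 1)
  expect_gt(cov2$age, 0)

  expect_error(sample_covariates("C"), "unknown group")
  bad <- covariate_defaults(); bad$A$bmi[2] <- -1
  expect_error(sample_covariates("A", params = bad), "negative SD")
})

test_that("group-B covariates concentrate around the published group means", {
  set.seed(11)
  bmis <- replicate(300, sample_covariates("B")$bmi)
  expect_equal(mean(bmis), 28.6, tolerance = 3 * 5.1 / sqrt(300) / 28.6)
  expect_equal(sd(bmis), 5.1, tolerance = 0.15)
})

test_that("noiseless rendering is piecewise constant and co-registered with masks", {
  set.seed(3)
  sh <- shift_config(noise_sigma = 0)
  cov <- sample_covariates("A", "M", degenerate_covariates(), id = "A0001")
  s <- render_subject(cov, sh)
  img <- s$frames$ED; msk <- s$masks$ED
  expect_true(all(img[msk == 1] == img[msk == 1][1]))   # LVBP one intensity
  expect_true(all(img[msk == 2] == img[msk == 2][1]))   # LVM
  expect_true(all(img[msk == 3] == img[msk == 3][1]))   # RVBP
  # the mask of each structure is exactly the set of pixels at its intensity
  expect_identical(unname(which(img == img[msk == 1][1])), which(msk == 1))
  expect_true(all(sort(unique(c(msk))) %in% 0:3))
  # LVM forms a ring adjacent to LVBP
  expect_gt(sum(msk == 2), 0)
})

test_that("end-systole contracts the blood pools", {
  set.seed(4)
  cov <- sample_covariates("A", "M", degenerate_covariates(), id = "A0001")
  s <- render_subject(cov, shift_config(noise_sigma = 0), contraction = 0.8)
  expect_lt(sum(s$masks$ES == 1), sum(s$masks$ED == 1))
  expect_lt(sum(s$masks$ES == 3), sum(s$masks$ED == 3))
})

test_that("rendering is deterministic given identical covariates and seed", {
  cov <- sample_covariates("B", "F", degenerate_covariates(), id = "B0001")
  set.seed(7); s1 <- render_subject(cov, shift_config_shifted())
  set.seed(7); s2 <- render_subject(cov, shift_config_shifted())
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$aux, s2$aux)
})

test_that("fat and ghost aux masks stay disjoint from the heart foreground", {
  for (sd in 1:6) {
    set.seed(sd)
    for (g in c("A", "B")) {
      s <- render_subject(sample_covariates(g, "F", id = paste0(g, "0001")),
                          shift_config_shifted())
      hm <- (s$masks$ED > 0) | (s$masks$ES > 0)
      expect_false(any((s$aux$fat | s$aux$ghost) & hm))
    }
  }
})

test_that("ghost echoes add exactly amplitude^k copies at k*spacing offsets", {
  img <- matrix(0, 32, 32)
  ring <- matrix(FALSE, 32, 32)
  img[10, 16] <- 5; ring[10, 16] <- TRUE

  out <- inject_ghosting(img, ring, amplitude = 0, spacing = 4, n_echoes = 2)
  expect_identical(out$image, img)

  out1 <- inject_ghosting(img, ring, amplitude = 0.25, spacing = 4, n_echoes = 1)
  expect_equal(out1$image[14, 16], 0.25 * 5)
  expect_true(out1$ghost[14, 16])

  out2 <- inject_ghosting(img, ring, amplitude = 0.25, spacing = 4, n_echoes = 2)
  expect_equal(out2$image[18, 16], 0.25^2 * 5)

  # column-axis echoes move along the other dimension
  outc <- inject_ghosting(img, ring, amplitude = 0.5, spacing = 4,
                          n_echoes = 1, axis = "col")
  expect_equal(outc$image[10, 20], 0.5 * 5)

  # echoes beyond the grid are clipped without error
  img2 <- matrix(0, 8, 8); ring2 <- matrix(FALSE, 8, 8)
  img2[7, 4] <- 1; ring2[7, 4] <- TRUE
  outz <- inject_ghosting(img2, ring2, amplitude = 0.5, spacing = 4, n_echoes = 2)
  expect_equal(sum(outz$image), sum(img2))

  expect_error(inject_ghosting(img, ring, 0.5, spacing = 0.5, n_echoes = 1),
               "spacing")
})

test_that("cohorts have the requested size, sex parity, and are reproducible", {
  coh <- generate_cohort(5, shift_config(), seed = 10, img_size = 48)
  expect_equal(nrow(coh$covariates), 10)
  sex_a <- table(coh$covariates$sex[coh$covariates$group == "A"])
  expect_equal(as.integer(sex_a[c("M", "F")]), c(3L, 2L))  # odd n: extra male

  coh2 <- generate_cohort(3, shift_config(), seed = 77, img_size = 48)
  coh3 <- generate_cohort(3, shift_config(), seed = 77, img_size = 48)
  expect_identical(coh2$subjects[["A0001"]]$frames,
                   coh3$subjects[["A0001"]]$frames)
  expect_identical(coh2$covariates, coh3$covariates)

  expect_error(generate_cohort(0), "n_per_group")
})

test_that("null configuration makes groups exchangeable in intensity and covariates", {
  nonsig_int <- 0; nonsig_cov <- 0
  for (r in 1:20) {
    coh <- generate_cohort(20, shift_config_null(), seed = 900 + r,
                           covariate_params = covariate_defaults_null(),
                           img_size = 48)
    # subject-level mean intensity (ED/ES frames of one subject are
    # correlated, so the t-test must run on per-subject aggregates)
    mi <- vapply(coh$subjects, function(s)
      mean(c(s$frames$ED, s$frames$ES)), numeric(1))
    grp <- coh$covariates$group[match(names(coh$subjects),
                                      coh$covariates$subject_id)]
    nonsig_int <- nonsig_int +
      (t.test(mi[grp == "A"], mi[grp == "B"])$p.value > 0.05)
    nonsig_cov <- nonsig_cov +
      (t.test(bmi ~ group, data = coh$covariates)$p.value > 0.05)
  }
  expect_gte(nonsig_int, 18)
  expect_gte(nonsig_cov, 18)
})
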