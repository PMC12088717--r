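test_that("heart bounding boxes match a brute-force coordinate scan", {
  # stated example: foreground rows 3-5, cols 2-7 (0-based) -> [3,6) x [2,8)
  m <- matrix(0L, 10, 10); m[4:6, 3:8] <- 1L
  bb <- heart_bbox(m)
  expect_equal(unlist(bb), c(row_min = 3, row_max = 6, col_min = 2, col_max = 8))
  one <- matrix(0L, 10, 10); one[5, 5] <- 2L
  expect_equal(unlist(heart_bbox(one)),
               c(row_min = 4, row_max = 5, col_min = 4, col_max = 5))
  expect_error(heart_bbox(matrix(0L, 5, 5)), "no foreground")

  set.seed(9)
  for (i in 1:20) {
    mm <- matrix(sample(0:3, 144, TRUE, prob = c(0.8, .07, .07, .06)), 12, 12)
    if (!any(mm > 0)) next
    fg <- which(mm > 0, arr.ind = TRUE)
    expect_equal(unlist(heart_bbox(mm)),
                 c(row_min = min(fg[, 1]) - 1, row_max = max(fg[, 1]),
                   col_min = min(fg[, 2]) - 1, col_max = max(fg[, 2])))
  }
})

test_that("the global crop size is the per-axis maximum over bounding boxes", {
  m1 <- matrix(0L, 20, 20); m1[3:12, 4:15] <- 1L   # 10 x 12
  m2 <- matrix(0L, 20, 20); m2[2:15, 5:12] <- 1L   # 14 x 8
  expect_equal(unname(global_crop_size(list(m1, m2))), c(14, 12))
  expect_equal(unname(global_crop_size(list(m1))), c(10, 12))
  small <- matrix(0L, 20, 20); small[8:9, 8:9] <- 1L
  expect_equal(global_crop_size(list(m1, m2, small)),
               global_crop_size(list(m1, m2)))
})

test_that("crops are fixed-size, contain the heart, centre correctly, and idempotent", {
  set.seed(10)
  img <- matrix(runif(400), 20, 20)
  msk <- matrix(0L, 20, 20); msk[9:12, 8:13] <- 1L
  cr <- crop_to_heart(img, msk, c(8, 8))
  expect_equal(dim(cr$image), c(8, 8))
  expect_equal(sum(cr$mask > 0), sum(msk > 0))  # all foreground contained

  # bbox centred at the image centre gives a symmetric window within parity
  msk2 <- matrix(0L, 20, 20); msk2[9:12, 9:12] <- 1L
  cr2 <- crop_to_heart(img, msk2, c(10, 10))
  expect_lte(abs(cr2$origin["row"] - (20 - 10) / 2), 1)
  expect_lte(abs(cr2$origin["col"] - (20 - 10) / 2), 1)

  # cropping an already-cropped window to the same size is the identity
  cr3 <- crop_to_heart(cr$image, cr$mask, c(8, 8))
  expect_identical(cr3$image, cr$image)

  # windows clipped by the edge shift rather than shrink
  msk3 <- matrix(0L, 20, 20); msk3[1:4, 1:4] <- 1L
  cr4 <- crop_to_heart(img, msk3, c(10, 10))
  expect_equal(dim(cr4$image), c(10, 10))
  expect_equal(sum(cr4$mask > 0), 16)

  expect_error(crop_to_heart(img, msk, c(30, 8)), "larger than the image")
})

test_that("blurring the heart changes only foreground pixels", {
  set.seed(11)
  img <- matrix(runif(900), 30, 30)
  msk <- matrix(0L, 30, 30); msk[12:18, 12:18] <- 1L
  out <- blur_heart(img, msk, sigma = 3)
  expect_identical(out[msk == 0L], img[msk == 0L])   # background bit-identical
  expect_false(identical(out[msk > 0L], img[msk > 0L]))

  tiny <- blur_heart(img, msk, sigma = 0.05)
  expect_lt(max(abs(tiny - img)), 1e-6)              # identity limit

  flat <- matrix(0.4, 30, 30)
  out_flat <- blur_heart(flat, msk, sigma = 3)
  expect_equal(out_flat, flat, tolerance = 1e-8)     # constant is invariant

  expect_error(blur_heart(img, msk, sigma = 0))
})
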