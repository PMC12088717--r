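# Correctness of the hand-rolled networks: analytic gradients are checked
# against central finite differences, and the trainers are exercised on a
# trivially separable task, a determinism contract, and a permutation null.

ns <- asNamespace("cmraudit")

test_that("classifier backward pass matches numerical gradients", {
  set.seed(42)
  par <- ns$.new_classifier(in_ch = 3, w1 = 4, w2 = 6)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- 1
  loss_fn <- function(p) {
    lg <- ns$.clf_forward(p, x)$logit
    pr <- 1 / (1 + exp(-lg))
    -(y * log(pr) + (1 - y) * log(1 - pr))
  }
  cs <- ns$.clf_forward(par, x, cache = TRUE)
  pr <- 1 / (1 + exp(-cs$logit))
  bk <- ns$.clf_backward(par, cs, pr - y)
  eps <- 1e-5
  for (ly in c("conv1", "res_a", "res_b", "conv2")) {
    v <- c(par$layers[[ly]]$W)
    idx <- seq_len(min(15, length(v)))
    ng <- vapply(idx, function(i) {
      pp <- par; pp$layers[[ly]]$W[i] <- v[i] + eps
      pm <- par; pm$layers[[ly]]$W[i] <- v[i] - eps
      (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }, numeric(1))
    an <- c(bk$grads$layers[[ly]]$W)[idx]
    expect_lt(max(abs(an - ng)) / max(abs(ng) + 1e-8), 1e-5)
  }
  ng_head <- vapply(seq_along(par$head$w), function(i) {
    pp <- par; pp$head$w[i] <- par$head$w[i] + eps
    pm <- par; pm$head$w[i] <- par$head$w[i] - eps
    (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(bk$grads$head$w - ng_head)), 1e-6)
})

test_that("segmenter loss and backward pass match numerical gradients", {
  set.seed(43)
  logits <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  mask <- matrix(sample(0:3, 64, TRUE), 8, 8)
  ls <- ns$.seg_loss(logits, mask)
  eps <- 1e-6
  idx <- sample.int(length(logits), 40)
  ng <- vapply(idx, function(i) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    (ns$.seg_loss(lp, mask)$loss - ns$.seg_loss(lm, mask)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(ng - ls$dlogits[idx])) / max(abs(ng)), 1e-5)

  spar <- ns$.new_segmenter(w = c(3, 4, 5))
  sx <- array(runif(16 * 16), c(16, 16, 1))
  sy <- matrix(sample(0:3, 256, TRUE), 16, 16)
  sloss <- function(p) ns$.seg_loss(ns$.seg_forward(p, sx)$logits, sy)$loss
  cs <- ns$.seg_forward(spar, sx, cache = TRUE)
  gg <- ns$.seg_backward(spar, cs, ns$.seg_loss(cs$logits, sy)$dlogits)
  for (ly in c("enc1", "enc2", "dec2", "head")) {
    v <- c(spar$layers[[ly]]$W)
    idx <- seq_len(min(12, length(v)))
    ng <- vapply(idx, function(i) {
      pp <- spar; pp$layers[[ly]]$W[i] <- v[i] + 1e-5
      pm <- spar; pm$layers[[ly]]$W[i] <- v[i] - 1e-5
      (sloss(pp) - sloss(pm)) / 2e-5
    }, numeric(1))
    an <- c(gg$layers[[ly]]$W)[idx]
    expect_lt(max(abs(an - ng)) / max(abs(ng) + 1e-8), 1e-4)
  }
})

test_that("the classifier fits a linearly separable toy task", {
  toy <- toy_separable_samples()
  m <- train_group_classifier(toy$samples, toy$labels,
                              classifier_hyper(epochs = 25, lr = 0.01,
                                               augment = FALSE),
                              seed = 2)
  ev <- evaluate_classifier(m, toy$samples, toy$labels)
  expect_gte(ev$accuracy, 0.95)
})

test_that("training is bit-reproducible for a fixed seed", {
  toy <- toy_separable_samples()
  h <- classifier_hyper(epochs = 2)
  m1 <- train_group_classifier(toy$samples, toy$labels, h, seed = 8)
  m2 <- train_group_classifier(toy$samples, toy$labels, h, seed = 8)
  expect_identical(m1$par, m2$par)
  expect_error(train_group_classifier(toy$samples, rep(1, length(toy$labels))),
               "both classes")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  toy <- toy_separable_samples(n_per_class = 16)
  accs <- vapply(1:5, function(sd) {
    set.seed(100 + sd)
    yperm <- sample(toy$labels)
    tr <- c(1:12, 17:28); te <- setdiff(seq_along(yperm), tr)
    m <- train_group_classifier(toy$samples[tr], yperm[tr],
                                classifier_hyper(epochs = 4, augment = FALSE),
                                seed = sd)
    evaluate_classifier(m, toy$samples[te], yperm[te])$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("both optimizers run and inputs are padded to the pooling grid", {
  toy <- toy_separable_samples(n_per_class = 4)
  m_sgd <- train_group_classifier(toy$samples, toy$labels,
                                  classifier_hyper(epochs = 1, optimizer = "sgd",
                                                   lr = 0.05),
                                  seed = 1)
  expect_s3_class(m_sgd, "cmr_classifier")
  # non-multiple-of-8 input is padded internally, not rejected
  odd <- lapply(toy$samples, function(x) x[1:13, 1:11, , drop = FALSE])
  m_odd <- train_group_classifier(odd, toy$labels,
                                  classifier_hyper(epochs = 1), seed = 1)
  expect_length(classifier_predict(m_odd, odd), length(odd))
})

test_that("augmentation preserves grids and mask label codes", {
  set.seed(12)
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  msk <- matrix(sample(0:3, 576, TRUE), 24, 24)
  ag <- ns$.augment_sample(x, msk, p_rotate = 1)
  expect_equal(dim(ag$x), dim(x))
  expect_equal(dim(ag$mask), dim(msk))
  expect_true(all(ag$mask %in% 0:3))
})
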