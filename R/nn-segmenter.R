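# U-shaped encoder-decoder segmenter (4 output classes).
#
# Architecture (input H x W x 1, H divisible by 4):
#   enc1 conv(1,w1)+ReLU -> maxpool2 -> enc2 conv(w1,w2)+ReLU -> maxpool2
#   -> bottleneck conv(w2,w3)+ReLU                      (latent layer)
#   -> upsample2 -> concat enc2 -> dec1 conv(w3+w2,w2)+ReLU
#   -> upsample2 -> concat enc1 -> dec2 conv(w2+w1,w1)+ReLU
#   -> 1x1 conv(w1,4) logits
# Loss: pixelwise cross-entropy + soft Dice over the three foreground
# classes, optimised by SGD with momentum under a 'poly' learning-rate decay.

.new_segmenter <- function(w = c(8, 16, 32), n_classes = 4) {
  list(layers = list(enc1 = .conv_layer(1, w[1]),
                     enc2 = .conv_layer(w[1], w[2]),
                     bott = .conv_layer(w[2], w[3]),
                     dec1 = .conv_layer(w[3] + w[2], w[2]),
                     dec2 = .conv_layer(w[2] + w[1], w[1]),
                     head = .conv_layer(w[1], n_classes, k = 1, pad = 0)),
       widths = w, n_classes = n_classes)
}

.seg_forward <- function(par, x, cache = FALSE) {
  z1 <- .conv_fwd(x, par$layers$enc1); a1 <- .relu(z1)
  mp1 <- cpp_maxpool2_fwd(a1)
  z2 <- .conv_fwd(mp1$y, par$layers$enc2); a2 <- .relu(z2)
  mp2 <- cpp_maxpool2_fwd(a2)
  z3 <- .conv_fwd(mp2$y, par$layers$bott); a3 <- .relu(z3)
  u1 <- cpp_upsample2_fwd(a3)
  c1 <- .concat3(u1, a2)
  z4 <- .conv_fwd(c1, par$layers$dec1); a4 <- .relu(z4)
  u2 <- cpp_upsample2_fwd(a4)
  c2 <- .concat3(u2, a1)
  z5 <- .conv_fwd(c2, par$layers$dec2); a5 <- .relu(z5)
  logits <- .conv_fwd(a5, par$layers$head)
  if (!cache) return(list(logits = logits, latent = a3))
  list(logits = logits, latent = a3, x = x, z1 = z1, a1 = a1, i1 = mp1$idx,
       p1 = mp1$y, z2 = z2, a2 = a2, i2 = mp2$idx, p2 = mp2$y, z3 = z3,
       a3 = a3, c1 = c1, z4 = z4, a4 = a4, c2 = c2, z5 = z5, a5 = a5)
}

.seg_backward <- function(par, cs, dlogits) {
  w <- par$widths
  bh <- .conv_bwd(cs$a5, par$layers$head, dlogits)
  dz5 <- .relu_bwd(bh$dx, cs$z5)
  b5 <- .conv_bwd(cs$c2, par$layers$dec2, dz5)
  du2 <- b5$dx[, , seq_len(w[2]), drop = FALSE]
  da1_skip <- b5$dx[, , w[2] + seq_len(w[1]), drop = FALSE]
  dz4 <- .relu_bwd(cpp_upsample2_bwd(du2), cs$z4)
  b4 <- .conv_bwd(cs$c1, par$layers$dec1, dz4)
  du1 <- b4$dx[, , seq_len(w[3]), drop = FALSE]
  da2_skip <- b4$dx[, , w[3] + seq_len(w[2]), drop = FALSE]
  dz3 <- .relu_bwd(cpp_upsample2_bwd(du1), cs$z3)
  b3 <- .conv_bwd(cs$p2, par$layers$bott, dz3)
  da2 <- cpp_maxpool2_bwd(b3$dx, cs$i2) + da2_skip
  dz2 <- .relu_bwd(da2, cs$z2)
  b2 <- .conv_bwd(cs$p1, par$layers$enc2, dz2)
  da1 <- cpp_maxpool2_bwd(b2$dx, cs$i1) + da1_skip
  dz1 <- .relu_bwd(da1, cs$z1)
  b1 <- .conv_bwd(cs$x, par$layers$enc1, dz1)
  list(layers = list(enc1 = list(W = b1$dW, b = b1$db),
                     enc2 = list(W = b2$dW, b = b2$db),
                     bott = list(W = b3$dW, b = b3$db),
                     dec1 = list(W = b4$dW, b = b4$db),
                     dec2 = list(W = b5$dW, b = b5$db),
                     head = list(W = bh$dW, b = bh$db)))
}

.softmax3 <- function(logits) {
  m <- apply(logits, c(1, 2), max)
  e <- exp(sweep(logits, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

# combined CE + soft-Dice loss; returns loss value and gradient w.r.t. logits
.seg_loss <- function(logits, mask, n_classes = 4, eps = 1e-6) {
  p <- .softmax3(logits)
  npix <- prod(dim(mask))
  onehot <- array(0, dim(p))
  for (k in seq_len(n_classes)) onehot[, , k] <- (mask == k - 1) * 1
  ce <- -sum(onehot * log(pmax(p, 1e-12))) / npix
  dce_logits <- (p - onehot) / npix  # CE gradient directly in logit space
  # soft Dice over foreground classes 1..3
  dice_loss <- 0
  ddice <- array(0, dim(p))
  fg <- 2:n_classes
  for (k in fg) {
    pk <- p[, , k]; gk <- onehot[, , k]
    num <- 2 * sum(pk * gk) + eps
    den <- sum(pk) + sum(gk) + eps
    dice_loss <- dice_loss + (1 - num / den)
    ddice[, , k] <- -(2 * gk * den - num) / den^2
  }
  dice_loss <- dice_loss / length(fg)
  ddice <- ddice / length(fg)
  # chain the Dice term through softmax: dz_k = p_k * (dp_k - sum_c p_c dp_c)
  dot <- apply(p * ddice, c(1, 2), sum)
  dlogits <- dce_logits + p * sweep(ddice, c(1, 2), dot)
  list(loss = ce + dice_loss, dlogits = dlogits)
}

#' Scaled-down segmenter training hyperparameters
#'
#' Defaults are a desk-scale recipe: 25 epochs of Adam at learning rate
#' 0.005 under a poly decay schedule (exponent 0.9), batch 4, base width 8,
#' mirror/translate augmentation. Adam is the default because it converges
#' reliably within the small desk-scale step budget; the full-scale published
#' recipe (SGD, 500 epochs, initial rate 0.01, momentum 0.99, batch 16) is
#' reachable via `optimizer = "sgd"` and overriding fields.
#'
#' @param epochs,lr,momentum,batch,poly_exp Training schedule (`momentum`
#'   applies to the SGD optimizer only).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param widths Channel widths of the three encoder stages.
#' @param augment Logical; mirror/translate augmentation of image and mask.
#' @return A named list of hyperparameters.
#' @export
segmenter_hyper <- function(epochs = 25, lr = 0.005, momentum = 0.9,
                            batch = 4, poly_exp = 0.9,
                            optimizer = c("adam", "sgd"),
                            widths = c(8, 16, 32), augment = TRUE) {
  optimizer <- match.arg(optimizer)
  as.list(environment())
}

#' Train the encoder-decoder segmenter
#'
#' @param images List of greyscale matrices (already normalized).
#' @param masks List of matching integer label matrices (0..3).
#' @param hyper See [segmenter_hyper()].
#' @param seed Integer seed.
#' @return An object of class `cmr_segmenter` (parameters + loss log).
#' @export
train_segmenter <- function(images, masks, hyper = segmenter_hyper(), seed = 1) {
  if (length(images) < 2) stop("need at least 2 training images")
  stopifnot(length(images) == length(masks))
  if (any(dim(images[[1]])[1:2] %% 4 != 0))
    stop("segmenter input dimensions must be divisible by 4")
  set.seed(seed)
  par <- .new_segmenter(w = hyper$widths)
  use_adam <- identical(hyper$optimizer, "adam")
  if (use_adam)
    opt <- list(m = .zero_like(par["layers"]), v = .zero_like(par["layers"]),
                t = 0)
  else
    mom <- .zero_like(par["layers"])
  n <- length(images)
  steps_total <- hyper$epochs * ceiling(n / hyper$batch)
  step <- 0
  loss_log <- numeric(hyper$epochs)
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = hyper$batch)) {
      lr <- hyper$lr * (1 - step / steps_total)^hyper$poly_exp
      step <- step + 1
      idx <- ord[start:min(start + hyper$batch - 1, n)]
      acc <- NULL
      for (i in idx) {
        x <- .as_cube(images[[i]]); y <- masks[[i]]
        if (hyper$augment) {
          ag <- .augment_sample(x, y)
          x <- ag$x; y <- ag$mask
        }
        cs <- .seg_forward(par, x, cache = TRUE)
        ls <- .seg_loss(cs$logits, y, par$n_classes)
        ep_loss <- ep_loss + ls$loss
        acc <- .grad_accum(acc, .seg_backward(par, cs, ls$dlogits))
      }
      acc <- .grad_scale(acc, 1 / length(idx))
      if (use_adam) {
        st <- .adam_step(par["layers"], acc, opt, lr)
        par$layers <- st$p$layers; opt <- st$state
      } else {
        st <- .sgd_step(par["layers"], acc, mom, lr, hyper$momentum)
        par$layers <- st$p$layers; mom <- st$m
      }
    }
    loss_log[ep] <- ep_loss / n
  }
  structure(list(par = par, hyper = hyper, seed = seed, loss = loss_log),
            class = "cmr_segmenter")
}

#' Predict a segmentation mask
#'
#' Per-pixel argmax over the 4 class scores.
#'
#' @param model A `cmr_segmenter`.
#' @param image Normalized greyscale matrix on the trained grid.
#' @return Integer label matrix (0=background, 1=LVBP, 2=LVM, 3=RVBP).
#' @export
predict_mask <- function(model, image) {
  logits <- .seg_forward(model$par, .as_cube(image))$logits
  apply(logits, c(1, 2), which.max) - 1L
}

#' Extract a latent vector from the segmenter encoder
#'
#' The decoder is ignored; the bottleneck feature maps are spatially
#' average-pooled into one fixed-length vector per image.
#'
#' @param model A `cmr_segmenter`.
#' @param image Normalized greyscale matrix.
#' @return Numeric vector of length `widths[3]`.
#' @export
extract_latent <- function(model, image) {
  x <- .as_cube(image)
  z1 <- .conv_fwd(x, model$par$layers$enc1); a1 <- .relu(z1)
  p1 <- cpp_maxpool2_fwd(a1)$y
  z2 <- .conv_fwd(p1, model$par$layers$enc2); a2 <- .relu(z2)
  p2 <- cpp_maxpool2_fwd(a2)$y
  a3 <- .relu(.conv_fwd(p2, model$par$layers$bott))
  .gap(a3)
}
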