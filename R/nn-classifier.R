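# Residual-style convolutional group classifier.
#
# Architecture (input H x W x 3, H divisible by 8):
#   avgpool2 stem -> conv(3,w1)+ReLU -> maxpool2
#   -> residual block [conv(w1,w1)+ReLU -> conv(w1,w1) + skip] + ReLU -> maxpool2
#   -> conv(w1,w2)+ReLU   (last convolutional layer, used by GradCAM)
#   -> global average pool -> linear -> logit
# Binary cross-entropy on the logit; group B is the positive class.

.new_classifier <- function(in_ch = 3, w1 = 8, w2 = 16) {
  list(layers = list(conv1 = .conv_layer(in_ch, w1),
                     res_a = .conv_layer(w1, w1),
                     res_b = .conv_layer(w1, w1),
                     conv2 = .conv_layer(w1, w2)),
       head = list(w = stats::rnorm(w2, 0, sqrt(1 / w2)), b = 0))
}

.clf_forward <- function(par, x, cache = FALSE) {
  # inputs of any size are zero-padded up to a multiple of 8 so the pooling
  # pyramid divides evenly (tight crop windows need not be /8 themselves)
  x <- .pad_to_multiple(.as_cube(x), 8)$x
  # zero-centre the [0,1] channels: symmetric inputs condition the
  # optimisation much better at these small step counts
  x0 <- cpp_avgpool2_fwd(x) - 0.5
  z1 <- .conv_fwd(x0, par$layers$conv1); a1 <- .relu(z1)
  mp1 <- cpp_maxpool2_fwd(a1); p1 <- mp1$y
  z2 <- .conv_fwd(p1, par$layers$res_a); a2 <- .relu(z2)
  z3 <- .conv_fwd(a2, par$layers$res_b) + p1; a3 <- .relu(z3)
  mp2 <- cpp_maxpool2_fwd(a3); p2 <- mp2$y
  z4 <- .conv_fwd(p2, par$layers$conv2); a4 <- .relu(z4)
  g <- .gap(a4)
  logit <- sum(g * par$head$w) + par$head$b
  if (!cache) return(list(logit = logit))
  list(logit = logit, x0 = x0, z1 = z1, p1 = p1, i1 = mp1$idx, z2 = z2,
       a2 = a2, z3 = z3, i2 = mp2$idx, p2 = p2, z4 = z4, a4 = a4, g = g)
}

# returns grads and (optionally) the gradient of the logit w.r.t. the last
# conv activations, which GradCAM consumes
.clf_backward <- function(par, cs, dlogit) {
  hw <- prod(dim(cs$a4)[1:2])
  d_head_w <- dlogit * cs$g
  d_head_b <- dlogit
  da4 <- array(rep(dlogit * par$head$w / hw, each = hw), dim = dim(cs$a4))
  dz4 <- .relu_bwd(da4, cs$z4)
  b4 <- .conv_bwd(cs$p2, par$layers$conv2, dz4)
  da3 <- cpp_maxpool2_bwd(b4$dx, cs$i2)
  dz3 <- .relu_bwd(da3, cs$z3)
  b3 <- .conv_bwd(cs$a2, par$layers$res_b, dz3)
  dz2 <- .relu_bwd(b3$dx, cs$z2)
  b2 <- .conv_bwd(cs$p1, par$layers$res_a, dz2)
  dp1 <- b2$dx + dz3  # conv path + identity skip
  da1 <- cpp_maxpool2_bwd(dp1, cs$i1)
  dz1 <- .relu_bwd(da1, cs$z1)
  b1 <- .conv_bwd(cs$x0, par$layers$conv1, dz1)
  list(grads = list(layers = list(conv1 = list(W = b1$dW, b = b1$db),
                                  res_a = list(W = b2$dW, b = b2$db),
                                  res_b = list(W = b3$dW, b = b3$db),
                                  conv2 = list(W = b4$dW, b = b4$db)),
                    head = list(w = d_head_w, b = d_head_b)),
       da4 = da4)
}

.grad_shape_like <- function(par) {
  list(layers = lapply(par$layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       head = list(w = par$head$w * 0, b = 0))
}

#' Scaled-down classifier training hyperparameters
#'
#' The defaults are a desk-scale CPU recipe: 12 epochs of Adam at learning
#' rate 0.002 (decayed by 10 at the three-quarter epoch), batch 16,
#' mirror/translate augmentation. Adam is used by default because at these
#' small step counts it converges far more reliably than plain SGD; the
#' full-scale published recipe (SGD with momentum, 100 epochs, learning rate
#' 0.001 decayed by 10 every 50 epochs) is available via
#' `optimizer = "sgd"`.
#'
#' @param epochs,lr,momentum,batch,decay_epoch,decay Training schedule
#'   (`momentum` applies to the SGD optimizer only).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param w1,w2 Channel widths of the two stages.
#' @param augment Logical; apply train-time augmentation.
#' @param p_rotate Probability of a random small rotation per sample.
#' @param val_fraction Fraction of training subjects held out per run as a
#'   validation split (monitored, not used for model selection).
#' @return A named list of hyperparameters.
#' @export
classifier_hyper <- function(epochs = 12, lr = 0.002, momentum = 0.9,
                             batch = 16, decay_epoch = ceiling(0.75 * epochs),
                             decay = 0.1, optimizer = c("adam", "sgd"),
                             w1 = 8, w2 = 16, augment = TRUE,
                             p_rotate = 0.2, val_fraction = 0.2) {
  optimizer <- match.arg(optimizer)
  as.list(environment())
}

#' Train the group classifier
#'
#' Trains the small residual CNN with binary cross-entropy and SGD with
#' momentum and stepped learning-rate decay. Deterministic given `seed`.
#'
#' @param samples List of `H x W x 3` arrays (see [compose_channels()]).
#' @param labels Integer/logical vector; 1 = group B (positive class).
#' @param hyper See [classifier_hyper()].
#' @param seed Integer seed.
#' @return An object of class `cmr_classifier` (parameters + training log).
#' @export
train_group_classifier <- function(samples, labels, hyper = classifier_hyper(),
                                   seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  par <- .new_classifier(in_ch = dim(samples[[1]])[3],
                         w1 = hyper$w1, w2 = hyper$w2)
  use_adam <- identical(hyper$optimizer, "adam")
  if (use_adam)
    opt <- list(m = .zero_like(par), v = .zero_like(par), t = 0)
  else
    mom <- .zero_like(par)
  n <- length(samples)
  loss_log <- numeric(hyper$epochs)
  lr <- hyper$lr
  for (ep in seq_len(hyper$epochs)) {
    if (ep == hyper$decay_epoch + 1) lr <- lr * hyper$decay
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = hyper$batch)) {
      idx <- ord[start:min(start + hyper$batch - 1, n)]
      acc <- NULL
      for (i in idx) {
        x <- samples[[i]]
        if (hyper$augment) x <- .augment_sample(x, p_rotate = hyper$p_rotate)$x
        cs <- .clf_forward(par, x, cache = TRUE)
        p <- 1 / (1 + exp(-cs$logit))
        y <- labels[i]
        ep_loss <- ep_loss - (y * log(max(p, 1e-12)) +
                              (1 - y) * log(max(1 - p, 1e-12)))
        bk <- .clf_backward(par, cs, p - y)
        acc <- .grad_accum(acc, bk$grads)
      }
      acc <- .grad_scale(acc, 1 / length(idx))
      if (use_adam) {
        st <- .adam_step(par, acc, opt, lr)
        par <- st$p; opt <- st$state
      } else {
        st <- .sgd_step(par, acc, mom, lr, hyper$momentum)
        par <- st$p; mom <- st$m
      }
    }
    loss_log[ep] <- ep_loss / n
  }
  structure(list(par = par, hyper = hyper, seed = seed, loss = loss_log),
            class = "cmr_classifier")
}

#' Predicted group-B probabilities
#' @param model A `cmr_classifier`.
#' @param samples List of input arrays.
#' @return Numeric vector of probabilities.
#' @export
classifier_predict <- function(model, samples) {
  vapply(samples, function(x) {
    1 / (1 + exp(-.clf_forward(model$par, x)$logit))
  }, numeric(1))
}

#' Confusion-matrix metrics from binary predictions
#'
#' Group B is the positive class: sensitivity is the fraction of group-B
#' samples predicted B, specificity the fraction of group-A samples
#' predicted A.
#'
#' @param predictions Predicted labels (1 = group B).
#' @param labels True labels (1 = group B).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `predictions`.
#' @export
classification_metrics <- function(predictions, labels) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels))
  tp <- sum(predictions == 1 & labels == 1)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       predictions = predictions)
}

#' Evaluate the group classifier on a labelled sample set
#'
#' @param model A `cmr_classifier`.
#' @param samples List of input arrays.
#' @param labels True labels (1 = group B).
#' @param threshold Decision threshold on the predicted probability.
#' @return See [classification_metrics()].
#' @export
evaluate_classifier <- function(model, samples, labels, threshold = 0.5) {
  if (length(samples) == 0) stop("evaluation set is empty")
  pred <- as.integer(classifier_predict(model, samples) >= threshold)
  classification_metrics(pred, labels)
}
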