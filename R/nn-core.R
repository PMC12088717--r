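# Shared pieces of the small from-scratch networks: layer constructors,
# activation helpers, SGD-with-momentum updates, and train-time augmentation.
# All randomness flows through R's RNG so seeded runs are bit-reproducible.

.as_cube <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# symmetric zero-padding of (H, W, C) up to multiples of `m`; returns the
# padded array and the top/left offsets of the original region
.pad_to_multiple <- function(x, m = 8) {
  d <- dim(x)
  pr <- (m - d[1] %% m) %% m
  pc <- (m - d[2] %% m) %% m
  if (pr == 0 && pc == 0)
    return(list(x = x, r0 = 0L, c0 = 0L, h = d[1], w = d[2]))
  out <- array(0, c(d[1] + pr, d[2] + pc, d[3]))
  r0 <- pr %/% 2; c0 <- pc %/% 2
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- x
  list(x = out, r0 = r0, c0 = c0, h = d[1], w = d[2])
}

.conv_layer <- function(cin, cout, k = 3, stride = 1, pad = 1) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = rep(0, cout), k = k, stride = stride, pad = pad)
}

.conv_fwd <- function(x, ly) cpp_conv2d_fwd(.as_cube(x), ly$W, ly$b, ly$k, ly$stride, ly$pad)
.conv_bwd <- function(x, ly, gy) cpp_conv2d_bwd(.as_cube(x), ly$W, gy, ly$k, ly$stride, ly$pad)

.relu <- function(x) { x[x < 0] <- 0; x }
.relu_bwd <- function(gy, z) { gy[z <= 0] <- 0; gy }

.gap <- function(a) apply(a, 3, mean)

.concat3 <- function(a, b) {
  out <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

.zero_like <- function(par) rapply(par, function(x) x * 0, how = "replace")

# momentum SGD over a nested parameter list; iterates over the gradient
# structure so non-trainable layer metadata (kernel size etc.) is untouched
.sgd_step <- function(par, grad, mom, lr, mu) {
  walk <- function(p, g, m) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m
      }
      return(list(p = p, m = m))
    }
    m <- mu * m - lr * g
    list(p = p + m, m = m)
  }
  walk(par, grad, mom)
}

.grad_accum <- function(acc, g) {
  if (is.null(acc)) return(g)
  walk <- function(a, b) {
    if (is.list(a)) { for (nm in names(a)) a[[nm]] <- walk(a[[nm]], b[[nm]]); return(a) }
    a + b
  }
  walk(acc, g)
}

.grad_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")

# Adam update over a nested parameter list; state carries first/second moment
# estimates (same shapes as the gradients) and the step counter
.adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(par, grad, state$m, state$v)
  list(p = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# mirror / translate / (optional) rotate augmentation applied jointly to an
# image stack and, when given, its label mask (kept exact: integer shifts,
# nearest-neighbour rotation for masks)
.augment_sample <- function(x, mask = NULL, max_shift = 3, p_rotate = 0,
                            max_angle = 10) {
  if (stats::runif(1) < 0.5) {
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  dr <- sample(-max_shift:max_shift, 1)
  dc <- sample(-max_shift:max_shift, 1)
  shift2 <- function(m, fill = 0) {
    out <- matrix(fill, nrow(m), ncol(m))
    r_src <- intersect(seq_len(nrow(m)), seq_len(nrow(m)) - dr)
    c_src <- intersect(seq_len(ncol(m)), seq_len(ncol(m)) - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  for (ch in seq_len(dim(x)[3])) x[, , ch] <- shift2(x[, , ch])
  if (!is.null(mask)) mask <- shift2(mask)
  if (p_rotate > 0 && stats::runif(1) < p_rotate) {
    ang <- stats::runif(1, -max_angle, max_angle)
    for (ch in seq_len(dim(x)[3]))
      x[, , ch] <- EBImage::rotate(x[, , ch], ang,
                                   output.dim = dim(x)[1:2], bg.col = 0)
    if (!is.null(mask))
      mask <- round(EBImage::rotate(mask, ang, filter = "none",
                                    output.dim = dim(mask), bg.col = 0))
  }
  list(x = x, mask = mask)
}
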