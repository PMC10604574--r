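# Compact 2D U-Net implemented directly on base-R arrays.
#
# Convolutions are 3x3 same-padding, realized as one BLAS matrix multiply
# per layer through an im2col expansion; the encoder halves resolution with
# 2x2 max-pooling, the decoder restores it with nearest-neighbour upsampling
# followed by a 3x3 convolution, with skip connections concatenated at each
# scale. The head is a 1x1 convolution with a per-pixel softmax. Everything
# has a hand-written backward pass so the network is trainable with Adam on
# a single CPU; gradients are verified numerically in the test suite.
#
# Tensors are arrays (H, W, C); parameters live in a flat named list with
# conv weights as (9*Cin) x Cout matrices.

#' U-Net configuration
#'
#' @param preset `"tiny"` (filters 8-128, for 64 x 64 phantoms; the default
#'   test and demonstration surface) or `"paper"` (filters 64-1024 as used
#'   for full-resolution radiographs).
#' @param encoder_filters,decoder_filters Filter counts per scale; the
#'   decoder must be one stage shorter than the encoder.
#' @param kernel_size Convolution kernel size (odd; the implementation
#'   supports 3).
#' @param learning_rate Adam step size.
#' @param batch_size Cases per optimizer step.
#' @param epochs Maximum training epochs.
#' @param early_stop_tol Minimum epoch-mean loss improvement counted as
#'   progress.
#' @param patience Epochs without improvement before stopping.
#' @param augment_factor On-the-fly augmentation multiplier per epoch (1 =
#'   no augmentation).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(preset = c("tiny", "paper"),
                        encoder_filters = NULL, decoder_filters = NULL,
                        kernel_size = 3L, learning_rate = NULL,
                        batch_size = 10L, epochs = 5L,
                        early_stop_tol = 1e-3, patience = 2L,
                        augment_factor = 1L) {
  preset <- match.arg(preset)
  if (is.null(encoder_filters))
    encoder_filters <- switch(preset,
                              tiny = c(8L, 16L, 32L, 64L, 128L),
                              paper = c(64L, 128L, 256L, 512L, 1024L))
  if (is.null(decoder_filters))
    decoder_filters <- rev(encoder_filters)[-1L]
  if (is.null(learning_rate))
    learning_rate <- switch(preset, tiny = 1e-3, paper = 1e-4)
  if (length(decoder_filters) != length(encoder_filters) - 1L)
    abort("decoder must have one fewer stage than the encoder")
  if (kernel_size %% 2L == 0L) abort("kernel size must be odd")
  if (kernel_size != 3L) abort("only 3x3 kernels are implemented")
  structure(
    list(preset = preset,
         encoder_filters = as.integer(encoder_filters),
         decoder_filters = as.integer(decoder_filters),
         kernel_size = as.integer(kernel_size),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         early_stop_tol = early_stop_tol,
         patience = as.integer(patience),
         augment_factor = as.integer(augment_factor),
         loss = "soft_dice"),
    class = "unet_config")
}

# ---- primitive layers -------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  out <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    blk <- xp[(1:H) + dr + 1L, (1:W) + dc + 1L, , drop = FALSE]
    out[, k * C + seq_len(C)] <- blk
    k <- k + 1L
  }
  out
}

col2im3 <- function(dXc, H, W, C) {
  gp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    gp[(1:H) + dr + 1L, (1:W) + dc + 1L, ] <-
      gp[(1:H) + dr + 1L, (1:W) + dc + 1L, , drop = FALSE] +
      array(dXc[, k * C + seq_len(C)], c(H, W, C))
    k <- k + 1L
  }
  gp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv3_fwd <- function(x, W, b, relu = TRUE) {
  d <- dim(x)
  Xc <- im2col3(x)
  Y <- Xc %*% W
  Y <- sweep(Y, 2L, b, `+`)
  if (relu) {
    mask <- Y > 0
    Y <- Y * mask
  } else mask <- NULL
  list(y = array(Y, c(d[1L], d[2L], ncol(W))),
       cache = list(Xc = Xc, W = W, dim = d, mask = mask))
}

conv3_bwd <- function(dy, cache) {
  d <- cache$dim
  dY <- matrix(dy, d[1L] * d[2L], dim(dy)[3L])
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, cache$W)
  list(dx = col2im3(dXc, d[1L], d[2L], ncol(cache$Xc) / 9L),
       dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  X <- matrix(x, d[1L] * d[2L], d[3L])
  Y <- sweep(X %*% W, 2L, b, `+`)
  list(y = array(Y, c(d[1L], d[2L], ncol(W))),
       cache = list(X = X, W = W, dim = d))
}

conv1_bwd <- function(dy, cache) {
  d <- cache$dim
  dY <- matrix(dy, d[1L] * d[2L], dim(dy)[3L])
  list(dx = array(tcrossprod(dY, cache$W), d),
       dW = crossprod(cache$X, dY), db = colSums(dY))
}

maxpool2_fwd <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  a11 <- x[ro, co, , drop = FALSE]
  a21 <- x[ro + 1L, co, , drop = FALSE]
  a12 <- x[ro, co + 1L, , drop = FALSE]
  a22 <- x[ro + 1L, co + 1L, , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  # deterministic tie-break: route gradient to the first max in scan order
  w11 <- a11 == m
  w21 <- a21 == m & !w11
  w12 <- a12 == m & !w11 & !w21
  w22 <- a22 == m & !w11 & !w21 & !w12
  list(y = m, cache = list(w = list(w11, w21, w12, w22), dim = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dim
  dx <- array(0, d)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  w <- cache$w
  dx[ro, co, ] <- dy * w[[1L]]
  dx[ro + 1L, co, ] <- dy * w[[2L]]
  dx[ro, co + 1L, ] <- dy * w[[3L]]
  dx[ro + 1L, co + 1L, ] <- dy * w[[4L]]
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  idx_r <- rep(seq_len(d[1L]), each = 2L)
  idx_c <- rep(seq_len(d[2L]), each = 2L)
  x[idx_r, idx_c, , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1L], 2L); co <- seq(1L, d[2L], 2L)
  dy[ro, co, , drop = FALSE] + dy[ro + 1L, co, , drop = FALSE] +
    dy[ro, co + 1L, , drop = FALSE] + dy[ro + 1L, co + 1L, , drop = FALSE]
}

softmax_channels <- function(z) {
  d <- dim(z)
  Z <- matrix(z, d[1L] * d[2L], d[3L])
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  array(E / rowSums(E), d)
}

# ---- model ------------------------------------------------------------

he_init <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                      nin, nout)

#' Build a U-Net model
#'
#' Initializes all convolution weights (He-normal, seeded) for the given
#' configuration. The model maps an `(H, W)` image to `(H, W, n_classes)`
#' per-pixel class probabilities summing to 1; inputs whose dimensions are
#' not divisible by `2^(stages-1)` are padded internally and the output is
#' cropped back, so output shape always equals input shape.
#'
#' @param cfg A [unet_config()].
#' @param n_classes Number of output classes (>= 2).
#' @param seed Seed for weight initialization.
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(cfg = unet_config(), n_classes = 3L, seed = 1L) {
  enc <- cfg$encoder_filters
  dec <- cfg$decoder_filters
  L <- length(enc)
  params <- list()
  with_seed(seed, {
    cin <- 1L
    for (i in seq_len(L)) {
      params[[sprintf("enc%d.a.W", i)]] <- he_init(9L * cin, enc[i])
      params[[sprintf("enc%d.a.b", i)]] <- numeric(enc[i])
      params[[sprintf("enc%d.b.W", i)]] <- he_init(9L * enc[i], enc[i])
      params[[sprintf("enc%d.b.b", i)]] <- numeric(enc[i])
      cin <- enc[i]
    }
    prev <- enc[L]
    for (j in seq_len(L - 1L)) {
      skip <- enc[L - j]
      params[[sprintf("dec%d.up.W", j)]] <- he_init(9L * prev, dec[j])
      params[[sprintf("dec%d.up.b", j)]] <- numeric(dec[j])
      params[[sprintf("dec%d.a.W", j)]] <- he_init(9L * (dec[j] + skip), dec[j])
      params[[sprintf("dec%d.a.b", j)]] <- numeric(dec[j])
      params[[sprintf("dec%d.b.W", j)]] <- he_init(9L * dec[j], dec[j])
      params[[sprintf("dec%d.b.b", j)]] <- numeric(dec[j])
      prev <- dec[j]
    }
    params[["head.W"]] <- he_init(prev, n_classes)
    params[["head.b"]] <- numeric(n_classes)
  })
  structure(list(cfg = cfg, n_classes = as.integer(n_classes),
                 params = params, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet_model> preset %s, %d classes, %s parameters\n",
              x$cfg$preset, x$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `unet_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

pad_multiple <- function(x, mult) {
  d <- dim(x)
  H <- as.integer(ceiling(d[1L] / mult) * mult)
  W <- as.integer(ceiling(d[2L] / mult) * mult)
  if (H == d[1L] && W == d[2L]) return(list(x = x, orig = d[1:2]))
  xp <- array(0, c(H, W, if (length(d) > 2L) d[3L] else NULL))
  if (length(d) > 2L) xp[seq_len(d[1L]), seq_len(d[2L]), ] <- x
  else xp[seq_len(d[1L]), seq_len(d[2L])] <- x
  list(x = xp, orig = d[1:2])
}

unet_forward <- function(model, image, with_cache = FALSE) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  L <- length(model$cfg$encoder_filters)
  mult <- 2L^(L - 1L)
  padded <- pad_multiple(image, mult)
  h <- padded$x
  p <- model$params
  caches <- list()
  skips <- list()
  for (i in seq_len(L)) {
    r <- conv3_fwd(h, p[[sprintf("enc%d.a.W", i)]], p[[sprintf("enc%d.a.b", i)]])
    caches[[sprintf("enc%d.a", i)]] <- r$cache
    r <- conv3_fwd(r$y, p[[sprintf("enc%d.b.W", i)]], p[[sprintf("enc%d.b.b", i)]])
    caches[[sprintf("enc%d.b", i)]] <- r$cache
    h <- r$y
    if (i < L) {
      skips[[i]] <- h
      r <- maxpool2_fwd(h)
      caches[[sprintf("pool%d", i)]] <- r$cache
      h <- r$y
    }
  }
  for (j in seq_len(L - 1L)) {
    h <- upsample2_fwd(h)
    r <- conv3_fwd(h, p[[sprintf("dec%d.up.W", j)]], p[[sprintf("dec%d.up.b", j)]])
    caches[[sprintf("dec%d.up", j)]] <- r$cache
    skip <- skips[[L - j]]
    nskip <- dim(skip)[3L]
    h <- array(c(skip, r$y), c(dim(skip)[1:2], nskip + dim(r$y)[3L]))
    caches[[sprintf("dec%d.nskip", j)]] <- nskip
    r <- conv3_fwd(h, p[[sprintf("dec%d.a.W", j)]], p[[sprintf("dec%d.a.b", j)]])
    caches[[sprintf("dec%d.a", j)]] <- r$cache
    r <- conv3_fwd(r$y, p[[sprintf("dec%d.b.W", j)]], p[[sprintf("dec%d.b.b", j)]])
    caches[[sprintf("dec%d.b", j)]] <- r$cache
    h <- r$y
  }
  r <- conv1_fwd(h, p[["head.W"]], p[["head.b"]])
  caches[["head"]] <- r$cache
  probs <- softmax_channels(r$y)
  orig <- padded$orig
  out <- probs[seq_len(orig[1L]), seq_len(orig[2L]), , drop = FALSE]
  if (with_cache)
    list(probs = out, probs_padded = probs, caches = caches, orig = orig)
  else out
}

# backward pass from d(loss)/d(logits) on the padded grid
unet_backward <- function(model, caches, dlogits) {
  L <- length(model$cfg$encoder_filters)
  p <- model$params
  grads <- list()
  r <- conv1_bwd(dlogits, caches[["head"]])
  grads[["head.W"]] <- r$dW; grads[["head.b"]] <- r$db
  dh <- r$dx
  for (j in rev(seq_len(L - 1L))) {
    r <- conv3_bwd(dh, caches[[sprintf("dec%d.b", j)]])
    grads[[sprintf("dec%d.b.W", j)]] <- r$dW
    grads[[sprintf("dec%d.b.b", j)]] <- r$db
    r <- conv3_bwd(r$dx, caches[[sprintf("dec%d.a", j)]])
    grads[[sprintf("dec%d.a.W", j)]] <- r$dW
    grads[[sprintf("dec%d.a.b", j)]] <- r$db
    nskip <- caches[[sprintf("dec%d.nskip", j)]]
    d <- dim(r$dx)
    dskip <- r$dx[, , seq_len(nskip), drop = FALSE]
    dup <- r$dx[, , nskip + seq_len(d[3L] - nskip), drop = FALSE]
    r <- conv3_bwd(dup, caches[[sprintf("dec%d.up", j)]])
    grads[[sprintf("dec%d.up.W", j)]] <- r$dW
    grads[[sprintf("dec%d.up.b", j)]] <- r$db
    dh <- upsample2_bwd(r$dx)
    # stash skip gradient to add when the encoder stage is reached
    grads[[sprintf(".dskip%d", L - j)]] <- dskip
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      dh <- maxpool2_bwd(dh, caches[[sprintf("pool%d", i)]])
      dh <- dh + grads[[sprintf(".dskip%d", i)]]
      grads[[sprintf(".dskip%d", i)]] <- NULL
    }
    r <- conv3_bwd(dh, caches[[sprintf("enc%d.b", i)]])
    grads[[sprintf("enc%d.b.W", i)]] <- r$dW
    grads[[sprintf("enc%d.b.b", i)]] <- r$db
    r <- conv3_bwd(r$dx, caches[[sprintf("enc%d.a", i)]])
    grads[[sprintf("enc%d.a.W", i)]] <- r$dW
    grads[[sprintf("enc%d.a.b", i)]] <- r$db
    dh <- r$dx
  }
  grads
}

#' Per-pixel class probabilities for an image
#'
#' @param model A `unet_model`.
#' @param image Numeric matrix `(H, W)`.
#' @return Array `(H, W, n_classes)`; probabilities sum to 1 per pixel.
#' @export
predict_probs <- function(model, image) {
  unet_forward(model, image)
}

# one-hot target array from an integer class matrix (values 0..K-1)
one_hot <- function(target, K) {
  d <- dim(target)
  out <- array(0, c(d, K))
  for (k in seq_len(K)) out[, , k] <- target == (k - 1L)
  out
}

#' Soft-Dice loss
#'
#' One minus the mean soft Dice coefficient over the foreground classes
#' (class 0 is background): for each class,
#' `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1e-6`.
#'
#' @param pred_probs Array `(H, W, K)` of per-pixel class probabilities.
#' @param target_mask Integer matrix of class ids `0..K-1`.
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, target_mask, eps = 1e-6) {
  d <- dim(pred_probs)
  if (!all(dim(target_mask) == d[1:2]))
    abort("prediction and target shapes differ")
  K <- d[3L]
  t_arr <- one_hot(target_mask, K)
  fg <- 2:K
  dices <- vapply(fg, function(k) {
    p <- pred_probs[, , k]; t <- t_arr[, , k]
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  1 - mean(dices)
}

# loss + gradient wrt logits (through the softmax), on matching shapes
dice_loss_grad <- function(probs, target, eps = 1e-6) {
  d <- dim(probs)
  K <- d[3L]
  t_arr <- one_hot(target, K)
  nfg <- K - 1L
  dP <- array(0, d)
  dices <- numeric(nfg)
  for (k in 2:K) {
    p <- probs[, , k]; t <- t_arr[, , k]
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    dices[k - 1L] <- num / den
    dP[, , k] <- -(2 * t * den - num) / den^2 / nfg
  }
  # softmax backward: dz = p * (dp - sum_k dp_k p_k)
  P <- matrix(probs, d[1L] * d[2L], K)
  G <- matrix(dP, d[1L] * d[2L], K)
  dZ <- P * (G - rowSums(G * P))
  list(loss = 1 - mean(dices), dlogits = array(dZ, d))
}
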