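# Fully convolutional segmentation network, implemented directly on base R
# matrices. Feature maps are (H*W) x C matrices in column-major pixel order;
# 3x3 convolutions are computed as nine shifted matrix products, which keeps
# the whole network inside BLAS. Backpropagation is hand-written. The
# architecture is a VGG19-style encoder truncated to 15 convolution layers
# with five 2x2 max-poolings, a three-layer fully convolutional head, and an
# FCN-8s-style decoder that fuses per-class score maps from the 3rd and 4th
# pooling stages via learned upsampling.

lin_idx <- function(i_range, j_range, H) {
  as.vector(outer(i_range, (j_range - 1L) * H, "+"))
}

conv3x3_offsets <- expand.grid(di = -1:1, dj = -1:1)

conv3x3_forward <- function(X, H, W, layer) {
  out <- matrix(rep(layer$b, each = H * W), H * W)
  for (k in 1:9) {
    di <- conv3x3_offsets$di[k]
    dj <- conv3x3_offsets$dj[k]
    if (max(1L, 1L - di) > min(H, H - di) ||
        max(1L, 1L - dj) > min(W, W - dj)) next
    ti <- max(1L, 1L - di):min(H, H - di)
    tj <- max(1L, 1L - dj):min(W, W - dj)
    tgt <- lin_idx(ti, tj, H)
    src <- lin_idx(ti + di, tj + dj, H)
    out[tgt, ] <- out[tgt, ] + X[src, , drop = FALSE] %*% layer$W[[k]]
  }
  out
}

conv3x3_backward <- function(dY, X, H, W, layer) {
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- vector("list", 9L)
  for (k in 1:9) {
    di <- conv3x3_offsets$di[k]
    dj <- conv3x3_offsets$dj[k]
    if (max(1L, 1L - di) > min(H, H - di) ||
        max(1L, 1L - dj) > min(W, W - dj)) {
      dW[[k]] <- layer$W[[k]] * 0
      next
    }
    ti <- max(1L, 1L - di):min(H, H - di)
    tj <- max(1L, 1L - dj):min(W, W - dj)
    tgt <- lin_idx(ti, tj, H)
    src <- lin_idx(ti + di, tj + dj, H)
    dYt <- dY[tgt, , drop = FALSE]
    dX[src, ] <- dX[src, ] + dYt %*% t(layer$W[[k]])
    dW[[k]] <- crossprod(X[src, , drop = FALSE], dYt)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

conv1x1_forward <- function(X, layer) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

conv1x1_backward <- function(dY, X, layer) {
  list(dX = dY %*% t(layer$W), dW = crossprod(X, dY), db = colSums(dY))
}

maxpool2_forward <- function(X, H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Hp <- H %/% 2L
  Wp <- W %/% 2L
  idx <- lapply(1:4, function(k) {
    a <- (k - 1L) %% 2L
    b <- (k - 1L) %/% 2L
    lin_idx(2L * seq_len(Hp) - 1L + a, 2L * seq_len(Wp) - 1L + b, H)
  })
  best <- X[idx[[1L]], , drop = FALSE]
  bidx <- matrix(1L, nrow(best), ncol(best))
  for (k in 2:4) {
    cand <- X[idx[[k]], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    bidx[upd] <- k
  }
  list(Y = best, bidx = bidx, idx = idx, H = Hp, W = Wp,
       H_in = H, W_in = W)
}

maxpool2_backward <- function(dY, pool, n_channels) {
  npix <- pool$H_in * pool$W_in
  dX <- matrix(0, npix, n_channels)
  np <- nrow(dY)
  for (k in 1:4) {
    sel <- which(pool$bidx == k)
    if (length(sel) == 0L) next
    r <- (sel - 1L) %% np + 1L
    ch <- (sel - 1L) %/% np
    flat <- pool$idx[[k]][r] + ch * npix
    dX[flat] <- dX[flat] + dY[sel]
  }
  dX
}

upsample_nn_forward <- function(X, H, W, s) {
  i_src <- ceiling(seq_len(H * s) / s)
  j_src <- ceiling(seq_len(W * s) / s)
  src <- lin_idx(i_src, j_src, H)
  list(Y = X[src, , drop = FALSE], src = src, n_in = H * W)
}

upsample_nn_backward <- function(dY, up) {
  # every input pixel appears s^2 times in `src`; rowsum over the source
  # index accumulates the gradient (groups 1..n_in are all present, so the
  # sorted rowsum order is the natural order)
  rowsum(dY, up$src)
}

relu <- function(X) {
  X[X < 0] <- 0
  X
}

#' Configuration of the fully convolutional segmentation network
#'
#' The `"full"` configuration is the clinical-scale architecture: a VGG19
#' channel progression (64, 128, 256, 512, 512) truncated to 15
#' convolution layers (2, 2, 4, 4, 3 per block — VGG19 itself has 16; a
#' 16-layer variant is available via `vgg19_full`), five 2x2 max-pool
#' layers, and a three-layer fully convolutional head; per-class score
#' maps from the 3rd and 4th pooling stages are fused into the upsampling
#' path, and the output is two per-pixel score channels (fossa, muscle) at
#' the input resolution. The `"small"` configuration keeps the identical
#' topology with thin channels for CPU-scale experiments on phantoms.
#'
#' @param variant `"small"` or `"full"`.
#' @param in_size input side length; must be divisible by 32 (five
#'   poolings).
#' @param vgg19_full if `TRUE`, keep VGG19's 16th encoder convolution.
#' @return An object of class `fcn_config`.
#' @export
fcn_config <- function(variant = c("small", "full"), in_size = 512L,
                       vgg19_full = FALSE) {
  variant <- match.arg(variant)
  if (in_size %% 32L != 0L) {
    stop("in_size must be divisible by 32 (five 2x2 poolings)",
         call. = FALSE)
  }
  if (variant == "full") {
    channels <- c(64L, 128L, 256L, 512L, 512L)
    convs <- c(2L, 2L, 4L, 4L, if (vgg19_full) 4L else 3L)
    head_channels <- 256L
  } else {
    channels <- c(8L, 16L, 24L, 32L, 32L)
    convs <- c(1L, 1L, 1L, 1L, 1L)
    head_channels <- 32L
  }
  structure(
    list(
      variant = variant,
      in_size = as.integer(in_size),
      channels = channels,
      convs_per_block = convs,
      conv_layers = sum(convs),
      pool_layers = 5L,
      head_layers = 3L,
      head_channels = head_channels,
      skip_sources = c("pool3", "pool4"),
      out_channels = 2L
    ),
    class = "fcn_config"
  )
}

#' Output shape of the network for a given input
#'
#' The decoder restores the input resolution, so an `H x H` single-channel
#' input maps to `H x H x 2` per-pixel scores.
#'
#' @param config an [fcn_config()].
#' @param in_size optional input side length overriding the config.
#' @return integer vector `c(height, width, channels)`.
#' @export
fcn_output_shape <- function(config, in_size = config$in_size) {
  if (in_size %% 32L != 0L) {
    stop("in_size must be divisible by 32", call. = FALSE)
  }
  c(in_size, in_size, config$out_channels)
}

new_conv3x3 <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(W = lapply(1:9, function(k) matrix(stats::rnorm(cin * cout, 0, sd),
                                          cin, cout)),
       b = numeric(cout), kind = "conv3")
}

new_conv1x1 <- function(cin, cout, sd = sqrt(2 / cin)) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
       b = numeric(cout), kind = "conv1")
}

#' Build the segmentation network
#'
#' Allocates and He-initializes all parameters; deterministic given
#' `seed`.
#'
#' @param config an [fcn_config()].
#' @param seed integer seed for the initialization.
#' @return An object of class `fcn_model` with elements `config` and
#'   `params` (named list of layer parameter sets).
#' @export
build_fcn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fcn_config"))
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (b in 1:5) {
      for (i in seq_len(config$convs_per_block[b])) {
        p[[sprintf("enc%d_%d", b, i)]] <- new_conv3x3(cin,
                                                      config$channels[b])
        cin <- config$channels[b]
      }
    }
    hc <- config$head_channels
    p$head1 <- new_conv3x3(config$channels[5L], hc)
    p$head2 <- new_conv1x1(hc, hc)
    p$score <- new_conv1x1(hc, 2L, sd = sqrt(1 / hc))
    p$score_pool4 <- new_conv1x1(config$channels[4L], 2L,
                                 sd = sqrt(1 / config$channels[4L]))
    p$score_pool3 <- new_conv1x1(config$channels[3L], 2L,
                                 sd = sqrt(1 / config$channels[3L]))
    p$up4 <- new_conv3x3(2L, 2L)
    p$up3 <- new_conv3x3(2L, 2L)
    p$up_final <- new_conv3x3(2L, 2L)
    p
  })
  structure(list(config = config, params = params), class = "fcn_model")
}

#' Total parameter count of the network
#'
#' @param model an `fcn_model`.
#' @return integer number of scalar parameters.
#' @export
fcn_parameter_count <- function(model) {
  sum(vapply(model$params, function(l) {
    nw <- if (is.list(l$W)) sum(vapply(l$W, length, integer(1))) else
      length(l$W)
    nw + length(l$b)
  }, numeric(1)))
}

#' Forward pass of the network
#'
#' @param model an `fcn_model`.
#' @param image numeric matrix `H x H` with intensities scaled to
#'   `[0, 1]`, or a [grayscale_slice()] (scaled internally).
#' @param keep_cache keep intermediate activations for backpropagation.
#' @return list with `logits` (`(H*W) x 2` matrix), `prob` (sigmoid of
#'   logits), `H`, `W`, and (if requested) `cache`.
#' @export
fcn_forward <- function(model, image, keep_cache = FALSE) {
  if (inherits(image, "grayscale_slice")) image <- image$pixels / 255
  H <- nrow(image)
  W <- ncol(image)
  if (H %% 32L != 0L || W %% 32L != 0L) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  p <- model$params
  cache <- list(H = H, W = W)
  X <- matrix(as.numeric(image), H * W, 1L)
  h <- H
  w <- W
  pools <- list()
  for (b in 1:5) {
    for (i in seq_len(model$config$convs_per_block[b])) {
      nm <- sprintf("enc%d_%d", b, i)
      pre <- conv3x3_forward(X, h, w, p[[nm]])
      if (keep_cache) cache[[paste0(nm, "_in")]] <- X
      X <- relu(pre)
      if (keep_cache) cache[[paste0(nm, "_out")]] <- X
    }
    pool <- maxpool2_forward(X, h, w)
    pools[[b]] <- pool
    X <- pool$Y
    h <- pool$H
    w <- pool$W
  }
  # fully convolutional head on pool5 features
  if (keep_cache) cache$head1_in <- X
  A1 <- relu(conv3x3_forward(X, h, w, p$head1))
  if (keep_cache) cache$head1_out <- A1
  A2 <- relu(conv1x1_forward(A1, p$head2))
  if (keep_cache) cache$head2_out <- A2
  S5 <- conv1x1_forward(A2, p$score)

  # decoder: learned upsampling with pool4/pool3 score fusion
  up_a <- upsample_nn_forward(S5, h, w, 2L)
  h4 <- pools[[4L]]$H
  w4 <- pools[[4L]]$W
  U4in <- up_a$Y
  U4 <- conv3x3_forward(U4in, h4, w4, p$up4)
  SP4 <- conv1x1_forward(pools[[4L]]$Y, p$score_pool4)
  F4 <- U4 + SP4

  up_b <- upsample_nn_forward(F4, h4, w4, 2L)
  h3 <- pools[[3L]]$H
  w3 <- pools[[3L]]$W
  U3in <- up_b$Y
  U3 <- conv3x3_forward(U3in, h3, w3, p$up3)
  SP3 <- conv1x1_forward(pools[[3L]]$Y, p$score_pool3)
  F3 <- U3 + SP3

  up_c <- upsample_nn_forward(F3, h3, w3, 8L)
  logits <- conv3x3_forward(up_c$Y, H, W, p$up_final)

  out <- list(logits = logits, prob = 1 / (1 + exp(-logits)), H = H, W = W)
  if (keep_cache) {
    cache$pools <- pools
    cache$h5 <- h
    cache$w5 <- w
    cache$S5 <- S5
    cache$up_a <- up_a
    cache$U4in <- U4in
    cache$up_b <- up_b
    cache$U3in <- U3in
    cache$up_c <- up_c
    cache$F4 <- F4
    cache$F3 <- F3
    out$cache <- cache
  }
  out
}

#' @keywords internal
fcn_backward <- function(model, fwd, target) {
  p <- model$params
  cfg <- model$config
  cache <- fwd$cache
  H <- cache$H
  W <- cache$W
  n <- length(fwd$logits)
  grads <- list()

  dlogits <- (fwd$prob - target) / n
  g <- conv3x3_backward(dlogits, cache$up_c$Y, H, W, p$up_final)
  grads$up_final <- g[c("dW", "db")]
  dF3 <- upsample_nn_backward(g$dX, cache$up_c)

  h3 <- cache$pools[[3L]]$H
  w3 <- cache$pools[[3L]]$W
  g <- conv1x1_backward(dF3, cache$pools[[3L]]$Y, p$score_pool3)
  grads$score_pool3 <- g[c("dW", "db")]
  dPool3_extra <- g$dX
  g <- conv3x3_backward(dF3, cache$U3in, h3, w3, p$up3)
  grads$up3 <- g[c("dW", "db")]
  dF4 <- upsample_nn_backward(g$dX, cache$up_b)

  h4 <- cache$pools[[4L]]$H
  w4 <- cache$pools[[4L]]$W
  g <- conv1x1_backward(dF4, cache$pools[[4L]]$Y, p$score_pool4)
  grads$score_pool4 <- g[c("dW", "db")]
  dPool4_extra <- g$dX
  g <- conv3x3_backward(dF4, cache$U4in, h4, w4, p$up4)
  grads$up4 <- g[c("dW", "db")]
  dS5 <- upsample_nn_backward(g$dX, cache$up_a)

  g <- conv1x1_backward(dS5, cache$head2_out, p$score)
  grads$score <- g[c("dW", "db")]
  dA2 <- g$dX * (cache$head2_out > 0)
  g <- conv1x1_backward(dA2, cache$head1_out, p$head2)
  grads$head2 <- g[c("dW", "db")]
  dA1 <- g$dX * (cache$head1_out > 0)
  g <- conv3x3_backward(dA1, cache$head1_in, cache$h5, cache$w5, p$head1)
  grads$head1 <- g[c("dW", "db")]
  dX <- g$dX

  extras <- list(NULL, NULL, dPool3_extra, dPool4_extra, NULL)
  for (b in 5:1) {
    # skip-connection gradients enter at the pooled feature map of
    # blocks 3 and 4, before the pooling backward
    if (!is.null(extras[[b]])) dX <- dX + extras[[b]]
    dX <- maxpool2_backward(dX, cache$pools[[b]], cfg$channels[b])
    h <- cache$pools[[b]]$H_in
    w <- cache$pools[[b]]$W_in
    for (i in rev(seq_len(cfg$convs_per_block[b]))) {
      nm <- sprintf("enc%d_%d", b, i)
      dpre <- dX * (cache[[paste0(nm, "_out")]] > 0)
      g <- conv3x3_backward(dpre, cache[[paste0(nm, "_in")]], h, w, p[[nm]])
      grads[[nm]] <- g[c("dW", "db")]
      dX <- g$dX
    }
  }
  grads
}
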