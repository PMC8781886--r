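#' Network configuration for CDCA-rPPGNet
#'
#' The default configuration is the full CDCA-rPPGNet architecture: a
#' 1x5x5 stem convolution (3 -> 16 channels), four CDC+CBAM blocks with
#' channel widths 32, 64, 64, 64, spatial 1x2x2 average pooling after the
#' stem and after each block but the last, adaptive average pooling to
#' 1x1 spatial, and a final 1x1x1 convolution collapsing 64 channels to the
#' one-dimensional pulse trace. Temporal resolution is never reduced, so a
#' T-frame clip always yields a T-sample trace.
#'
#' @param clip_len nominal clip length in frames (the network itself is
#'   fully convolutional in time).
#' @param in_size spatial input size `(H, W)` in pixels.
#' @param in_channels colour channels of the input clip.
#' @param stem_channels output channels of the stem convolution.
#' @param block_channels integer vector of per-block channel widths; its
#'   length sets the number of CDC+CBAM blocks.
#' @param stem_kernel,block_kernel kernel shapes `(kt, kh, kw)`.
#' @param theta central-difference trade-off for all block convolutions.
#' @param reduction_ratio CBAM perceptron bottleneck ratio.
#' @param spatial_kernel CBAM spatial-attention kernel edge length.
#' @param intensity_max maximum representable pixel intensity; clips are
#'   divided by this before entering the network.
#' @return object of class `rppg_net_config`.
#' @export
rppg_net_config <- function(clip_len = 128L, in_size = c(96L, 96L),
                            in_channels = 3L, stem_channels = 16L,
                            block_channels = c(32L, 64L, 64L, 64L),
                            stem_kernel = c(1L, 5L, 5L),
                            block_kernel = c(3L, 3L, 3L),
                            theta = 0.6, reduction_ratio = 16L,
                            spatial_kernel = 7L, intensity_max = 255) {
  cfg <- list(clip_len = as.integer(clip_len), in_size = as.integer(in_size),
              in_channels = as.integer(in_channels),
              stem_channels = as.integer(stem_channels),
              block_channels = as.integer(block_channels),
              stem_kernel = as.integer(stem_kernel),
              block_kernel = as.integer(block_kernel),
              theta = theta, reduction_ratio = as.integer(reduction_ratio),
              spatial_kernel = as.integer(spatial_kernel),
              intensity_max = intensity_max)
  if (any(cfg$stem_kernel %% 2L == 0L) || any(cfg$block_kernel %% 2L == 0L))
    stop("all kernel dimensions must be odd")
  n_pool <- 1L + length(cfg$block_channels) - 1L
  if (any(cfg$in_size %% 2L^n_pool != 0L))
    stop("in_size must be divisible by 2^", n_pool,
         " (one halving per pooling stage)")
  structure(cfg, class = "rppg_net_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

conv_layer <- function(name, kernel, cin, cout, pad, theta, act) {
  list(type = "conv", name = name,
       w = he_init(c(kernel, cin, cout), prod(kernel) * cin),
       b = numeric(cout),
       stride = c(1L, 1L, 1L), pad = as.integer(pad),
       theta = theta, act = act)
}

#' Build a CDCA-rPPGNet model
#'
#' Assembles the layer stack described in [rppg_net_config()] with freshly
#' initialised weights (He-scaled normals for convolutions and the CBAM
#' perceptron, zero biases). Seed the R RNG before calling for reproducible
#' initialisation.
#'
#' @param config an [rppg_net_config()].
#' @return object of class `rppg_net`: the layer list plus its config.
#' @export
rppg_net <- function(config = rppg_net_config()) {
  nb <- length(config$block_channels)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  sk <- config$stem_kernel
  add(conv_layer("stem", sk, config$in_channels, config$stem_channels,
                 pad = (sk - 1L) %/% 2L, theta = 0, act = "relu"))
  add(list(type = "pool", name = "pool0"))
  cin <- config$stem_channels
  bk <- config$block_kernel
  for (b in seq_len(nb)) {
    cout <- config$block_channels[b]
    add(conv_layer(sprintf("block%d.conv1", b), bk, cin, cout,
                   pad = (bk - 1L) %/% 2L, theta = config$theta, act = "relu"))
    add(conv_layer(sprintf("block%d.conv2", b), bk, cout, cout,
                   pad = (bk - 1L) %/% 2L, theta = config$theta, act = "relu"))
    cp <- cbam_params(cout, config$reduction_ratio, config$spatial_kernel)
    add(c(list(type = "cbam", name = sprintf("block%d.cbam", b), params = cp),
          list(weights = cbam_init(cp))))
    if (b < nb) add(list(type = "pool", name = sprintf("pool%d", b)))
    cin <- cout
  }
  add(list(type = "gap", name = "gap"))
  add(conv_layer("head", c(1L, 1L, 1L), cin, 1L, pad = c(0L, 0L, 0L),
                 theta = 0, act = "linear"))
  structure(list(config = config, layers = layers), class = "rppg_net")
}

avgpool_hw <- function(x) {
  d <- dim(x)
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  o3 <- seq(1L, d[3], 2L); e3 <- o3 + 1L
  (x[, o2, o3, , drop = FALSE] + x[, e2, o3, , drop = FALSE] +
     x[, o2, e3, , drop = FALSE] + x[, e2, e3, , drop = FALSE]) / 4
}

avgpool_hw_bw <- function(gy, d) {
  gx <- array(0, d)
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  o3 <- seq(1L, d[3], 2L); e3 <- o3 + 1L
  g <- gy / 4
  gx[, o2, o3, ] <- g; gx[, e2, o3, ] <- g
  gx[, o2, e3, ] <- g; gx[, e2, e3, ] <- g
  gx
}

gap_hw <- function(x) {
  d <- dim(x)
  xr <- array(x, c(d[1], d[2] * d[3], d[4]))
  m <- colMeans(aperm(xr, c(2L, 1L, 3L)))            # (T, C)
  array(m, c(d[1], 1L, 1L, d[4]))
}

gap_hw_bw <- function(gy, d) {
  g2 <- array(gy, c(d[1], d[4])) / (d[2] * d[3])
  aperm(array(g2, c(d[1], d[4], d[2], d[3])), c(1L, 3L, 4L, 2L))
}

# Forward pass; with cache = TRUE also returns what the backward pass needs.
net_forward <- function(model, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      w_eff <- cdc_effective_kernel(l$w, l$theta)
      y <- conv3d(x, w_eff, l$b, stride = l$stride, pad = l$pad)
      if (l$act == "relu") y <- pmax(y, 0)
      if (cache) caches[[i]] <- list(x = x, y = y)
    } else if (l$type == "pool") {
      y <- avgpool_hw(x)
      if (cache) caches[[i]] <- list(d = dim(x))
    } else if (l$type == "cbam") {
      fw <- cbam_fw(x, l$weights)
      y <- fw$y
      if (cache) caches[[i]] <- fw
    } else if (l$type == "gap") {
      y <- gap_hw(x)
      if (cache) caches[[i]] <- list(d = dim(x))
    } else stop("unknown layer type: ", l$type)
    x <- y
  }
  list(y = x, caches = caches)
}

# Backward pass given the caches of net_forward(); returns per-layer
# parameter gradients (same structure as the parameters) and nothing else.
net_backward <- function(model, caches, gy) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      cc <- caches[[i]]
      if (l$act == "relu") gy <- gy * (cc$y > 0)
      w_eff <- cdc_effective_kernel(l$w, l$theta)
      cb <- conv3d_backward(cc$x, w_eff, gy, stride = l$stride, pad = l$pad,
                            has_bias = TRUE)
      grads[[i]] <- list(w = cdc_kernel_grad(cb$gw, l$theta), b = cb$gb)
      gy <- cb$gx
    } else if (l$type == "pool") {
      gy <- avgpool_hw_bw(gy, caches[[i]]$d)
    } else if (l$type == "cbam") {
      bw <- cbam_bw(caches[[i]], l$weights, gy)
      grads[[i]] <- bw$grads
      gy <- bw$gx
    } else if (l$type == "gap") {
      gy <- gap_hw_bw(gy, caches[[i]]$d)
    }
  }
  grads
}

layer_params <- function(l) {
  switch(l$type,
         conv = list(w = l$w, b = l$b),
         cbam = l$weights,
         NULL)
}

set_layer_params <- function(l, p) {
  if (l$type == "conv") { l$w <- p$w; l$b <- p$b }
  else if (l$type == "cbam") l$weights <- p
  l
}

#' Count trainable parameters
#'
#' @param model an `rppg_net`.
#' @return integer count of independently trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    p <- layer_params(l)
    if (is.null(p)) 0L else sum(vapply(p, length, integer(1)))
  }, integer(1)))
}

#' @export
coef.rppg_net <- function(object, ...) {
  p <- lapply(object$layers, layer_params)
  names(p) <- vapply(object$layers, `[[`, character(1), "name")
  p[!vapply(p, is.null, logical(1))]
}

# Output shape of every layer for a given input shape (T, H, W, C).
net_shapes <- function(model, input_shape) {
  d <- as.integer(input_shape)
  out <- list()
  for (l in model$layers) {
    if (l$type == "conv") {
      kd <- dim(l$w)
      d <- c((d[1] + 2L * l$pad[1] - kd[1]) %/% l$stride[1] + 1L,
             (d[2] + 2L * l$pad[2] - kd[2]) %/% l$stride[2] + 1L,
             (d[3] + 2L * l$pad[3] - kd[3]) %/% l$stride[3] + 1L,
             kd[5])
    } else if (l$type == "pool") {
      d <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4])
    } else if (l$type == "gap") {
      d <- c(d[1], 1L, 1L, d[4])
    }
    out[[l$name]] <- d
  }
  out
}

#' @export
print.rppg_net <- function(x, ...) {
  cfg <- x$config
  cat("CDCA-rPPGNet\n")
  cat(sprintf("  input : %d x %d x %d x %d (T x H x W x C)\n",
              cfg$clip_len, cfg$in_size[1], cfg$in_size[2], cfg$in_channels))
  sh <- net_shapes(x, c(cfg$clip_len, cfg$in_size, cfg$in_channels))
  for (nm in names(sh))
    cat(sprintf("  %-14s -> %s\n", nm, paste(sh[[nm]], collapse = " x ")))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Predict the rPPG trace for one clip
#'
#' Scales the clip to `[0, 1]` by the configured maximum intensity and runs
#' the forward pass. The raw trace is unfiltered; pass it through
#' [bandpass()] before heart-rate estimation.
#'
#' @param object an `rppg_net`.
#' @param clip an `roi_clip` or a `(T, H, W, 3)` array.
#' @param ... unused.
#' @return object of class `rppg_prediction`: the length-T `signal` plus
#'   clip metadata (`start_frame`, `frame_rate`).
#' @export
predict.rppg_net <- function(object, clip, ...) {
  if (inherits(clip, "roi_clip")) {
    x <- clip$frames
    meta <- list(start_frame = clip$start_frame, frame_rate = clip$frame_rate)
  } else {
    x <- clip
    meta <- list(start_frame = 0L, frame_rate = NA_real_)
  }
  d <- dim(x)
  cfg <- object$config
  if (length(d) != 4L || d[4] != cfg$in_channels ||
      !all(d[2:3] == cfg$in_size))
    stop("clip shape ", paste(d, collapse = "x"),
         " does not match the configured input ",
         paste(c("T", cfg$in_size, cfg$in_channels), collapse = "x"))
  out <- net_forward(object, x / cfg$intensity_max)$y
  structure(list(signal = as.vector(out), start_frame = meta$start_frame,
                 frame_rate = meta$frame_rate),
            class = "rppg_prediction")
}

#' @export
print.rppg_prediction <- function(x, ...) {
  cat(sprintf("rPPG prediction: %d samples, start frame %d\n",
              length(x$signal), x$start_frame))
  invisible(x)
}
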