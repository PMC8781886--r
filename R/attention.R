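#' 3-D convolutional block attention (3D-CBAM)
#'
#' Sequential channel and spatial attention for spatiotemporal feature maps.
#' Channel attention pools the map globally over T x H x W (average and max),
#' pushes both descriptors through a shared two-layer perceptron
#' (C -> C/r -> C, inner rectifier, no biases), sums and squashes with a
#' sigmoid; the resulting per-channel weights rescale the map. Spatial
#' attention then pools over channels (average and max), convolves the
#' two-channel stack with a 7x7x7 kernel and squashes with a sigmoid to a
#' per-voxel weight. Both stages are pure element-wise rescalings, so the
#' output shape always equals the input shape and every attention weight
#' lies strictly in (0, 1).
#'
#' @param channels number of feature channels C.
#' @param reduction_ratio bottleneck ratio r of the shared perceptron;
#'   C must be divisible by r. Default 16.
#' @param spatial_kernel odd edge length of the spatial-attention kernel.
#' @return object of class `cbam_params`.
#' @export
cbam_params <- function(channels, reduction_ratio = 16L, spatial_kernel = 7L) {
  channels <- as.integer(channels)
  reduction_ratio <- as.integer(reduction_ratio)
  spatial_kernel <- as.integer(spatial_kernel)
  if (channels %% reduction_ratio != 0L)
    stop("channels (", channels, ") must be divisible by the reduction ratio (",
         reduction_ratio, ")")
  if (spatial_kernel %% 2L == 0L) stop("spatial kernel must be odd")
  structure(list(channels = channels, reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel),
            class = "cbam_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Fresh CBAM weights: shared MLP (no biases) + spatial conv (with bias).
cbam_init <- function(params) {
  C <- params$channels
  Cr <- C %/% params$reduction_ratio
  k <- params$spatial_kernel
  list(W0 = matrix(stats::rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
       W1 = matrix(stats::rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr),
       ws = array(stats::rnorm(k^3 * 2, sd = sqrt(2 / (2 * k^3))),
                  c(k, k, k, 2L, 1L)),
       wb = 0)
}

#' Channel-attention map
#'
#' @param x 4-d feature map `(T, H, W, C)`.
#' @param weights list with `W0` (C/r x C) and `W1` (C x C/r), the shared
#'   perceptron; typically from a built network or [cbam_init()].
#' @return numeric vector of length C with entries in (0, 1).
#' @export
channel_attention <- function(x, weights) {
  channel_attention_fw(x, weights)$map
}

channel_attention_fw <- function(x, weights) {
  d <- dim(x)
  n <- prod(d[1:3])
  Fm <- matrix(x, n, d[4])
  avg <- colMeans(Fm)
  amax <- vapply(seq_len(d[4]), function(c) which.max(Fm[, c]), integer(1))
  mx <- Fm[cbind(amax, seq_len(d[4]))]
  z0a <- pmax(drop(weights$W0 %*% avg), 0)
  z0m <- pmax(drop(weights$W0 %*% mx), 0)
  s <- sigmoid(drop(weights$W1 %*% z0a) + drop(weights$W1 %*% z0m))
  list(map = s, avg = avg, mx = mx, amax = amax, z0a = z0a, z0m = z0m, n = n)
}

#' Spatial-attention map
#'
#' @param x 4-d feature map `(T, H, W, C)` (already channel-refined).
#' @param weights list with `ws` (k x k x k x 2 x 1 kernel) and `wb`
#'   (scalar bias).
#' @return 3-d array `(T, H, W)` with entries in (0, 1).
#' @export
spatial_attention <- function(x, weights) {
  fw <- spatial_attention_fw(x, weights)
  array(fw$map, dim(x)[1:3])
}

spatial_attention_fw <- function(x, weights) {
  d <- dim(x)
  n <- prod(d[1:3])
  Fm <- matrix(x, n, d[4])
  am <- rowMeans(Fm)
  cmax <- max.col(Fm, ties.method = "first")
  mm <- Fm[cbind(seq_len(n), cmax)]
  cc <- array(c(am, mm), c(d[1:3], 2L))
  k <- dim(weights$ws)[1]
  pad <- rep((k - 1L) %/% 2L, 3L)
  pre <- conv3d(cc, weights$ws, weights$wb, pad = pad)
  s <- sigmoid(as.vector(pre))            # length n
  list(map = s, concat = cc, cmax = cmax, pad = pad)
}

#' Apply 3D-CBAM refinement to a feature map
#'
#' Channel attention followed by spatial attention, each applied as an
#' element-wise multiplication.
#'
#' @param x 4-d feature map `(T, H, W, C)`.
#' @param weights list with `W0`, `W1`, `ws`, `wb` (see [cbam_init()]).
#' @return refined feature map with the same shape as `x`.
#' @export
cbam3d <- function(x, weights) {
  cbam_fw(x, weights)$y
}

cbam_fw <- function(x, weights) {
  d <- dim(x)
  n <- prod(d[1:3])
  ca <- channel_attention_fw(x, weights)
  Fp <- matrix(x, n, d[4]) * rep(ca$map, each = n)
  Fp <- array(Fp, d)
  sa <- spatial_attention_fw(Fp, weights)
  y <- array(matrix(Fp, n, d[4]) * sa$map, d)
  list(y = y, x = x, Fp = Fp, ca = ca, sa = sa)
}

# Backward pass through a CBAM stage. `fw` is the cache from cbam_fw().
# Returns gradient w.r.t. the input and the four weight tensors.
cbam_bw <- function(fw, weights, gy) {
  d <- dim(fw$x)
  n <- prod(d[1:3])
  C <- d[4]
  Gy <- matrix(gy, n, C)
  Fpm <- matrix(fw$Fp, n, C)

  ## spatial stage: y = Fp * s_s
  s_s <- fw$sa$map
  gs_s <- rowSums(Fpm * Gy)
  gFp <- Gy * s_s
  gpre <- array(gs_s * s_s * (1 - s_s), c(d[1:3], 1L))
  cb <- conv3d_backward(fw$sa$concat, weights$ws, gpre, pad = fw$sa$pad,
                        has_bias = TRUE)
  gcc <- matrix(cb$gx, n, 2L)
  gFp <- gFp + gcc[, 1L] / C              # channel-average path
  idx <- cbind(seq_len(n), fw$sa$cmax)    # channel-max path
  gFp[idx] <- gFp[idx] + gcc[, 2L]

  ## channel stage: Fp = x * s_c
  ca <- fw$ca
  s_c <- ca$map
  Xm <- matrix(fw$x, n, C)
  gs_c <- colSums(Xm * gFp)
  gX <- gFp * rep(s_c, each = n)
  gz <- gs_c * s_c * (1 - s_c)            # pre-sigmoid gradient, length C
  gW1 <- gz %o% ca$z0a + gz %o% ca$z0m
  gz0a <- drop(crossprod(weights$W1, gz)) * (ca$z0a > 0)
  gz0m <- drop(crossprod(weights$W1, gz)) * (ca$z0m > 0)
  gW0 <- gz0a %o% ca$avg + gz0m %o% ca$mx
  gavg <- drop(crossprod(weights$W0, gz0a))
  gmx <- drop(crossprod(weights$W0, gz0m))
  gX <- gX + matrix(gavg / n, n, C, byrow = TRUE)
  midx <- cbind(ca$amax, seq_len(C))
  gXm <- gX
  gXm[midx] <- gXm[midx] + gmx

  list(gx = array(gXm, d),
       grads = list(W0 = gW0, W1 = gW1, ws = cb$gw, wb = cb$gb))
}
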