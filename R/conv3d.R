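#' 3-D convolution (cross-correlation) of a feature map
#'
#' Low-level building block for the network layers. Feature maps are
#' 4-d arrays ordered `(T, H, W, C)`; kernels are 5-d arrays ordered
#' `(kt, kh, kw, C_in, C_out)`. The operation is the deep-learning
#' convention (no kernel flip).
#'
#' @param x 4-d numeric array `(T, H, W, C_in)`.
#' @param w 5-d numeric array `(kt, kh, kw, C_in, C_out)`.
#' @param bias numeric vector of length `C_out`, or `NULL` for no bias.
#' @param stride integer length-3 `(st, sh, sw)`.
#' @param pad integer length-3 zero padding `(pt, ph, pw)` applied on both
#'   sides of each axis.
#' @return 4-d array `(To, Ho, Wo, C_out)` following the standard
#'   convolution shape formula `(n + 2p - k) %/% s + 1` per axis.
#' @export
conv3d <- function(x, w, bias = NULL, stride = c(1L, 1L, 1L),
                   pad = c(0L, 0L, 0L)) {
  stopifnot(is.array(x), length(dim(x)) == 4L,
            is.array(w), length(dim(w)) == 5L)
  .conv3d_fw(x, w, if (is.null(bias)) numeric(0) else as.numeric(bias),
             as.integer(stride), as.integer(pad))
}

# Gradients of conv3d with respect to input, kernel and bias.
conv3d_backward <- function(x, w, gy, stride = c(1L, 1L, 1L),
                            pad = c(0L, 0L, 0L), has_bias = TRUE) {
  .conv3d_bw(x, w, gy, as.integer(stride), as.integer(pad), has_bias)
}
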