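#' Temporal central-difference convolution (3DCDC-T)
#'
#' A 3-D convolution augmented with a temporal central-difference term: on
#' top of the ordinary windowed weighted sum, each output position receives
#' `theta * (-x(p0) * sum(w[pn]))` where the sum runs over the kernel taps
#' with a nonzero temporal offset (the "adjacent time steps") and `x(p0)` is
#' the centre input sample. `theta = 0` reduces exactly to conventional 3-D
#' convolution; `theta = 1` weights the temporal-gradient information fully.
#' The operator makes the response sensitive to frame-to-frame intensity
#' change, which is where the pulse signal lives.
#'
#' @name cdc3dt
NULL

#' Layer specification for one 3DCDC-T layer
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel integer length-3 `(kt, kh, kw)`; all odd.
#' @param theta trade-off between intensity-level and gradient-level
#'   information, in `[0, 1]`. Default 0.6, the convention of the
#'   central-difference-convolution literature.
#' @param stride,padding integer length-3.
#' @param bias logical; add a per-output-channel bias after the combined sum.
#' @return an object of class `cdc_spec`.
#' @export
cdc_spec <- function(in_channels, out_channels, kernel = c(3L, 3L, 3L),
                     theta = 0.6, stride = c(1L, 1L, 1L),
                     padding = c(1L, 1L, 1L), bias = TRUE) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel <= 0L) || any(kernel %% 2L == 0L))
    stop("kernel dimensions must be positive odd integers")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must be a single value in [0, 1]")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = kernel, theta = theta,
                 stride = as.integer(stride), padding = as.integer(padding),
                 bias = isTRUE(bias)),
            class = "cdc_spec")
}

#' Split a kernel's receptive field into current and adjacent time steps
#'
#' Partitions the kernel offsets into the current time step (temporal offset
#' zero) and the adjacent time steps (nonzero temporal offset). Offsets are
#' centred, e.g. a temporal extent of 3 spans offsets -1, 0, 1.
#'
#' @param kernel integer length-3 `(kt, kh, kw)`, all odd.
#' @return list with integer offset matrices `current` and `adjacent`
#'   (columns `dt`, `dh`, `dw`), forming a disjoint cover of the field.
#' @export
split_receptive_field <- function(kernel) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel %% 2L == 0L) || any(kernel <= 0L))
    stop("kernel dimensions must be positive odd integers")
  half <- (kernel - 1L) %/% 2L
  offs <- as.matrix(expand.grid(dt = -half[1]:half[1],
                                dh = -half[2]:half[2],
                                dw = -half[3]:half[3]))
  cur <- offs[, "dt"] == 0L
  list(current = offs[cur, , drop = FALSE],
       adjacent = offs[!cur, , drop = FALSE])
}

# Sum of kernel weights over the adjacent time steps, per (C_in, C_out).
cdc_adjacent_sum <- function(w) {
  kd <- dim(w)
  ct <- (kd[1] + 1L) %/% 2L
  apply(w, c(4L, 5L), sum) - apply(w[ct, , , , , drop = FALSE], c(4L, 5L), sum)
}

# Fold the central-difference correction into the kernel: subtracting
# theta * sum_{R''} w at the centre tap makes one ordinary convolution
# compute the full 3DCDC-T response.
cdc_effective_kernel <- function(w, theta) {
  if (theta == 0) return(w)
  kd <- dim(w)
  ct <- (kd[1] + 1L) %/% 2L
  ch <- (kd[2] + 1L) %/% 2L
  cw <- (kd[3] + 1L) %/% 2L
  w[ct, ch, cw, , ] <- w[ct, ch, cw, , ] - theta * cdc_adjacent_sum(w)
  w
}

# Map a gradient w.r.t. the effective kernel back onto the raw kernel.
cdc_kernel_grad <- function(gw_eff, theta) {
  if (theta == 0) return(gw_eff)
  kd <- dim(gw_eff)
  ct <- (kd[1] + 1L) %/% 2L
  ch <- (kd[2] + 1L) %/% 2L
  cw <- (kd[3] + 1L) %/% 2L
  gc <- gw_eff[ct, ch, cw, , ]            # (Cin, Cout) centre gradient
  adj_t <- setdiff(seq_len(kd[1]), ct)
  gcorr <- array(0, kd)
  gcorr[adj_t, , , , ] <- rep(-theta * gc,
                              each = length(adj_t) * kd[2] * kd[3]) |>
    array(c(length(adj_t), kd[2], kd[3], kd[4], kd[5]))
  gw_eff + gcorr
}

#' Optimised 3DCDC-T forward pass
#'
#' Computes the temporal central-difference convolution by folding the
#' correction term into the kernel centre and running a single ordinary
#' convolution; numerically identical to [cdc3dt_reference()].
#'
#' @param x 4-d input array `(T, H, W, C_in)`.
#' @param w 5-d kernel array `(kt, kh, kw, C_in, C_out)`.
#' @param bias numeric length `C_out` or `NULL`.
#' @param spec a [cdc_spec()].
#' @return 4-d output array.
#' @export
cdc3dt_forward <- function(x, w, bias, spec) {
  conv3d(x, cdc_effective_kernel(w, spec$theta), bias,
         stride = spec$stride, pad = spec$padding)
}

#' Nested-loop reference for 3DCDC-T (oracle)
#'
#' Direct transcription of the operator definition with explicit loops over
#' output positions and kernel taps. Slow by design; used to validate
#' [cdc3dt_forward()] on small instances.
#'
#' @inheritParams cdc3dt_forward
#' @return 4-d output array.
#' @export
cdc3dt_reference <- function(x, w, bias, spec) {
  xd <- dim(x); kd <- dim(w)
  if (kd[4] != xd[4]) stop("input channel mismatch")
  st <- spec$stride; pd <- spec$padding
  To <- (xd[1] + 2 * pd[1] - kd[1]) %/% st[1] + 1L
  Ho <- (xd[2] + 2 * pd[2] - kd[2]) %/% st[2] + 1L
  Wo <- (xd[3] + 2 * pd[3] - kd[3]) %/% st[3] + 1L
  Cout <- kd[5]
  half <- (kd[1:3] - 1L) %/% 2L
  rf <- split_receptive_field(kd[1:3])
  y <- array(0, c(To, Ho, Wo, Cout))
  at <- function(t, h, w_, c) {           # zero-padded lookup, offsets 1-based
    if (t < 1 || t > xd[1] || h < 1 || h > xd[2] || w_ < 1 || w_ > xd[3])
      return(0)
    x[t, h, w_, c]
  }
  for (co in seq_len(Cout)) for (to in seq_len(To)) {
    t0 <- (to - 1L) * st[1] - pd[1] + 1L + half[1]
    for (ho in seq_len(Ho)) {
      h0 <- (ho - 1L) * st[2] - pd[2] + 1L + half[2]
      for (wo in seq_len(Wo)) {
        w0 <- (wo - 1L) * st[3] - pd[3] + 1L + half[3]
        acc <- 0
        for (ci in seq_len(xd[4])) {
          adj_wsum <- 0
          for (r in seq_len(nrow(rf$current))) {
            o <- rf$current[r, ]
            acc <- acc + w[o[1] + half[1] + 1L, o[2] + half[2] + 1L,
                           o[3] + half[3] + 1L, ci, co] *
              at(t0 + o[1], h0 + o[2], w0 + o[3], ci)
          }
          for (r in seq_len(nrow(rf$adjacent))) {
            o <- rf$adjacent[r, ]
            wv <- w[o[1] + half[1] + 1L, o[2] + half[2] + 1L,
                    o[3] + half[3] + 1L, ci, co]
            acc <- acc + wv * at(t0 + o[1], h0 + o[2], w0 + o[3], ci)
            adj_wsum <- adj_wsum + wv
          }
          acc <- acc + spec$theta * (-at(t0, h0, w0, ci)) * adj_wsum
        }
        y[to, ho, wo, co] <- acc + if (is.null(bias)) 0 else bias[co]
      }
    }
  }
  y
}
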