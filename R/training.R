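#' Negative Pearson correlation loss
#'
#' `1 - r` where `r` is the Pearson correlation between the predicted and
#' reference traces. The loss penalises waveform-shape mismatch only: it is
#' invariant to positive affine transforms of either trace, and ranges over
#' `[0, 2]` (0 at perfect correlation, 2 at perfect anti-correlation). If
#' either trace has zero variance the correlation is undefined; the loss
#' then falls back to 1 with a warning and a zero gradient.
#'
#' @param x predicted trace.
#' @param y reference trace of the same length (frame-rate-aligned PPG).
#' @param gradient also return the gradient with respect to `x`.
#' @return the loss, or (with `gradient = TRUE`) a list `value`, `grad`.
#' @export
neg_pearson_loss <- function(x, y, gradient = FALSE) {
  if (length(x) != length(y)) stop("traces must have equal length")
  if (length(x) < 2L) stop("traces must have at least two samples")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  eps <- .Machine$double.eps * length(x)
  if (sx <= eps * max(1, max(abs(x))) || sy <= eps * max(1, max(abs(y)))) {
    warning("zero-variance trace in Pearson loss; returning 1")
    if (gradient) return(list(value = 1, grad = numeric(length(x))))
    return(1)
  }
  r <- sum(xc * yc) / (sx * sy)
  if (!gradient) return(1 - r)
  g <- yc / (sx * sy) - r * xc / sx^2
  list(value = 1 - r, grad = -(g - mean(g)))
}

#' Left-right flip augmentation
#'
#' Mirrors every frame of a clip along the width axis. The pulse label is
#' unaffected, so flipping doubles the corpus for free.
#'
#' @param clip an `roi_clip` or `(T, H, W, C)` array.
#' @return object of the same kind with the width axis reversed.
#' @export
flip_augment <- function(clip) {
  if (inherits(clip, "roi_clip")) {
    clip$frames <- clip$frames[, , dim(clip$frames)[3]:1, , drop = FALSE]
    return(clip)
  }
  clip[, , dim(clip)[3]:1, , drop = FALSE]
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam at learning rate 2e-4,
#' batch size 8, 30 epochs, 128-frame clips sampled every 8 frames, with
#' left-right flip augmentation.
#'
#' @param learning_rate,batch_size,epochs Adam step size, clips per update,
#'   passes over the corpus.
#' @param clip_len,clip_stride clip sampling geometry in frames.
#' @param flip_augment logical; mirror every clip to double the corpus.
#' @param seed RNG seed threaded through shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 8L, epochs = 30L,
                         clip_len = 128L, clip_stride = 8L,
                         flip_augment = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            clip_len >= 2L, clip_stride >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), clip_len = as.integer(clip_len),
                 clip_stride = as.integer(clip_stride),
                 flip_augment = isTRUE(flip_augment), seed = as.integer(seed)),
            class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, zeros_like))
  array(0, dim(p) %||% length(p))
}

adam_init <- function(params) {
  zeros <- zeros_like(params)
  list(m = zeros, v = zeros, t = 0L)
}

# One Adam update over a nested parameter/gradient structure.
adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

model_params <- function(model) {
  p <- lapply(model$layers, layer_params)
  names(p) <- vapply(model$layers, `[[`, character(1), "name")
  p
}

model_set_params <- function(model, params) {
  for (i in seq_along(model$layers))
    if (!is.null(params[[i]]))
      model$layers[[i]] <- set_layer_params(model$layers[[i]], params[[i]])
  model
}

# Loss and parameter gradients for one clip (already intensity-scaled label).
clip_loss_grads <- function(model, x, label) {
  fw <- net_forward(model, x, cache = TRUE)
  pl <- neg_pearson_loss(as.vector(fw$y), label, gradient = TRUE)
  gy <- array(pl$grad, dim(fw$y))
  list(loss = pl$value, grads = net_backward(model, fw$caches, gy))
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(Map(sum_grads, a, b))
  a + b
}

scale_grads <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, scale_grads, s = s))
  g * s
}

#' Train a CDCA-rPPGNet by negative Pearson correlation
#'
#' Mini-batch Adam over a corpus of ROI clips with frame-aligned reference
#' pulse labels. Batch gradients are averaged over the clips of the batch.
#' When validation clips are supplied the parameters with the best
#' validation loss are retained; otherwise the final parameters are.
#'
#' @param model an [rppg_net()].
#' @param clips list of `roi_clip` objects or `(T, H, W, C)` arrays.
#' @param labels list of numeric traces, one per clip, each of the clip's
#'   length (see [resample_reference()] for alignment).
#' @param config a [train_config()].
#' @param val_clips,val_labels optional held-out clips and labels.
#' @param verbose print one line per epoch.
#' @return object of class `rppg_fit`: the trained `model`, per-epoch
#'   `history` (data frame with train and validation loss), and the config.
#' @export
rppg_train <- function(model, clips, labels, config = train_config(),
                       val_clips = NULL, val_labels = NULL, verbose = FALSE) {
  if (length(clips) == 0L) stop("empty training corpus")
  if (length(clips) != length(labels))
    stop("clips and labels must pair up")
  clip_array <- function(cl) if (inherits(cl, "roi_clip")) cl$frames else cl
  imax <- model$config$intensity_max
  xs <- lapply(clips, function(cl) clip_array(cl) / imax)
  if (config$flip_augment) {
    xs <- c(xs, lapply(xs, function(x) x[, , dim(x)[3]:1, , drop = FALSE]))
    labels <- c(labels, labels)
  }
  vxs <- lapply(val_clips %||% list(), function(cl) clip_array(cl) / imax)

  set.seed(config$seed)
  params <- model_params(model)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n <- length(xs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      acc <- NULL
      bloss <- 0
      for (i in idx) {
        lg <- clip_loss_grads(model, xs[[i]], labels[[i]])
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", ep, ", clip ", i)
        acc <- sum_grads(acc, lg$grads)
        bloss <- bloss + lg$loss
      }
      acc <- scale_grads(acc, 1 / length(idx))
      upd <- adam_step(opt, params, acc, config$learning_rate)
      params <- upd$params
      opt <- upd$state
      model <- model_set_params(model, params)
      ep_loss <- ep_loss + bloss
    }
    ep_loss <- ep_loss / n
    vloss <- NA_real_
    if (length(vxs)) {
      vloss <- mean(vapply(seq_along(vxs), function(i) {
        neg_pearson_loss(as.vector(net_forward(model, vxs[[i]])$y),
                         val_labels[[i]])
      }, numeric(1)))
      if (vloss < best$loss) best <- list(loss = vloss, params = params)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vloss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss,
                      ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
  }
  if (length(vxs)) model <- model_set_params(model, best$params)
  structure(list(model = model, history = hist, config = config),
            class = "rppg_fit")
}

#' @export
print.rppg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("rppg_fit: %d epochs, final train loss %.4f", nrow(h),
              h$train_loss[nrow(h)]))
  if (any(is.finite(h$val_loss)))
    cat(sprintf(", best val loss %.4f", min(h$val_loss, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @export
plot.rppg_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "negative Pearson loss",
                 ylim = range(c(h$train_loss, h$val_loss), na.rm = TRUE), ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", c("train", "validation"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
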