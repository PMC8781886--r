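# Loop-level oracles written directly from the attention definitions.
channel_map_oracle <- function(x, W0, W1) {
  C <- dim(x)[4]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    v <- as.vector(x[, , , c])
    avg[c] <- mean(v); mx[c] <- max(v)
  }
  mlp <- function(v) as.vector(W1 %*% pmax(as.vector(W0 %*% v), 0))
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

spatial_map_oracle <- function(x, ws, wb) {
  d <- dim(x)
  am <- apply(x, 1:3, mean)
  mm <- apply(x, 1:3, max)
  k <- dim(ws)[1]; half <- (k - 1) / 2
  pre <- array(0, d[1:3])
  cc <- list(am, mm)
  for (t in 1:d[1]) for (h in 1:d[2]) for (w_ in 1:d[3]) {
    acc <- wb
    for (ci in 1:2) for (dt in -half:half) for (dh in -half:half)
      for (dw in -half:half) {
        tt <- t + dt; hh <- h + dh; ww <- w_ + dw
        if (tt >= 1 && tt <= d[1] && hh >= 1 && hh <= d[2] &&
            ww >= 1 && ww <= d[3])
          acc <- acc + ws[dt + half + 1, dh + half + 1, dw + half + 1, ci, 1] *
            cc[[ci]][tt, hh, ww]
      }
    pre[t, h, w_] <- acc
  }
  1 / (1 + exp(-pre))
}

random_cbam <- function(C = 4L, r = 2L, k = 3L, seed = 1L) {
  set.seed(seed)
  params <- cbam_params(C, r, k)
  list(params = params, weights = rppgnet:::cbam_init(params),
       x = array(stats::rnorm(5 * 4 * 4 * C), c(5, 4, 4, C)))
}

test_that("channel attention matches the loop oracle", {
  rc <- random_cbam(seed = 31)
  got <- channel_attention(rc$x, rc$weights)
  expect_equal(got, channel_map_oracle(rc$x, rc$weights$W0, rc$weights$W1),
               tolerance = 1e-12)
})

test_that("zero perceptron weights give uniform channel weights of 0.5", {
  rc <- random_cbam(seed = 32)
  w <- rc$weights
  w$W0[] <- 0; w$W1[] <- 0
  expect_equal(channel_attention(rc$x, w), rep(0.5, 4))
})

test_that("constant input makes average and max pooling coincide", {
  rc <- random_cbam(seed = 33)
  x <- array(1.7, c(5, 4, 4, 4))
  mlp <- function(v, w) as.vector(w$W1 %*% pmax(as.vector(w$W0 %*% v), 0))
  expected <- 1 / (1 + exp(-2 * mlp(rep(1.7, 4), rc$weights)))
  expect_equal(channel_attention(x, rc$weights), expected, tolerance = 1e-12)
})

test_that("channel attention is invariant to spatial permutations", {
  rc <- random_cbam(seed = 34)
  m1 <- channel_attention(rc$x, rc$weights)
  xp <- rc$x[sample(5), , , , drop = FALSE][, sample(4), , , drop = FALSE]
  expect_equal(channel_attention(xp, rc$weights), m1, tolerance = 1e-12)
})

test_that("spatial attention matches the loop oracle", {
  rc <- random_cbam(seed = 35)
  got <- spatial_attention(rc$x, rc$weights)
  expect_equal(got, spatial_map_oracle(rc$x, rc$weights$ws, rc$weights$wb),
               tolerance = 1e-12)
})

test_that("a zero spatial kernel gives a uniform 0.5 map of input shape", {
  rc <- random_cbam(seed = 36)
  w <- rc$weights
  w$ws[] <- 0; w$wb <- 0
  m <- spatial_attention(rc$x, w)
  expect_equal(dim(m), dim(rc$x)[1:3])
  expect_equal(m, array(0.5, dim(rc$x)[1:3]))
})

test_that("both attention maps lie strictly in (0, 1)", {
  for (seed in 37:39) {
    rc <- random_cbam(seed = seed)
    cm <- channel_attention(rc$x, rc$weights)
    sm <- spatial_attention(rc$x, rc$weights)
    expect_true(all(cm > 0 & cm < 1))
    expect_true(all(sm > 0 & sm < 1))
  }
})

test_that("cbam3d preserves shape and attenuates nonnegative inputs", {
  rc <- random_cbam(seed = 40)
  y <- cbam3d(rc$x, rc$weights)
  expect_equal(dim(y), dim(rc$x))

  xpos <- abs(rc$x)
  ypos <- cbam3d(xpos, rc$weights)
  expect_true(all(ypos <= xpos))
  expect_true(all(ypos >= 0))

  # sequential application: cbam(x) equals spatial(channel-refined) applied
  # to the channel-refined map
  s_c <- channel_attention(rc$x, rc$weights)
  n <- prod(dim(rc$x)[1:3])
  Fp <- array(matrix(rc$x, n, 4) * rep(s_c, each = n), dim(rc$x))
  s_s <- spatial_attention(Fp, rc$weights)
  expect_equal(y, array(matrix(Fp, n, 4) * as.vector(s_s), dim(rc$x)),
               tolerance = 1e-12)
})

test_that("saturated maps approach the multiplicative identity", {
  rc <- random_cbam(seed = 41)
  w <- rc$weights
  w$W0[] <- 0; w$W1[] <- 0; w$ws[] <- 0
  w$wb <- 50                                   # sigmoid ~ 1
  # spatial map ~1, channel map = 0.5 exactly: output = x / 2
  expect_equal(cbam3d(rc$x, w), rc$x / 2, tolerance = 1e-6)
})

test_that("cbam rejects channels not divisible by the reduction ratio", {
  expect_error(cbam_params(6, 4), "divisible")
  expect_error(cbam_params(8, 4, spatial_kernel = 4), "odd")
})

test_that("cbam backward matches finite differences", {
  rc <- random_cbam(seed = 42)
  gy <- array(stats::rnorm(length(rc$x)), dim(rc$x))
  fw <- rppgnet:::cbam_fw(rc$x, rc$weights)
  bw <- rppgnet:::cbam_bw(fw, rc$weights, gy)
  lossx <- function(x) sum(cbam3d(x, rc$weights) * gy)
  eps <- 1e-6
  for (k in sample(length(rc$x), 5)) {
    xp <- rc$x; xp[k] <- xp[k] + eps
    xm <- rc$x; xm[k] <- xm[k] - eps
    expect_equal(bw$gx[k], (lossx(xp) - lossx(xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (nm in c("W0", "W1", "ws")) {
    for (k in sample(length(rc$weights[[nm]]), 3)) {
      wp <- rc$weights; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- rc$weights; wm[[nm]][k] <- wm[[nm]][k] - eps
      num <- (sum(cbam3d(rc$x, wp) * gy) - sum(cbam3d(rc$x, wm) * gy)) /
        (2 * eps)
      expect_equal(bw$grads[[nm]][k], num, tolerance = 1e-4)
    }
  }
})
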