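# Shared fixtures, built in code.

# Landmarks with the ten ROI-driving points at hand-chosen positions and
# the rest on a neutral grid.
make_landmarks <- function(p3 = c(100, 200), p13 = c(220, 205),
                           eye_y = c(180, 182, 181, 183),
                           p50 = c(150, 260), p52 = c(170, 258),
                           p19 = c(120, 170), p24 = c(200, 168)) {
  pts <- cbind(rep(160, 68), rep(220, 68))
  pts[3 + 1, ] <- p3
  pts[13 + 1, ] <- p13
  pts[40 + 1, ] <- c(140, eye_y[1])
  pts[41 + 1, ] <- c(150, eye_y[2])
  pts[46 + 1, ] <- c(180, eye_y[3])
  pts[47 + 1, ] <- c(190, eye_y[4])
  pts[50 + 1, ] <- p50
  pts[52 + 1, ] <- p52
  pts[19 + 1, ] <- p19
  pts[24 + 1, ] <- p24
  landmark_set(pts, frame_index = 0L)
}

# A small random CDC instance: input, kernel, bias and spec.
random_cdc_instance <- function(theta, tdim = 6L, hdim = 5L, wdim = 5L,
                                cin = 2L, cout = 2L, kernel = c(3L, 3L, 3L),
                                stride = c(1L, 1L, 1L),
                                padding = c(1L, 1L, 1L)) {
  list(x = array(stats::rnorm(tdim * hdim * wdim * cin),
                 c(tdim, hdim, wdim, cin)),
       w = array(stats::rnorm(prod(kernel) * cin * cout),
                 c(kernel, cin, cout)),
       b = stats::rnorm(cout),
       spec = cdc_spec(cin, cout, kernel = kernel, theta = theta,
                       stride = stride, padding = padding))
}

# Sine pulse trace: f in Hz, rate in Hz, duration in seconds.
sine_trace <- function(f, rate = 30, duration = 10, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  pulse_trace(sin(2 * pi * f * t + phase), rate = rate)
}

# Tiny network configuration that exercises every layer type quickly.
tiny_net_config <- function(...) {
  args <- utils::modifyList(
    list(clip_len = 8L, in_size = c(12L, 12L), stem_channels = 4L,
         block_channels = c(4L, 4L), reduction_ratio = 2L,
         spatial_kernel = 3L, intensity_max = 1),
    list(...))
  do.call(rppg_net_config, args)
}
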