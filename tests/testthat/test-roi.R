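test_that("cheek box follows the ten-landmark geometry", {
  lms <- make_landmarks()
  box <- cheek_box(lms)
  expect_equal(box$x_left, 100)
  expect_equal(box$y_top, 183)
  expect_equal(box$width, 120)
  expect_equal(box$height, 75)
})

test_that("degenerate cheek geometry errors with the frame named", {
  # upper lip at the eyelid line: zero height
  lms <- make_landmarks(p50 = c(150, 183), p52 = c(170, 183))
  expect_error(cheek_box(lms), "degenerate cheek.*frame 0")
  # zero width
  lms <- make_landmarks(p13 = c(100, 205))
  expect_error(cheek_box(lms), "degenerate cheek")
})

test_that("forehead box extends upward by half the cheek height", {
  lms <- make_landmarks()
  fh <- forehead_box(lms, cheek_box(lms))     # Hcrec = 75
  expect_equal(fh$x_left, 120)
  expect_equal(fh$y_top, 168 - 37.5)
  expect_equal(fh$width, 80)
  expect_equal(fh$height, 37.5)

  # equal brow heights: the min is either one
  lms2 <- make_landmarks(p24 = c(200, 170))
  fh2 <- forehead_box(lms2, cheek_box(lms2))
  expect_equal(fh2$y_top, 170 - 37.5)

  expect_error(forehead_box(make_landmarks(p24 = c(120, 168)),
                            cheek_box(make_landmarks())),
               "degenerate forehead")
})

test_that("stitching places the cheek above the forehead at 96x96", {
  frame <- array(0, c(300, 320, 3))
  frame[, , 1] <- 1                            # red everywhere
  lms <- make_landmarks()
  cb <- cheek_box(lms)
  fb <- forehead_box(lms, cb)
  # paint the forehead region blue
  fr <- rppgnet:::box_indices(fb, dim(frame))
  frame[fr$rows, fr$cols, 1] <- 0
  frame[fr$rows, fr$cols, 3] <- 1
  out <- crop_resize_stitch(frame, cb, fb)
  expect_equal(dim(out), c(96L, 96L, 3L))
  expect_true(all(out[1:64, , 1] == 1))        # cheek rows stay red
  expect_true(all(out[1:64, , 3] == 0))
  expect_true(all(out[65:96, , 3] == 1))       # forehead rows are blue
  expect_true(all(out[65:96, , 1] == 0))
})

test_that("a constant frame stitches to a constant tile", {
  frame <- array(0.37, c(300, 320, 3))
  lms <- make_landmarks()
  cb <- cheek_box(lms)
  out <- crop_resize_stitch(frame, cb, forehead_box(lms, cb))
  expect_equal(out, array(0.37, c(96, 96, 3)), tolerance = 1e-12)
})

test_that("geometry is translation-equivariant", {
  lms <- make_landmarks()
  shift <- c(17, -9)
  pts2 <- sweep(lms$points, 2, shift, "+")
  lms2 <- landmark_set(pts2)
  cb <- cheek_box(lms); cb2 <- cheek_box(lms2)
  expect_equal(cb2$x_left, cb$x_left + shift[1])
  expect_equal(cb2$y_top, cb$y_top + shift[2])
  expect_equal(cb2$width, cb$width)
  expect_equal(cb2$height, cb$height)
  fb <- forehead_box(lms, cb); fb2 <- forehead_box(lms2, cb2)
  expect_equal(fb2$x_left, fb$x_left + shift[1])
  expect_equal(fb2$y_top, fb$y_top + shift[2])

  # shifting frame content with the landmarks leaves the stitched pixels
  # unchanged
  set.seed(11)
  frame <- array(runif(300 * 320 * 3), c(300, 320, 3))
  # shift is (dx = +17, dy = -9): frame2[y, x] = frame[y + 9, x - 17]
  frame2 <- array(0.5, c(300, 320, 3))
  frame2[1:(300 - 9), (1 + 17):320, ] <- frame[(1 + 9):300, 1:(320 - 17), ]
  out <- crop_resize_stitch(frame, cb, fb)
  out2 <- crop_resize_stitch(frame2, cb2, fb2)
  expect_equal(out2, out, tolerance = 1e-12)
})

test_that("forehead boxes above the image clip to row 0 with a warning", {
  lms <- make_landmarks(p19 = c(120, 20), p24 = c(200, 18))
  cb <- cheek_box(lms)
  fb <- forehead_box(lms, cb)                  # extends above y = 0
  frame <- array(0.5, c(300, 320, 3))
  expect_warning(out <- crop_resize_stitch(frame, cb, fb),
                 "clipped to row 0")
  expect_equal(dim(out), c(96L, 96L, 3L))
})

test_that("clip arithmetic matches the closed form", {
  mk <- function(n) array(0, c(n, 6, 6, 3))
  expect_length(build_clips(mk(160), 128, 8), 5)
  expect_equal(vapply(build_clips(mk(160), 128, 8), `[[`, numeric(1),
                      "start_frame"),
               c(0, 8, 16, 24, 32))
  expect_length(build_clips(mk(128), 128, 8), 1)
  expect_warning(out <- build_clips(mk(127), 128, 8), "shorter")
  expect_length(out, 0)
  # property sweep over N for several strides
  for (stride in c(4L, 8L, 16L)) for (n in seq(128L, 200L, by = 7L)) {
    got <- length(build_clips(mk(n), 128, stride))
    expect_identical(got, as.integer((n - 128L) %/% stride + 1L))
  }
})

test_that("landmark CSV round-trips exactly and rejects bad files", {
  lms <- lapply(0:2, function(i)
    landmark_set(matrix(stats::runif(136, 0, 300), 68, 2), frame_index = i))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lms, path)
  back <- parse_landmarks(path)
  expect_length(back, 3)
  for (i in 1:3) expect_equal(back[[i]]$points, lms[[i]]$points)

  # wrong column count: drop one x column
  df <- utils::read.csv(path, check.names = FALSE)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, -2], bad, row.names = FALSE)
  expect_error(parse_landmarks(bad), "x_0")
  expect_error(parse_landmarks("no/such/file.csv"), "not found")
})

test_that("stitched tiles keep shape for random valid geometry", {
  set.seed(21)
  frame <- array(runif(300 * 320 * 3), c(300, 320, 3))
  for (i in 1:5) {
    lms <- make_landmarks(p3 = c(80 + runif(1, 0, 20), 200),
                          p13 = c(200 + runif(1, 0, 40), 205),
                          p50 = c(150, 250 + runif(1, 0, 20)),
                          p52 = c(170, 255 + runif(1, 0, 10)))
    cb <- cheek_box(lms)
    out <- crop_resize_stitch(frame, cb, forehead_box(lms, cb))
    expect_equal(dim(out), c(96L, 96L, 3L))
  }
})
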