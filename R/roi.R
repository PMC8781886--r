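#' Facial landmark sets and region-of-interest geometry
#'
#' The pipeline consumes 68-point facial landmarks in the standard 0-based
#' convention (jaw 0-16, brows 17-26, nose 27-35, eyes 36-47, mouth 48-67),
#' with image coordinates origin top-left and y increasing downward. Ten
#' points drive the ROI geometry: the jaw points P3/P13 and the lower-eyelid
#' points P40/P41/P46/P47 plus the upper-lip points P50/P52 bound the cheek
#' rectangle, and the brow points P19/P24 anchor the forehead rectangle.
#'
#' @name roi-geometry
NULL

#' Construct a landmark set
#'
#' @param points 68 x 2 numeric matrix of (x, y) pixel coordinates.
#' @param frame_index integer frame index (0-based).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L)
    stop("a landmark set needs exactly 68 (x, y) points")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, frame_index = as.integer(frame_index)),
            class = "landmark_set")
}

# 0-based landmark lookup: pt(lms, 3) is P3.
pt <- function(lms, i) lms$points[i + 1L, ]

#' Rectangular region of interest
#'
#' @param x_left,y_top top-left corner in pixels (0-based image coordinates).
#' @param width,height extent in pixels; must be positive.
#' @return object of class `roi_box`.
#' @export
roi_box <- function(x_left, y_top, width, height) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0)
    stop("degenerate ROI: non-positive width or height")
  structure(list(x_left = x_left, y_top = y_top,
                 width = width, height = height),
            class = "roi_box")
}

#' Cheek bounding box from landmarks
#'
#' The cheek rectangle spans horizontally from jaw point P3 to jaw point
#' P13, vertically from the lowest lower-eyelid point (max of the y
#' coordinates of P40, P41, P46, P47) down to the highest upper-lip point
#' (min of the y coordinates of P50, P52).
#'
#' @param lms a [landmark_set()].
#' @return an [roi_box()].
#' @export
cheek_box <- function(lms) {
  x_left <- pt(lms, 3)["x"]
  y_top <- max(pt(lms, 40)["y"], pt(lms, 41)["y"],
               pt(lms, 46)["y"], pt(lms, 47)["y"])
  width <- pt(lms, 13)["x"] - x_left
  height <- min(pt(lms, 50)["y"], pt(lms, 52)["y"]) - y_top
  if (!is.finite(width) || width <= 0 || !is.finite(height) || height <= 0)
    stop("degenerate cheek ROI at frame ", lms$frame_index,
         " (width ", format(width), ", height ", format(height), ")")
  roi_box(unname(x_left), unname(y_top), unname(width), unname(height))
}

#' Forehead bounding box from landmarks
#'
#' The forehead rectangle spans horizontally from brow point P19 to brow
#' point P24 and extends upward from the higher of the two brow points by
#' half the cheek height.
#'
#' @param lms a [landmark_set()].
#' @param cheek the cheek [roi_box()] of the same frame (its height sets
#'   the forehead height).
#' @return an [roi_box()]. Boxes that extend above the image are clipped at
#'   crop time, not here.
#' @export
forehead_box <- function(lms, cheek) {
  x_left <- pt(lms, 19)["x"]
  width <- pt(lms, 24)["x"] - x_left
  height <- 0.5 * cheek$height
  y_top <- min(pt(lms, 19)["y"], pt(lms, 24)["y"]) - height
  if (!is.finite(width) || width <= 0)
    stop("degenerate forehead ROI at frame ", lms$frame_index,
         " (width ", format(width), ")")
  roi_box(unname(x_left), unname(y_top), unname(width), unname(height))
}

# Round-half-up keeps the geometry translation-equivariant (round() ties to
# even, which would round y and y + integer shift to different offsets).
round_half_up <- function(x) floor(x + 0.5)

# Round a box to integer pixel bounds and clip it to the frame; 0-based in,
# 1-based R indices out.
box_indices <- function(box, frame_dim, what = "ROI") {
  x0 <- round_half_up(box$x_left); y0 <- round_half_up(box$y_top)
  x1 <- round_half_up(box$x_left + box$width) - 1
  y1 <- round_half_up(box$y_top + box$height) - 1
  H <- frame_dim[1]; W <- frame_dim[2]
  if (x1 < 0 || y1 < 0 || x0 > W - 1 || y0 > H - 1)
    stop(what, " box lies fully outside the frame")
  if (y0 < 0) {
    warning(what, " box extends above the frame; clipped to row 0")
    y0 <- 0
  }
  x0 <- max(x0, 0); x1 <- min(x1, W - 1); y1 <- min(y1, H - 1)
  if (x1 < x0 || y1 < y0) stop(what, " box collapses after clipping")
  list(rows = (y0:y1) + 1L, cols = (x0:x1) + 1L)
}

resize_bilinear <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  as.matrix(EBImage::resize(m, w = h, h = w, filter = "bilinear"))
}

#' Crop, resize and stitch the cheek and forehead regions
#'
#' Crops both boxes from the frame (rounding fractional edges to the
#' nearest pixel), resizes the cheek to the upper two thirds and the
#' forehead to the lower third of the stitched tile (64x96 and 32x96 at the
#' default 96x96 output), and concatenates them vertically.
#'
#' @param frame `(H, W, 3)` numeric array.
#' @param cheek,forehead [roi_box()]es from [cheek_box()] /
#'   [forehead_box()].
#' @param out_size stitched output size `(H, W)`; H divisible by 3.
#' @return `(out_H, out_W, 3)` array, cheek on top.
#' @export
crop_resize_stitch <- function(frame, cheek, forehead, out_size = c(96L, 96L)) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] == 3L,
            out_size[1] %% 3L == 0L)
  ch <- box_indices(cheek, dim(frame), "cheek")
  fh <- box_indices(forehead, dim(frame), "forehead")
  hc <- 2L * out_size[1] %/% 3L
  hf <- out_size[1] - hc
  out <- array(0, c(out_size[1], out_size[2], 3L))
  for (c in 1:3) {
    out[seq_len(hc), , c] <-
      resize_bilinear(frame[ch$rows, ch$cols, c], hc, out_size[2])
    out[hc + seq_len(hf), , c] <-
      resize_bilinear(frame[fh$rows, fh$cols, c], hf, out_size[2])
  }
  out
}

#' Extract stitched ROI frames for a whole sequence
#'
#' @param frames `(T, H, W, 3)` array of video frames.
#' @param landmarks list of [landmark_set()]s, one per frame.
#' @param out_size stitched tile size `(H, W)`.
#' @return `(T, out_H, out_W, 3)` array of stitched ROI tiles.
#' @export
extract_roi_frames <- function(frames, landmarks, out_size = c(96L, 96L)) {
  d <- dim(frames)
  if (length(landmarks) != d[1])
    stop("need one landmark set per frame (", d[1], " frames, ",
         length(landmarks), " landmark sets)")
  out <- array(0, c(d[1], out_size, 3L))
  for (i in seq_len(d[1])) {
    lms <- landmarks[[i]]
    cb <- cheek_box(lms)
    fb <- forehead_box(lms, cb)
    out[i, , , ] <- crop_resize_stitch(frames[i, , , ], cb, fb, out_size)
  }
  out
}

#' Cut a stitched-frame sequence into fixed-length clips
#'
#' Clips start at frames `0, stride, 2*stride, ...`, giving
#' `floor((N - clip_len) / stride) + 1` clips for an N-frame sequence.
#'
#' @param stitched `(N, H, W, 3)` array of stitched ROI frames.
#' @param clip_len clip length in frames.
#' @param stride hop between clip starts in frames.
#' @param frame_rate frames per second, carried into the clip metadata.
#' @return list of `roi_clip` objects (`frames`, `start_frame`,
#'   `frame_rate`); empty with a warning when the sequence is shorter than
#'   one clip.
#' @export
build_clips <- function(stitched, clip_len = 128L, stride = 8L,
                        frame_rate = 30) {
  n <- dim(stitched)[1]
  clip_len <- as.integer(clip_len); stride <- as.integer(stride)
  if (n < clip_len) {
    warning("sequence of ", n, " frames shorter than one ", clip_len,
            "-frame clip")
    return(list())
  }
  starts <- seq(0L, n - clip_len, by = stride)
  lapply(starts, function(s) {
    structure(list(frames = stitched[s + seq_len(clip_len), , , ,
                                     drop = FALSE],
                   start_frame = s, frame_rate = frame_rate),
              class = "roi_clip")
  })
}

#' @export
print.roi_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("roi_clip: %d frames of %dx%d, start frame %d @ %g fps\n",
              d[1], d[2], d[3], x$start_frame, x$frame_rate))
  invisible(x)
}

landmark_header <- function() {
  c("frame", paste0("x_", 0:67), paste0("y_", 0:67))
}

#' Read per-frame landmarks from CSV
#'
#' Expects the OpenFace-compatible dialect: a header row
#' `frame,x_0..x_67,y_0..y_67` and one row per frame.
#'
#' @param path CSV file path.
#' @return list of [landmark_set()]s in row order.
#' @export
parse_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- landmark_header()
  if (!identical(names(df), expected))
    stop("landmark CSV must have columns frame,x_0..x_67,y_0..y_67 (",
         ncol(df), " columns found, ", length(expected), " expected)")
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.numeric(df[i, -1])
    if (anyNA(row) || !all(is.finite(row)))
      stop("malformed landmark row ", i, " in ", path)
    landmark_set(cbind(row[1:68], row[69:136]), frame_index = df$frame[i])
  })
}

#' Write landmarks in the CSV dialect read by [parse_landmarks()]
#'
#' @param landmarks list of [landmark_set()]s.
#' @param path output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- t(vapply(landmarks, function(l)
    c(l$frame_index, l$points[, "x"], l$points[, "y"]), numeric(137)))
  colnames(rows) <- landmark_header()
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
}
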