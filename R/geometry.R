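#' Scene geometry of the gaze-judgment setup
#'
#' Describes the physical arrangement used to photograph the gazer and
#' present judgments: a planar surface a fixed distance in front of the
#' gazer's eyes, imaged into a rectangular pixel frame.  Plane coordinates
#' are in cm with the origin at the gazer's straight-ahead point, x
#' rightward and y upward; pixel coordinates are 0-based with the origin at
#' the top-left of the frame, x rightward and y downward.
#'
#' @param gazer_to_plane Distance from the gazer's eyes to the gazed-upon
#'   plane, cm.
#' @param camera_to_plane Distance from the camera to the plane, cm
#'   (recorded for completeness; judgments are modelled on the plane).
#' @param eye_height Height of the eyes / plane origin / camera axis, cm.
#' @param frame_px Width and height of the presented frame, pixels.
#' @param plane_extent_cm Physical width and height of the frame on the
#'   plane, cm.  The aspect ratio must match `frame_px` within 1%.  The
#'   default (50 x 66.64 cm) preserves the 550:733 pixel aspect.
#' @return A `scene_geometry` object (a list with the validated fields).
#' @examples
#' geom <- scene_geometry()
#' geom$gazer_to_plane
#' @export
scene_geometry <- function(gazer_to_plane = 115,
                           camera_to_plane = 160,
                           eye_height = 125,
                           frame_px = c(550L, 733L),
                           plane_extent_cm = c(50, 50 * 733 / 550)) {
  stop_if_not(is.numeric(gazer_to_plane) && gazer_to_plane > 0,
              "gazer_to_plane must be a positive length (cm)")
  stop_if_not(is.numeric(camera_to_plane) && camera_to_plane > 0,
              "camera_to_plane must be a positive length (cm)")
  stop_if_not(is.numeric(eye_height) && eye_height > 0,
              "eye_height must be a positive length (cm)")
  frame_px <- as.integer(frame_px)
  stop_if_not(length(frame_px) == 2 && all(frame_px > 0),
              "frame_px must be two positive integers (width, height)")
  stop_if_not(length(plane_extent_cm) == 2 && all(plane_extent_cm > 0),
              "plane_extent_cm must be two positive lengths (width, height)")
  aspect_px <- frame_px[1] / frame_px[2]
  aspect_cm <- plane_extent_cm[1] / plane_extent_cm[2]
  stop_if_not(abs(aspect_cm / aspect_px - 1) <= 0.01,
              "plane_extent_cm aspect ratio must match frame_px within 1%")
  structure(list(gazer_to_plane = gazer_to_plane,
                 camera_to_plane = camera_to_plane,
                 eye_height = eye_height,
                 frame_px = frame_px,
                 plane_extent_cm = plane_extent_cm),
            class = "scene_geometry")
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat("Scene geometry\n")
  cat(sprintf("  gazer -> plane : %g cm\n", x$gazer_to_plane))
  cat(sprintf("  camera -> plane: %g cm\n", x$camera_to_plane))
  cat(sprintf("  eye height     : %g cm\n", x$eye_height))
  cat(sprintf("  frame          : %d x %d px = %.2f x %.2f cm\n",
              x$frame_px[1], x$frame_px[2],
              x$plane_extent_cm[1], x$plane_extent_cm[2]))
  invisible(x)
}

#' Lattice of gaze-target locations
#'
#' Builds the 33 fixation targets on the gazed-upon plane: the origin
#' (straight ahead, direction index 0) plus 32 lattice marks in seven rows.
#' Odd rows carry five marks at 10-cm spacing; even rows carry four marks
#' offset horizontally by half the spacing, giving nine interleaved column
#' positions.  The vertical pitch between rows is configurable.
#'
#' @param geometry A [scene_geometry()].
#' @param row_pitch_cm Vertical spacing between lattice rows, cm.
#' @param mark_spacing_cm Horizontal spacing between marks within a row, cm.
#' @return A `target_grid` data frame with columns `direction` (0-32),
#'   `x_cm`, `y_cm` and `row` (`NA` for the origin).
#' @examples
#' tg <- make_target_grid(scene_geometry())
#' nrow(tg)          # 33
#' table(tg$row)     # rows of 5,4,5,4,5,4,5 marks
#' @export
make_target_grid <- function(geometry, row_pitch_cm = 10, mark_spacing_cm = 10) {
  stop_if_not(inherits(geometry, "scene_geometry"), "geometry must be a scene_geometry")
  stop_if_not(row_pitch_cm > 0, "row_pitch_cm must be > 0")
  stop_if_not(mark_spacing_cm > 0, "mark_spacing_cm must be > 0")
  s <- mark_spacing_cm
  rows <- lapply(1:7, function(i) {
    y <- (4 - i) * row_pitch_cm               # +3..-3 pitches, top to bottom
    x <- if (i %% 2 == 1) seq(-2, 2) * s else seq(-1.5, 1.5) * s
    data.frame(row = i, x_cm = x, y_cm = y)
  })
  marks <- do.call(rbind, rows)
  out <- rbind(data.frame(row = NA_integer_, x_cm = 0, y_cm = 0), marks)
  out <- data.frame(direction = 0:32, out[, c("x_cm", "y_cm", "row")])
  half <- geometry$plane_extent_cm / 2
  stop_if_not(all(abs(out$x_cm) < half[1]) && all(abs(out$y_cm) < half[2]),
              "target lattice exceeds the plane extent; widen plane_extent_cm")
  class(out) <- c("target_grid", "data.frame")
  out
}

#' Discrete working grid over the stimulus frame
#'
#' All probability maps (likelihoods, priors, posteriors) are represented on
#' a uniform lattice of cells covering the frame, and clicks are binned to
#' cells with a half-open convention (left/top edges inclusive).  The
#' default divides each frame axis by 5, giving 110 x 147 cells.
#'
#' @param geometry A [scene_geometry()].
#' @param downsample Integer factor relating frame pixels to grid cells.
#' @return A `working_grid` object carrying cell counts (`nx`, `ny`), the
#'   frame size, the plane extent, cell sizes and cell-center coordinates.
#' @examples
#' wg <- working_grid(scene_geometry())
#' c(wg$nx, wg$ny)   # 110 147
#' @export
working_grid <- function(geometry, downsample = 5) {
  stop_if_not(inherits(geometry, "scene_geometry"), "geometry must be a scene_geometry")
  stop_if_not(downsample >= 1, "downsample must be >= 1")
  nx <- as.integer(ceiling(geometry$frame_px[1] / downsample))
  ny <- as.integer(ceiling(geometry$frame_px[2] / downsample))
  W <- geometry$plane_extent_cm[1]
  H <- geometry$plane_extent_cm[2]
  structure(list(
    nx = nx, ny = ny,
    frame_px = geometry$frame_px,
    extent_cm = geometry$plane_extent_cm,
    cell_cm = c(W / nx, H / ny),
    # cell centers in plane cm; rows run top (y = +H/2) to bottom
    xs_cm = -W / 2 + (seq_len(nx) - 0.5) * W / nx,
    ys_cm = H / 2 - (seq_len(ny) - 0.5) * H / ny
  ), class = "working_grid")
}

#' @export
print.working_grid <- function(x, ...) {
  cat(sprintf("Working grid: %d x %d cells (%.3f x %.3f cm each) over %d x %d px\n",
              x$nx, x$ny, x$cell_cm[1], x$cell_cm[2],
              x$frame_px[1], x$frame_px[2]))
  invisible(x)
}

#' Number of cells in a working grid
#' @param grid A [working_grid()].
#' @return Integer cell count `nx * ny`.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' Convert between plane (cm) and frame (pixel) coordinates
#'
#' Plane coordinates are centered on the straight-ahead point with y upward;
#' pixel coordinates are 0-based from the top-left with y downward.
#'
#' @param xy Two-column matrix (or length-2 vector) of coordinates.
#' @param grid A [working_grid()].
#' @return A two-column matrix of converted coordinates.
#' @export
cm_to_px <- function(xy, grid) {
  xy <- rbind(xy)
  W <- grid$extent_cm[1]; H <- grid$extent_cm[2]
  cbind((xy[, 1] + W / 2) * grid$frame_px[1] / W,
        (H / 2 - xy[, 2]) * grid$frame_px[2] / H)
}

#' @rdname cm_to_px
#' @export
px_to_cm <- function(xy, grid) {
  xy <- rbind(xy)
  W <- grid$extent_cm[1]; H <- grid$extent_cm[2]
  cbind(xy[, 1] * W / grid$frame_px[1] - W / 2,
        H / 2 - xy[, 2] * H / grid$frame_px[2])
}

#' Bin frame-pixel clicks to working-grid cells
#'
#' Cells are half-open: a click on a cell's left or top edge belongs to that
#' cell.  Clicks must lie inside the frame (`0 <= x < width`,
#' `0 <= y < height`).
#'
#' @param xy Two-column matrix (or length-2 vector) of pixel coordinates.
#' @param grid A [working_grid()].
#' @return A matrix with columns `row`, `col` and the column-major linear
#'   index `cell` into an `ny x nx` map matrix.
#' @export
px_to_cell <- function(xy, grid) {
  xy <- rbind(xy)
  ok <- xy[, 1] >= 0 & xy[, 1] < grid$frame_px[1] &
        xy[, 2] >= 0 & xy[, 2] < grid$frame_px[2]
  stop_if_not(all(ok), "click outside the frame")
  col <- pmin(floor(xy[, 1] * grid$nx / grid$frame_px[1]) + 1L, grid$nx)
  row <- pmin(floor(xy[, 2] * grid$ny / grid$frame_px[2]) + 1L, grid$ny)
  cbind(row = row, col = col, cell = (col - 1L) * grid$ny + row)
}
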