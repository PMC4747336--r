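#' Construct a salience map
#'
#' A salience map is a nonnegative 2-D field over the working grid modelling
#' how likely each location is to attract visual attention a priori.  Maps
#' track a normalization state: `"raw"` (arbitrary nonnegative units, as
#' produced by a salience algorithm), `"center_corrected"` (divided by the
#' cohort-average map) or `"normalized"` (entries sum to 1, usable as a
#' Bayesian prior).
#'
#' @param values Numeric matrix (`ny x nx`, rows = pixel rows top to
#'   bottom) of nonnegative salience values.
#' @param state One of `"raw"`, `"center_corrected"`, `"normalized"`.
#' @param image_id Optional token identifying the source image.
#' @return A `salience_map` object.
#' @export
salience_map <- function(values, state = c("raw", "center_corrected", "normalized"),
                         image_id = NULL) {
  state <- match.arg(state)
  stop_if_not(is.matrix(values) && is.numeric(values) && all(dim(values) > 0),
              "values must be a non-empty numeric matrix")
  stop_if_not(all(is.finite(values)), "salience values must be finite")
  stop_if_not(all(values >= 0), "salience values must be nonnegative")
  if (state == "normalized")
    stop_if_not(abs(sum(values) - 1) <= 1e-9, "normalized map must sum to 1")
  structure(list(values = values, state = state, image_id = image_id),
            class = "salience_map")
}

#' @export
print.salience_map <- function(x, ...) {
  cat(sprintf("Salience map%s: %d x %d cells, state = %s, sum = %.6g\n",
              if (is.null(x$image_id)) "" else paste0(" [", x$image_id, "]"),
              ncol(x$values), nrow(x$values), x$state, sum(x$values)))
  invisible(x)
}

.map_values <- function(map) {
  if (inherits(map, "salience_map") || inherits(map, "likelihood_map") ||
      inherits(map, "posterior_map")) map$values else map
}

#' Normalize a salience map to sum to 1
#'
#' Rescales a nonnegative map so that its entries sum to 1, the form in
#' which a map enters the Bayesian model as a prior.  Idempotent and
#' invariant to positive rescaling of the input.
#'
#' @param map A [salience_map()] (or bare matrix) with at least one
#'   positive entry and no negative entries.
#' @return A `salience_map` with state `"normalized"`.
#' @examples
#' m <- salience_map(matrix(c(1, 3), 1))
#' normalize_map(m)$values   # 0.25 0.75
#' @export
normalize_map <- function(map) {
  v <- .map_values(map)
  stop_if_not(all(v >= 0), "map has negative entries")
  total <- sum(v)
  stop_if_not(total > 0, "cannot normalize an all-zero map")
  salience_map(v / total, state = "normalized",
               image_id = if (inherits(map, "salience_map")) map$image_id)
}

#' Pixelwise average of a set of salience maps
#'
#' The cohort-average map captures the spatial regularities shared across
#' images -- dominated by the center bias of natural-image salience -- and
#' is the divisor used by [center_correct()].
#'
#' @param maps A list of at least two raw [salience_map()]s with identical
#'   shapes.
#' @return A `salience_map` (state `"raw"`, `image_id = "average"`).
#' @export
average_map <- function(maps) {
  stop_if_not(is.list(maps) && length(maps) >= 2, "need at least 2 maps to average")
  vals <- lapply(maps, .map_values)
  d <- dim(vals[[1]])
  stop_if_not(all(vapply(vals, function(v) identical(dim(v), d), logical(1))),
              "maps must share the same shape")
  salience_map(Reduce(`+`, vals) / length(vals), state = "raw", image_id = "average")
}

#' Remove center bias from a salience map
#'
#' Divides a map pixelwise by the cohort-average map, yielding a field in
#' which no location is systematically more salient than any other across
#' the image set: the pixelwise mean of a corrected cohort is the unit map.
#' Division is performed on raw maps; the result is normalized only when it
#' is later used as a prior.
#'
#' @param map A raw [salience_map()].
#' @param average The cohort [average_map()]; must be strictly positive
#'   everywhere unless `floor_zeros = TRUE`, in which case an epsilon floor
#'   (relative, 1e-12) is applied before division.
#' @param floor_zeros Apply the epsilon floor to zero cells of `average`.
#' @return A `salience_map` with state `"center_corrected"`.
#' @export
center_correct <- function(map, average, floor_zeros = FALSE) {
  v <- .map_values(map)
  a <- .map_values(average)
  stop_if_not(identical(dim(v), dim(a)), "map and average must share a shape")
  if (any(a <= 0)) {
    stop_if_not(isTRUE(floor_zeros),
                "average map has zero cells; rerun with floor_zeros = TRUE")
    a <- pmax(a, .EPS * max(a))
  }
  salience_map(v / a, state = "center_corrected",
               image_id = if (inherits(map, "salience_map")) map$image_id)
}

#' Salience value at a clicked location
#'
#' Looks up the value of the working-grid cell containing a click, using
#' the same half-open binning convention as [px_to_cell()].
#'
#' @param map A [salience_map()] (any state) on the working grid.
#' @param click Length-2 vector (or 1-row matrix) of frame-pixel
#'   coordinates; must lie inside the frame.
#' @param grid The [working_grid()].
#' @return The scalar cell value.
#' @export
salience_at <- function(map, click, grid) {
  v <- .map_values(map)
  stop_if_not(nrow(v) == grid$ny && ncol(v) == grid$nx,
              "map shape does not match the working grid")
  v[px_to_cell(click, grid)[1, "cell"]]
}

#' Low-level contrast salience of an image
#'
#' A simple bottom-up salience field: difference-of-Gaussians contrast
#' energy (absolute center-surround response summed over two spatial
#' scales).  This serves as the package's low-level-features-only salience
#' definition; externally computed maps from trained salience models can be
#' supplied as files instead.
#'
#' @param image Numeric matrix of image intensities (`ny x nx`).
#' @param scales Center Gaussian standard deviations in cells; each
#'   surround uses twice the center scale.
#' @param image_id Optional token for the resulting map.
#' @return A raw [salience_map()]; constant images yield an all-zero map
#'   (which [normalize_map()] will subsequently reject).
#' @export
contrast_salience <- function(image, scales = c(1, 2), image_id = NULL) {
  image <- .map_values(image)
  stop_if_not(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  out <- 0
  for (s in scales) {
    # replicate edges so the frame border itself is not detected as contrast
    center <- EBImage::gblur(image, sigma = s, boundary = "replicate")
    surround <- EBImage::gblur(image, sigma = 2 * s, boundary = "replicate")
    out <- out + abs(center - surround)
  }
  # gblur can leave tiny negative ringing on exact-constant inputs
  out[out < 1e-10 * max(abs(image))] <- 0
  salience_map(out, state = "raw", image_id = image_id)
}
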