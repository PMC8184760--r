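# Stimulus design and array geometry.
#
# Coordinate convention throughout: visual degrees, x positive rightward,
# y positive upward, fixation at the origin. The stimulated region is the
# lower-right quadrant (x > 0, y < 0).

SHAPES <- c("circle", "square", "diamond", "triangle", "inverse_triangle")
COLORS <- c("blue", "brown", "green", "red", "gray")
SIZE_CLASSES <- c(small = 1.0, medium = 1.2, large = 1.4)

#' Map shapes to angularity classes
#'
#' The five object shapes collapse onto three angularity classes: the circle
#' is circular, square and diamond are quadrangular (they differ only in
#' global orientation), triangle and inverse triangle are triangular.
#'
#' @param shape character vector of shape names.
#' @return character vector in `c("circular","quadrangular","triangular")`.
#' @export
shape_angularity <- function(shape) {
  out <- c(circle = "circular", square = "quadrangular", diamond = "quadrangular",
           triangle = "triangular", inverse_triangle = "triangular")[shape]
  if (any(is.na(out))) stop("unknown shape: ", paste(shape[is.na(out)], collapse = ", "))
  unname(out)
}

#' Stimulus locations in the lower-right visual quadrant
#'
#' Five fixed object locations at eccentricities of 3.5, 5.8 and 8.2 visual
#' degrees, placed so that typical distances between neighbouring locations
#' are around 3 degrees (comparable to typical epidural receptive-field
#' diameters).
#'
#' @return tibble with `location_id`, `x`, `y`, `eccentricity` (degrees).
#' @export
stimulus_locations <- function() {
  ecc <- c(3.5, 5.8, 5.8, 8.2, 8.2)
  ang <- c(-45, -20, -70, -40, -75) * pi / 180
  tibble(
    location_id = 1:5,
    x = ecc * cos(ang),
    y = ecc * sin(ang),
    eccentricity = ecc
  )
}

#' Full factorial stimulus condition table
#'
#' Enumerates the complete design: 5 locations x 3 sizes x 5 shapes x
#' 5 colors = 375 distinct conditions. Sizes are orbit diameters (the circle
#' into which every shape fits exactly): 1.0 (small), 1.2 (medium) and
#' 1.4 degrees (large).
#'
#' @param locations tibble as returned by [stimulus_locations()].
#' @return tibble with one row per condition (`condition_id`, location
#'   coordinates, `size_class`, `size_deg`, `shape`, `angularity`, `color`).
#' @export
stimulus_conditions <- function(locations = stimulus_locations()) {
  grid <- expand.grid(
    color = COLORS,
    shape = SHAPES,
    size_class = names(SIZE_CLASSES),
    location_id = locations$location_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("location_id", "size_class", "shape", "color")]
  out <- as_tibble(grid)
  out$condition_id <- seq_len(nrow(out))
  idx <- match(out$location_id, locations$location_id)
  out$loc_x <- locations$x[idx]
  out$loc_y <- locations$y[idx]
  out$size_deg <- unname(SIZE_CLASSES[out$size_class])
  out$angularity <- shape_angularity(out$shape)
  out[, c("condition_id", "location_id", "loc_x", "loc_y", "size_class",
          "size_deg", "shape", "angularity", "color")]
}

#' Hexagonal epidural array geometry
#'
#' Generates a hexagonally packed electrode lattice with the given
#' center-to-center pitch and keeps the `n_electrodes` sites closest to the
#' lattice centroid, emulating a compact surface array.
#'
#' @param n_electrodes number of electrodes (default 202).
#' @param pitch_mm center-to-center distance in mm (default 1.8).
#' @param diameter_um electrode contact diameter in micrometres (metadata).
#' @return object of class `efp_array`: tibble of `electrode_id`, `x_mm`,
#'   `y_mm` plus `pitch_mm` and `diameter_um` attributes.
#' @export
array_geometry <- function(n_electrodes = 202, pitch_mm = 1.8, diameter_um = 560) {
  assert_positive(n_electrodes, "n_electrodes")
  assert_positive(pitch_mm, "pitch_mm")
  side <- ceiling(sqrt(n_electrodes)) + 2
  rows <- -side:side
  cols <- -side:side
  pos <- expand.grid(col = cols, row = rows)
  x <- (pos$col + 0.5 * (pos$row %% 2)) * pitch_mm
  y <- pos$row * pitch_mm * sqrt(3) / 2
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  keep <- order(d)[seq_len(n_electrodes)]
  out <- tibble(electrode_id = seq_len(n_electrodes), x_mm = x[keep], y_mm = y[keep])
  structure(out, pitch_mm = pitch_mm, diameter_um = diameter_um,
            class = c("efp_array", class(out)))
}
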