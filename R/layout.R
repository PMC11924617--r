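#' Sensor layout for one foot
#'
#' A `sensor_layout` holds the planar coordinates of the pressure sensors of
#' one insole, in millimetres. `x` is medial-lateral, `y` is
#' posterior-to-anterior (larger `y` = closer to the toes). These coordinates
#' are the spatial frame for every center-of-pressure computation.
#'
#' @param coords numeric matrix or two-column data.frame, one row per sensor,
#'   columns `(x, y)` in mm.
#' @param side `"left"` or `"right"`.
#' @return An object of class `sensor_layout` with fields `side`, `n`,
#'   `coords` (an `n x 2` matrix with columns `x`, `y`).
#' @examples
#' sensor_layout(cbind(c(-10, 10), c(0, 200)), side = "left")
#' @export
sensor_layout <- function(coords, side = c("left", "right")) {
  side <- match.arg(side)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("layout coordinates must have two columns (x, y)")
  if (nrow(coords) < 1L)
    stop("layout needs at least one sensor")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("layout coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(side = side, n = nrow(coords), coords = coords),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %s foot, %d sensors, y span %.0f..%.0f mm\n",
              x$side, x$n, min(x$coords[, "y"]), max(x$coords[, "y"])))
  invisible(x)
}

#' Bilateral layout pair
#'
#' Bundles a left and a right [sensor_layout()] and checks that both feet
#' carry the same number of sensors, as required within one recording.
#'
#' @param left,right `sensor_layout` objects (or coordinate matrices).
#' @return A list of class `layout_pair` with elements `left`, `right`.
#' @export
layout_pair <- function(left, right) {
  if (!inherits(left, "sensor_layout")) left <- sensor_layout(left, "left")
  if (!inherits(right, "sensor_layout")) right <- sensor_layout(right, "right")
  if (left$n != right$n)
    stop("left and right layouts must have the same sensor count")
  structure(list(left = left, right = right), class = "layout_pair")
}

#' Read / write a layout pair as JSON
#'
#' The on-disk format is `{"left": [[x, y], ...], "right": [[x, y], ...]}`
#' with coordinates in mm.
#'
#' @param path file path.
#' @return `read_layout()` returns a `layout_pair`; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!all(c("left", "right") %in% names(obj)))
    stop("layout JSON must have 'left' and 'right' entries")
  layout_pair(sensor_layout(obj$left, "left"), sensor_layout(obj$right, "right"))
}

#' @rdname read_layout
#' @param layout a `layout_pair`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "layout_pair"))
  obj <- list(left = unname(layout$left$coords),
              right = unname(layout$right$coords))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Default stylized insole layout
#'
#' A 16-sensor layout on a 4 x 4 grid (4 medial-lateral columns x 4 rows from
#' heel to toe), mirroring a generic instrumented insole. Coordinates are in
#' mm; the left foot mirrors the right in `x`. This is the simulator's default
#' frame; real devices must supply their own layout.
#'
#' @param n_col,n_row grid dimensions (columns across the foot, rows heel to
#'   toe).
#' @param width,length insole footprint in mm.
#' @return A `layout_pair`.
#' @examples
#' default_insole_layout()
#' @export
default_insole_layout <- function(n_col = 4, n_row = 4,
                                  width = 60, length = 240) {
  xs <- seq(-width / 2, width / 2, length.out = n_col + 2)[-c(1, n_col + 2)]
  ys <- seq(0, length, length.out = n_row + 2)[-c(1, n_row + 2)]
  grid <- as.matrix(expand.grid(x = xs, y = ys))  # row-major: heel row first
  layout_pair(sensor_layout(cbind(-grid[, 1], grid[, 2]), "left"),
              sensor_layout(grid, "right"))
}
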