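#' Generate a rectilinear street network
#'
#' Builds a rows-by-cols grid of street intersections with uniform spacing,
#' the planar idealization of a midwestern US county road network. The
#' network supports intersection counting within a circular buffer, the
#' operation used to measure street intersection density.
#'
#' @param rows,cols Number of grid rows / columns (each >= 2).
#' @param spacing Distance between adjacent intersections, in miles.
#'
#' @return An object of class `street_network`: a list with tibbles
#'   `intersections` (columns `x`, `y`) and `segments`
#'   (columns `x0`, `y0`, `x1`, `y1`, `length`), coordinates in miles.
#' @export
#' @examples
#' net <- generate_street_network(3, 3, 1)
#' nrow(net$intersections)  # 9
generate_street_network <- function(rows, cols, spacing = 1) {
  if (!is.numeric(spacing) || spacing <= 0)
    abort("spacing must be a positive number of miles")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2 || cols < 2) abort("rows and cols must both be >= 2")

  nodes <- expand.grid(ix = seq_len(cols) - 1L, iy = seq_len(rows) - 1L)
  intersections <- tibble(x = nodes$ix * spacing, y = nodes$iy * spacing)

  horiz <- expand.grid(ix = seq_len(cols - 1L) - 1L, iy = seq_len(rows) - 1L)
  vert <- expand.grid(ix = seq_len(cols) - 1L, iy = seq_len(rows - 1L) - 1L)
  segments <- bind_rows(
    tibble(x0 = horiz$ix * spacing, y0 = horiz$iy * spacing,
           x1 = (horiz$ix + 1L) * spacing, y1 = horiz$iy * spacing),
    tibble(x0 = vert$ix * spacing, y0 = vert$iy * spacing,
           x1 = vert$ix * spacing, y1 = (vert$iy + 1L) * spacing)
  )
  segments$length <- sqrt((segments$x1 - segments$x0)^2 +
                            (segments$y1 - segments$y0)^2)

  structure(list(intersections = intersections, segments = segments,
                 rows = rows, cols = cols, spacing = spacing),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("<street_network> %d x %d grid, spacing %g mi: %d intersections, %d segments\n",
              x$rows, x$cols, x$spacing,
              nrow(x$intersections), nrow(x$segments)))
  invisible(x)
}

#' Count street intersections within a circular buffer
#'
#' Counts network intersections at Euclidean distance at most `radius`
#' from `point` (closed buffer: boundary intersections are included).
#'
#' @param point Numeric length-2 vector `c(x, y)`, miles.
#' @param network A [generate_street_network()] object.
#' @param radius Buffer radius in miles (> 0); the conventional choice is
#'   one mile.
#'
#' @return Integer count of intersections in the buffer.
#' @export
count_intersections <- function(point, network, radius = 1) {
  stopifnot(inherits(network, "street_network"), length(point) == 2)
  if (radius <= 0) abort("radius must be positive")
  ints <- network$intersections
  if (nrow(ints) == 0) {
    warn("network has no intersections; returning 0")
    return(0L)
  }
  d2 <- (ints$x - point[1])^2 + (ints$y - point[2])^2
  sum(d2 <= radius^2 + 1e-12)
}

#' Convert a buffer count to an intersection density
#'
#' Divides the number of intersections in a circular buffer by the buffer
#' area, giving intersections per square mile.
#'
#' @param count Number of intersections in the buffer.
#' @param radius Buffer radius in miles (> 0).
#'
#' @return Density in intersections per square mile.
#' @export
#' @examples
#' density_from_count(5, 1)  # 5 / pi
density_from_count <- function(count, radius = 1) {
  if (any(radius <= 0)) abort("radius must be positive")
  count / (pi * radius^2)
}
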