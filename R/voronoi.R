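#' Coordinates of emerged plants
#'
#' Maps the 1-cells of an emergence grid to field coordinates: the plant
#' of grid cell (i, j) sits at the cell center, `x = (j - 1/2) *
#' plant_spacing`, `y = (i - 1/2) * row_spacing` (1-based indices). Plants
#' are listed in row-major order, the order used by
#' [voronoi_cell_areas()].
#'
#' @param grid an [emergence_grid()] with at least one emerged plant.
#' @return An object of class `"plant_map"`: list with a data frame
#'   `coords` (`x`, `y` in m, plus grid indices `row`, `col`) and the
#'   field dimensions `width`, `height` in m.
#' @export
plant_coordinates <- function(grid) {
  stopifnot(inherits(grid, "emergence_grid"))
  ct <- emergence_counts(grid)
  if (ct$n_emerged == 0L) stop("empty field: no emerged plants")
  lay <- grid$layout
  # row-major scan
  idx <- which(t(grid$cells) == 1L)
  col <- (idx - 1L) %% lay$n_cols + 1L
  row <- (idx - 1L) %/% lay$n_cols + 1L
  d <- layout_dims(lay)
  structure(list(coords = data.frame(x = (col - 0.5) * lay$plant_spacing,
                                     y = (row - 0.5) * lay$row_spacing,
                                     row = row, col = col),
                 width = d[["width"]], height = d[["height"]]),
            class = "plant_map")
}

#' @export
print.plant_map <- function(x, ...) {
  cat(sprintf("Plant map: %d plants on a %.4g m x %.4g m field\n",
              nrow(x$coords), x$width, x$height))
  invisible(x)
}

#' Nutrition areas from a field-clipped Voronoi tessellation
#'
#' Each emerged plant receives its Voronoi cell — the set of field points
#' closer to it than to any other emerged plant — intersected with the
#' field rectangle. The areas partition the field exactly: they are
#' positive and sum to `width * height`. On a full regular grid every
#' cell is the `row_spacing x plant_spacing` rectangle; when a neighbor
#' is missing, the surrounding plants absorb its ground, which is the
#' geometric channel of yield compensation.
#'
#' @param grid an [emergence_grid()] with at least one emerged plant.
#' @return Numeric vector of areas (m^2), aligned with the row-major
#'   plant order of [plant_coordinates()].
#' @examples
#' g <- simulate_emergence(field_layout(5, 5, 0.6, 0.3), 0.8, seed = 1)
#' a <- voronoi_cell_areas(g)
#' sum(a) - prod(layout_dims(g$layout))  # ~0: exact partition
#' @export
voronoi_cell_areas <- function(grid) {
  stopifnot(inherits(grid, "emergence_grid"))
  if (sum(grid$cells) == 0L) stop("empty field: no emerged plants")
  voronoi_areas_cpp(grid$cells, grid$layout$row_spacing,
                    grid$layout$plant_spacing)
}

#' Voronoi cell polygons (for rendering and small-field checks)
#'
#' Reference implementation of the clipped tessellation that also returns
#' the cell polygons: each plant's cell is the field rectangle clipped by
#' the perpendicular bisector with *every* other plant. Quadratic in the
#' number of plants — intended for plots and small fields; use
#' [voronoi_cell_areas()] for areas at scale.
#'
#' @param grid an [emergence_grid()] with at least one emerged plant.
#' @return A list of polygons (each a list with `x`, `y` vertex vectors),
#'   aligned with [plant_coordinates()] order.
#' @export
voronoi_polygons <- function(grid) {
  pm <- plant_coordinates(grid)
  px <- pm$coords$x
  py <- pm$coords$y
  n <- length(px)
  lapply(seq_len(n), function(i) {
    poly <- list(x = c(0, pm$width, pm$width, 0),
                 y = c(0, 0, pm$height, pm$height))
    for (s in seq_len(n)) {
      if (s == i) next
      poly <- .clip_halfplane_r(poly, 2 * (px[s] - px[i]),
                                2 * (py[s] - py[i]),
                                px[s]^2 - px[i]^2 + py[s]^2 - py[i]^2)
    }
    poly
  })
}

.clip_halfplane_r <- function(poly, a, b, c) {
  n <- length(poly$x)
  if (n == 0L) return(poly)
  f <- a * poly$x + b * poly$y - c
  nx <- ny <- numeric(0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (f[k] <= 0) {
      nx <- c(nx, poly$x[k]); ny <- c(ny, poly$y[k])
    }
    if ((f[k] < 0 && f[k2] > 0) || (f[k] > 0 && f[k2] < 0)) {
      t <- f[k] / (f[k] - f[k2])
      nx <- c(nx, poly$x[k] + t * (poly$x[k2] - poly$x[k]))
      ny <- c(ny, poly$y[k] + t * (poly$y[k2] - poly$y[k]))
    }
  }
  list(x = nx, y = ny)
}

#' Plot the clipped tessellation of a grid
#'
#' Draws cell polygons, emerged plants (black) and missing positions
#' (red crosses). Quadratic in plant count — meant for small fields.
#'
#' @param grid an [emergence_grid()].
#' @param ... passed to [graphics::plot()].
#' @return The grid, invisibly.
#' @export
plot_tessellation <- function(grid, ...) {
  pm <- plant_coordinates(grid)
  polys <- voronoi_polygons(grid)
  graphics::plot(NA, xlim = c(0, pm$width), ylim = c(pm$height, 0),
                 xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  for (p in polys) graphics::polygon(p$x, p$y, border = "grey40")
  graphics::points(pm$coords$x, pm$coords$y, pch = 16, cex = 0.6)
  lay <- grid$layout
  miss <- which(t(grid$cells) == 0L)
  if (length(miss)) {
    mc <- (miss - 1L) %% lay$n_cols + 1L
    mr <- (miss - 1L) %/% lay$n_cols + 1L
    graphics::points((mc - 0.5) * lay$plant_spacing,
                     (mr - 0.5) * lay$row_spacing,
                     pch = 4, col = "red", cex = 0.6)
  }
  invisible(grid)
}

#' Compensated field yield of an emergence grid
#'
#' When every position emerged, per-plant yield is set by the planting
#' density itself and the field produces `yield_at_density(model, D)`
#' with `D = 1 / (row_spacing * plant_spacing)` plants/m^2. With missing
#' seedlings, each survivor is scored by its personal nutrition area
#' ([voronoi_cell_areas()]) through [per_plant_yield()], and the summed
#' plant masses are normalized by the field area — so plants bordering a
#' gap partially compensate the lost stand.
#'
#' @param model a [yield_model()].
#' @param grid an [emergence_grid()].
#' @return Field yield in t/hm^2 (0, with a warning, for an empty field).
#' @examples
#' lay <- field_layout(10, 20, 0.5, 1 / (0.5 * 6))  # density 6 plants/m^2
#' m <- yield_model(Dm = 6, Ym = 7.5, A = -0.5)
#' g <- simulate_emergence(lay, 1)    # full stand at the optimum
#' compensated_field_yield(m, g)      # exactly Ym
#' @export
compensated_field_yield <- function(model, grid) {
  stopifnot(inherits(model, "yield_model"), inherits(grid, "emergence_grid"))
  ct <- emergence_counts(grid)
  if (ct$n_emerged == 0L) {
    warning("empty field: no emerged plants, yield is 0")
    return(0)
  }
  lay <- grid$layout
  field_m2 <- prod(layout_dims(lay))
  if (ct$n_missing == 0L) {
    d <- 1 / (lay$row_spacing * lay$plant_spacing)  # plants/m^2
    return(yield_at_density(model, d))
  }
  areas <- voronoi_cell_areas(grid)
  .yield_from_areas(model, areas, field_m2)
}

# total compensated yield (t/hm^2) from per-plant areas on field_m2 m^2
.yield_from_areas <- function(model, areas, field_m2) {
  sum(per_plant_yield(model, areas)) / (field_m2 / 1e4)
}
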