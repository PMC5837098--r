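#' Rectangular planting layout
#'
#' A field is a rectangular lattice of planting positions: `n_rows` rows
#' separated by `row_spacing` m, each with `n_cols` positions separated by
#' `plant_spacing` m. Plants sit at cell centers, so the planted rectangle
#' is exactly `n_cols * plant_spacing` m wide and `n_rows * row_spacing` m
#' tall, and the planting density is `1e4 / (row_spacing * plant_spacing)`
#' plants/hm^2.
#'
#' @param n_rows,n_cols numbers of planting rows and of positions per row.
#' @param row_spacing,plant_spacing distances between rows and between
#'   plants within a row, m.
#' @return An object of class `"field_layout"`.
#' @examples
#' field_layout(60, 120, row_spacing = 0.6, plant_spacing = 0.3)
#' @seealso [layout_from_density()], [simulate_emergence()]
#' @export
field_layout <- function(n_rows, n_cols, row_spacing, plant_spacing) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            length(row_spacing) == 1L, length(plant_spacing) == 1L)
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) ||
      n_cols != round(n_cols))
    stop("`n_rows` and `n_cols` must be positive integers")
  if (!is.finite(row_spacing) || row_spacing <= 0 ||
      !is.finite(plant_spacing) || plant_spacing <= 0)
    stop("spacings must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 row_spacing = row_spacing, plant_spacing = plant_spacing),
            class = "field_layout")
}

#' @rdname field_layout
#' @param layout a `field_layout`.
#' @return `layout_density()`: planting density in plants/hm^2;
#'   `layout_dims()`: named vector `c(width, height)` in m.
#' @export
layout_density <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  1e4 / (layout$row_spacing * layout$plant_spacing)
}

#' @rdname field_layout
#' @export
layout_dims <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  c(width = layout$n_cols * layout$plant_spacing,
    height = layout$n_rows * layout$row_spacing)
}

#' Build a layout from a target planting density
#'
#' Row spacing is fixed (agronomic practice keeps it machine-compatible)
#' and the density is adjusted through the plant spacing:
#' `plant_spacing = 1e4 / (row_spacing * target_density)`. Row and column
#' counts are the largest that fit the requested field rectangle, so the
#' realized density matches the target up to this granularity.
#'
#' @param target_density desired planting density, plants/hm^2.
#' @param row_spacing distance between rows, m (default 0.6).
#' @param field_width,field_height field dimensions, m (default 100 x 100,
#'   one hectare).
#' @return A [field_layout()].
#' @examples
#' layout_from_density(45000, 0.6, 100, 100)  # 166 rows x 270 cols
#' @export
layout_from_density <- function(target_density, row_spacing = 0.6,
                                field_width = 100, field_height = 100) {
  if (!is.finite(target_density) || target_density <= 0)
    stop("`target_density` must be positive")
  if (field_width <= 0 || field_height <= 0)
    stop("field dimensions must be positive")
  plant_spacing <- 1e4 / (row_spacing * target_density)
  n_rows <- floor(field_height / row_spacing)
  n_cols <- floor(field_width / plant_spacing)
  if (n_rows < 1 || n_cols < 1)
    stop("degenerate layout: spacing exceeds the field size")
  field_layout(n_rows, n_cols, row_spacing, plant_spacing)
}

#' @export
print.field_layout <- function(x, ...) {
  d <- layout_dims(x)
  cat(sprintf("Planting layout: %d rows x %d cols (%g m x %g m spacing)\n",
              x$n_rows, x$n_cols, x$row_spacing, x$plant_spacing))
  cat(sprintf("  field %.4g m x %.4g m, density %.6g plants/hm^2\n",
              d[["width"]], d[["height"]], layout_density(x)))
  invisible(x)
}

#' Simulate a seedling-emergence grid
#'
#' Each planting position independently produces an emerged seedling with
#' probability `rate` (coded 1) or stays empty (coded 0) — an i.i.d.
#' Bernoulli field, the stochastic model behind single-seed sowing where
#' no hole receives a replacement seed. With a `seed` the draw is
#' bit-reproducible.
#'
#' @param layout a [field_layout()].
#' @param rate field seedling-emergence rate, in \[0, 1\].
#' @param seed optional integer RNG seed.
#' @return An object of class `"emergence_grid"`: list with the `layout`,
#'   the 0/1 integer matrix `cells` (`n_rows` x `n_cols`), `rate` and
#'   `seed`.
#' @examples
#' g <- simulate_emergence(field_layout(6, 12, 0.6, 0.3), 0.85, seed = 1)
#' emergence_counts(g)
#' @export
simulate_emergence <- function(layout, rate, seed = NULL) {
  stopifnot(inherits(layout, "field_layout"), is.numeric(rate),
            length(rate) == 1L)
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("`rate` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cells <- matrix(rbinom(layout$n_rows * layout$n_cols, 1L, rate),
                  nrow = layout$n_rows, ncol = layout$n_cols)
  structure(list(layout = layout, cells = cells, rate = rate, seed = seed),
            class = "emergence_grid")
}

#' Wrap an existing 0/1 matrix as an emergence grid
#'
#' @param cells 0/1 matrix (1 = emerged).
#' @param layout a [field_layout()] with matching dimensions; defaults to
#'   unit-square spacing.
#' @param rate nominal emergence rate to record (defaults to the realized
#'   fraction).
#' @return An `"emergence_grid"`.
#' @export
emergence_grid <- function(cells, layout = NULL, rate = NULL) {
  cells <- as.matrix(cells)
  if (!all(cells %in% c(0L, 1L))) stop("`cells` must be a 0/1 matrix")
  storage.mode(cells) <- "integer"
  if (is.null(layout)) layout <- field_layout(nrow(cells), ncol(cells), 1, 1)
  stopifnot(inherits(layout, "field_layout"))
  if (nrow(cells) != layout$n_rows || ncol(cells) != layout$n_cols)
    stop("matrix shape does not match the layout")
  if (is.null(rate)) rate <- mean(cells)
  structure(list(layout = layout, cells = cells, rate = rate, seed = NULL),
            class = "emergence_grid")
}

#' Emergence counts of a grid
#'
#' @param grid an `"emergence_grid"`.
#' @return List with `n_emerged`, `n_missing` and the `realized_rate`
#'   (fraction emerged).
#' @export
emergence_counts <- function(grid) {
  stopifnot(inherits(grid, "emergence_grid"))
  n <- length(grid$cells)
  n1 <- sum(grid$cells)
  list(n_emerged = n1, n_missing = n - n1, realized_rate = n1 / n)
}

#' @export
print.emergence_grid <- function(x, ...) {
  ct <- emergence_counts(x)
  cat(sprintf(
    "Emergence grid %d x %d: rate %.4g, %d emerged / %d missing (%.2f%%)\n",
    x$layout$n_rows, x$layout$n_cols, x$rate, ct$n_emerged, ct$n_missing,
    100 * ct$realized_rate))
  invisible(x)
}

#' @export
plot.emergence_grid <- function(x, ...) {
  # emerged = black dot, missing = white, rows top-down
  m <- t(x$cells[rev(seq_len(nrow(x$cells))), , drop = FALSE])
  graphics::image(z = m, col = c("white", "black"), axes = FALSE,
                  asp = nrow(x$cells) / ncol(x$cells) *
                    x$layout$row_spacing / x$layout$plant_spacing, ...)
  graphics::box()
  invisible(x)
}

#' Export an emergence grid as a lossless binary image
#'
#' One pixel per planting position: black for an emerged seedling, white
#' for a missing one. The format follows the file extension: `.png`
#' (grayscale, via the png package) or `.pgm` (plain-text P2), both
#' lossless so the matrix round-trips exactly.
#'
#' @param grid an `"emergence_grid"`.
#' @param path output file ending in `.png` or `.pgm`.
#' @return The path, invisibly.
#' @export
export_grid_image <- function(grid, path) {
  stopifnot(inherits(grid, "emergence_grid"), is.character(path),
            length(path) == 1L)
  ext <- tolower(tools::file_ext(path))
  gray <- 1 - grid$cells  # emerged -> 0 (black), missing -> 1 (white)
  ok <- tryCatch({
    if (ext == "png") {
      png::writePNG(gray, target = path)
    } else if (ext == "pgm") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("P2", paste(ncol(gray), nrow(gray)), "1"), con)
      write.table(gray, con, row.names = FALSE, col.names = FALSE)
    } else stop("unsupported image extension: ", ext)
    TRUE
  }, error = function(e) {
    stop("failed to write grid image to '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

# Deterministic per-replicate seed stream derived from (base_seed, r),
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(base_seed, r) {
  h <- (as.double(base_seed) %% 2147483647) * 48271 + as.double(r) * 16807
  as.integer(h %% 2147483629 + 1)
}
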