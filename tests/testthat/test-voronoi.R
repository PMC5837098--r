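test_that("plant coordinates sit at cell centers in row-major order", {
  g <- emergence_grid(matrix(1L, 1, 1), field_layout(1, 1, 0.6, 0.3))
  pm <- plant_coordinates(g)
  expect_equal(pm$coords$x, 0.15)
  expect_equal(pm$coords$y, 0.30)

  full <- emergence_grid(matrix(1L, 2, 2), field_layout(2, 2, 0.6, 0.3))
  pf <- plant_coordinates(full)
  expect_equal(pf$coords$x, c(0.15, 0.45, 0.15, 0.45))
  expect_equal(pf$coords$y, c(0.3, 0.3, 0.9, 0.9))

  set.seed(71)
  for (k in 1:100) {
    cells <- random_cells(sample(2:8, 1), sample(2:8, 1), runif(1, 0.3, 1),
                          min_ones = 1L)
    g <- emergence_grid(cells, field_layout(nrow(cells), ncol(cells),
                                            0.6, 0.3))
    expect_identical(nrow(plant_coordinates(g)$coords),
                     emergence_counts(g)$n_emerged)
  }
  expect_error(plant_coordinates(emergence_grid(matrix(0L, 2, 2))), "empty")
})

test_that("a lone plant owns the whole field", {
  cells <- matrix(0L, 4, 6)
  cells[2, 3] <- 1L
  g <- emergence_grid(cells, field_layout(4, 6, 0.6, 0.3))
  expect_equal(voronoi_cell_areas(g), 4 * 0.6 * 6 * 0.3, tolerance = 1e-12)
})

test_that("a full regular grid partitions into exact spacing rectangles", {
  lay <- field_layout(7, 11, 0.6, 0.3)
  g <- simulate_emergence(lay, 1)
  a <- voronoi_cell_areas(g)
  expect_equal(a, rep(0.6 * 0.3, 77), tolerance = 1e-12)
})

test_that("ring-searched areas equal the all-pairs polygon construction", {
  set.seed(72)
  for (k in 1:50) {
    nr <- sample(2:7, 1)
    nc <- sample(2:7, 1)
    cells <- random_cells(nr, nc, runif(1, 0.3, 0.95), min_ones = 1L)
    g <- emergence_grid(cells, field_layout(nr, nc, 0.6, 0.3))
    fast <- voronoi_cell_areas(g)
    slow <- vapply(voronoi_polygons(g), poly_area_shoelace, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("areas conserve the field and match a rasterized oracle", {
  set.seed(73)
  for (k in 1:100) {
    nr <- sample(1:15, 1)
    nc <- sample(1:15, 1)
    cells <- random_cells(nr, nc, runif(1, 0.1, 1), min_ones = 1L)
    g <- emergence_grid(cells, field_layout(nr, nc, 0.6, 0.3))
    a <- voronoi_cell_areas(g)
    expect_true(all(a > 0))
    expect_lt(abs(sum(a) - nr * 0.6 * nc * 0.3) / (nr * 0.6 * nc * 0.3),
              1e-6)
  }

  # rasterized nearest-neighbor oracle on one awkward layout
  cells <- matrix(1L, 5, 5)
  cells[c(3, 13, 22)] <- 0L
  g <- emergence_grid(cells, field_layout(5, 5, 0.6, 0.3))
  a <- voronoi_cell_areas(g)
  ora <- nn_area_oracle(cells, 0.6, 0.3, k = 40)
  expect_equal(a, ora, tolerance = 0.02)
})

test_that("a removed interior plant is redistributed to its neighbors", {
  lay <- field_layout(5, 5, 0.6, 0.3)
  full <- emergence_grid(matrix(1L, 5, 5), lay)
  holed_cells <- matrix(1L, 5, 5)
  holed_cells[3, 3] <- 0L
  holed <- emergence_grid(holed_cells, lay)

  a_full <- voronoi_cell_areas(full)
  a_holed <- voronoi_cell_areas(holed)
  expect_equal(sum(a_holed), sum(a_full), tolerance = 1e-9)

  pm <- plant_coordinates(holed)
  gain <- a_holed - 0.6 * 0.3
  # under the rectangular metric the 4-neighbors of (3,3) absorb its ground
  touching <- with(pm$coords, (row == 3 & abs(col - 3) == 1) |
                     (col == 3 & abs(row - 3) == 1))
  expect_true(all(gain[touching] > 1e-6))
  expect_equal(sum(gain), 0.6 * 0.3, tolerance = 1e-9)
  # no plant loses area when a competitor disappears
  expect_true(all(gain > -1e-12))
})

test_that("identical grids give bit-identical areas", {
  lay <- field_layout(12, 18, 0.6, 0.3)
  g <- simulate_emergence(lay, 0.85, seed = 81)
  expect_identical(voronoi_cell_areas(g), voronoi_cell_areas(g))
})

test_that("compensated yield reduces to the parabola on full stands", {
  Dm <- 6
  m <- yield_model(Dm = Dm, Ym = 7.5, A = -0.5)
  lay <- field_layout(10, 20, 0.5, 1 / (0.5 * Dm))
  expect_equal(compensated_field_yield(m, simulate_emergence(lay, 1)), 7.5,
               tolerance = 1e-12)

  # lone survivor: clamped per-plant yield spread over the field
  cells <- matrix(0L, 10, 20)
  cells[5, 5] <- 1L
  g1 <- emergence_grid(cells, lay)
  area <- prod(layout_dims(lay))
  expect_equal(compensated_field_yield(m, g1),
               per_plant_yield(m, area) / (area / 1e4))
  expect_gte(compensated_field_yield(m, g1), 0)

  expect_warning(y0 <- compensated_field_yield(
    m, emergence_grid(matrix(0L, 3, 3), field_layout(3, 3, 0.5, 1 / 3))),
    "empty")
  expect_identical(y0, 0)
})

test_that("area compensation beats the rigid nominal-area accounting", {
  # The bound holds whenever per-plant yield is non-decreasing in area,
  # i.e. when the expanded intercept A*Dm^2 + Ym is non-negative; every
  # survivor then earns at least its full-stand share from an area that
  # can only have grown.
  Dm <- 4.5
  m <- yield_model(Dm = Dm, Ym = 7.5, theta = 48)
  stopifnot(m$A * Dm^2 + m$Ym >= 0)
  lay <- field_layout(20, 40, 0.5, 1 / (0.5 * Dm))
  field_hm2 <- prod(layout_dims(lay)) / 1e4
  for (r in 1:200) {
    g <- simulate_emergence(lay, 0.9, seed = derive_seed(91, r))
    comp <- compensated_field_yield(m, g)
    rigid <- emergence_counts(g)$n_emerged *
      per_plant_yield(m, 1 / Dm) / field_hm2
    expect_gt(comp, rigid)
    expect_lt(comp, m$Ym)  # compensation is partial, never full recovery
  }
})
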