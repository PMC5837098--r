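test_that("spot labeling handles the canonical small cases", {
  expect_identical(label_spots(matrix(1L, 4, 4))$n_spots, 0L)

  one <- matrix(1L, 3, 3)
  one[2, 2] <- 0L
  lab <- label_spots(one)
  expect_identical(lab$n_spots, 1L)
  expect_identical(sum(lab$labels == 1L), 1L)

  diagm <- matrix(c(0L, 1L, 1L, 0L), 2)
  expect_identical(label_spots(diagm, connectivity = 4)$n_spots, 2L)
  expect_identical(label_spots(diagm, connectivity = 8)$n_spots, 1L)
  expect_error(label_spots(diagm, connectivity = 6), "4 or 8")
})

test_that("labeling agrees with a BFS flood-fill oracle on random grids", {
  set.seed(21)
  for (k in 1:500) {
    cells <- random_cells(sample(1:8, 1), sample(1:8, 1), runif(1, 0.1, 0.9))
    for (conn in c(4, 8)) {
      got <- label_spots(emergence_grid(cells), connectivity = conn)
      ora <- bfs_label_oracle(cells, conn)
      expect_identical(got$n_spots, ora$n_spots)
      expect_identical(canonical_labels(got$labels),
                       canonical_labels(ora$labels))
    }
  }
})

test_that("spot statistics satisfy their defining identities", {
  lay <- field_layout(10, 12, 0.6, 0.3)
  grids <- lapply(1:20, function(r)
    simulate_emergence(lay, 0.8, seed = derive_seed(5, r)))
  st <- spot_statistics(grids)
  expect_equal(st$hundred_dot_spot, 100 * st$mean_spots / 120,
               tolerance = 1e-9)
  expect_equal(st$spot_missing_seedling, st$mean_missing / st$mean_spots,
               tolerance = 1e-9)
  expect_identical(st$n_replicates, 20L)

  full <- list(simulate_emergence(lay, 1), simulate_emergence(lay, 1))
  stf <- spot_statistics(full)
  expect_equal(stf$mean_missing, 0)
  expect_equal(stf$mean_spots, 0)
  expect_equal(stf$hundred_dot_spot, 0)
  expect_true(is.na(stf$spot_missing_seedling))

  expect_error(spot_statistics(list()), "non-empty")
  bad <- list(simulate_emergence(lay, 0.8),
              simulate_emergence(field_layout(5, 5, 0.6, 0.3), 0.8))
  expect_error(spot_statistics(bad), "one layout")
})

test_that("a single-replicate sweep equals the statistics of that grid", {
  lay <- gap_reference_layout()
  sw <- spot_rate_sweep(lay, rates = 0.85, n_replicates = 1, seed = 31)
  g <- simulate_emergence(lay, 0.85, seed = sowsim:::derive_seed(31, 1))
  st <- spot_statistics(list(g))
  expect_equal(sw$mean_missing, st$mean_missing)
  expect_equal(sw$mean_spots, st$mean_spots)
})

test_that("mean spot count matches the Euler-characteristic approximation", {
  lay <- gap_reference_layout()
  nr <- lay$n_rows
  nc <- lay$n_cols
  q <- 0.05
  # V - E + T for the 8-neighbor (king) graph of an i.i.d. zero field:
  # vertices, adjacent pairs (incl. diagonals), 3-cliques (4 per unit square)
  V <- nr * nc * q
  E <- (nr * (nc - 1) + (nr - 1) * nc + 2 * (nr - 1) * (nc - 1)) * q^2
  TT <- 4 * (nr - 1) * (nc - 1) * q^3
  sw <- spot_rate_sweep(lay, rates = 1 - q, n_replicates = 300, seed = 41)
  expect_lt(abs(sw$mean_spots - (V - E + TT)) / (V - E + TT), 0.03)
})

test_that("missing counts track 7200(1-rate) and spots peak near 0.81", {
  sw <- spot_rate_sweep(n_replicates = 200, seed = 42)
  expected <- 7200 * (1 - sw$rate)
  se <- sw$sd_missing / sqrt(sw$n_replicates)
  expect_true(all(abs(sw$mean_missing - expected) < 4 * se))
  expect_true(all(diff(sw$mean_missing) > 0))  # rates listed descending
  peak <- sw$rate[which.max(sw$hundred_dot_spot)]
  expect_true(peak %in% c(0.75, 0.8, 0.85))
})

test_that("Monte-Carlo standard error shrinks as 1/sqrt(n)", {
  lay <- gap_reference_layout()
  s500 <- spot_rate_sweep(lay, rates = 0.9, n_replicates = 500, seed = 51)
  s2000 <- spot_rate_sweep(lay, rates = 0.9, n_replicates = 2000, seed = 52)
  se500 <- s500$sd_missing / sqrt(500)
  se2000 <- s2000$sd_missing / sqrt(2000)
  expect_equal(se500 / se2000, 2, tolerance = 0.2)
})

test_that("quadratic fits interpolate exactly and verify against normal equations", {
  x <- c(0.1, 0.3, 0.5, 0.8, 1.2)
  y <- 2 * x^2 - x + 3
  f <- fit_quadratic(x, y)
  expect_equal(unname(coef(f)), c(2, -1, 3), tolerance = 1e-9)
  expect_equal(f$r_squared, 1)
  expect_equal(f$vertex[["x"]], 0.25, tolerance = 1e-9)

  # vertex identity on a noisy fit
  set.seed(61)
  yn <- y + rnorm(5, 0, 0.2)
  fn <- fit_quadratic(x, yn)
  cf <- coef(fn)
  expect_equal(fn$vertex[["x"]], -cf[["b"]] / (2 * cf[["a"]]),
               tolerance = 1e-9)
  expect_equal(fn$vertex[["y"]],
               cf[["c"]] - cf[["b"]]^2 / (4 * cf[["a"]]), tolerance = 1e-9)

  # independent normal-equations solution
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(unname(cf), unname(beta[c(3, 2, 1)]), tolerance = 1e-9)

  expect_error(fit_quadratic(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_quadratic(rep(1, 4), 1:4), "rank-deficient")
})

test_that("exponential fits recover exact laws and match an OLS-on-logs oracle", {
  x <- seq(0.2, 1.4, by = 0.3)
  y <- 5 * exp(-2 * x)
  f <- fit_exponential(x, y)
  expect_equal(unname(coef(f)), c(5, -2), tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  set.seed(62)
  yn <- y * exp(rnorm(length(y), 0, 0.1))
  fl <- fit_exponential(x, yn, method = "log-linear")
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% log(yn))
  expect_equal(fl$coefficients[["alpha"]], exp(beta[1]), tolerance = 1e-9)
  expect_equal(fl$coefficients[["beta"]], beta[2], tolerance = 1e-9)

  # nonlinear refinement cannot worsen the original-scale fit
  fn <- fit_exponential(x, yn, method = "nonlinear")
  sse <- function(ft) sum((yn - ft$coefficients[["alpha"]] *
                             exp(ft$coefficients[["beta"]] * x))^2)
  expect_lte(sse(fn), sse(fl) + 1e-12)

  expect_error(fit_exponential(x, y - 1), "positive")
})

test_that("the reference table's spot-seedling law is close to a -6.1 exponent", {
  ref <- reference_spot_table()
  f <- fit_exponential(ref$rate, ref$spot_missing_seedling)
  expect_lt(abs(f$coefficients[["beta"]] - (-6.144)), 0.5)
  expect_gt(f$r_squared, 0.95)
})
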