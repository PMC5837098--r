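#' Seeds per hole for a target missing rate under multi-seed sowing
#'
#' Traditional sowing drops several seeds per hole so that at least one
#' emerges. With emergence probability `rate` per seed, a hole stays empty
#' with probability `(1 - rate)^n`; the smallest `n` with
#' `(1 - rate)^n <= max_missing_rate` is
#' `ceiling(log10(max_missing_rate) / log10(1 - rate))` — for the default
#' 1% target, `-2 / log10(1 - rate)`.
#'
#' @param emergence_rate per-seed field emergence probability, strictly
#'   between 0 and 1.
#' @param max_missing_rate tolerated probability of an empty hole
#'   (default 0.01).
#' @return List with `n` (integer seeds per hole) and `bound` (the
#'   real-valued lower bound it ceilings).
#' @examples
#' seeds_per_hole(0.85)   # bound 2.4, n = 3
#' @export
seeds_per_hole <- function(emergence_rate, max_missing_rate = 0.01) {
  stopifnot(is.numeric(emergence_rate), length(emergence_rate) == 1L)
  if (!is.finite(emergence_rate) || emergence_rate <= 0 ||
      emergence_rate >= 1)
    stop("`emergence_rate` must lie strictly between 0 and 1")
  if (max_missing_rate <= 0 || max_missing_rate >= 1)
    stop("`max_missing_rate` must lie strictly between 0 and 1")
  bound <- log10(max_missing_rate) / log10(1 - emergence_rate)
  list(n = as.integer(ceiling(bound - 1e-9)), bound = bound)
}

#' Sowing density of the two single-seed policies
#'
#' Method 1 sows at the optimum density `D*` and accepts an expected stand
#' of `D* * rate`; Method 2 inflates sowing to `D* / rate` so the expected
#' emerged stand equals `D*`. At `rate = 1` the two coincide.
#'
#' @param method 1 or 2.
#' @param optimum_density target (optimum) stand, plants/hm^2.
#' @param emergence_rate field seedling-emergence rate in (0, 1].
#' @return Sowing density in plants/hm^2.
#' @examples
#' sowing_density(2, 60000, 0.85)  # 70588.2
#' @export
sowing_density <- function(method, optimum_density, emergence_rate) {
  if (!method %in% c(1, 2)) stop("`method` must be 1 or 2")
  if (optimum_density <= 0) stop("`optimum_density` must be positive")
  if (!is.finite(emergence_rate) || emergence_rate <= 0 ||
      emergence_rate > 1)
    stop("`emergence_rate` must lie in (0, 1]")
  if (method == 1) optimum_density else optimum_density / emergence_rate
}

#' Factorial comparison of the two sowing policies
#'
#' Runs the full factorial of optimum density x maximum yield x density
#' sensitivity x emergence rate for both sowing policies. Each cell
#' simulates `n_replicates` emergence grids (row spacing fixed, plant
#' spacing set by the policy's sowing density), scores every replicate
#' with the Voronoi-compensated yield, and reports the mean and standard
#' deviation. Grids are shared across the (maximum yield, sensitivity)
#' combinations, which only rescale the parabola, so the factorial runs
#' at the cost of the density x rate x method grid.
#'
#' @param optimum_densities optimum densities, plants/m^2.
#' @param max_yields maximum yields `Ym`, t/hm^2.
#' @param sensitivities tangent-angle sensitivities, degrees.
#' @param rates field emergence rates.
#' @param n_replicates replicates per cell (default 200).
#' @param row_spacing fixed row spacing, m.
#' @param field_width,field_height simulated field, m. Yields are
#'   normalized per hm^2, so field size only sets the Monte-Carlo
#'   granularity; the default 36 m x 36 m (60 rows) keeps the full
#'   factorial fast while holding per-cell standard errors well below the
#'   policy differences under study.
#' @param seed base RNG seed; replicate streams are derived
#'   deterministically from it.
#' @return A data frame of class `"method_comparison"`: one row per
#'   factorial cell and method with `optimum_density`, `max_yield`,
#'   `sensitivity`, `rate`, `method`, `mean_yield`, `sd_yield`,
#'   `n_replicates`.
#' @examples
#' res <- run_method_comparison(optimum_densities = 6, max_yields = 7.5,
#'                              sensitivities = 112, rates = c(0.85, 0.95),
#'                              n_replicates = 20, field_width = 12,
#'                              field_height = 12, seed = 1)
#' res[, c("rate", "method", "mean_yield", "sd_yield")]
#' @export
run_method_comparison <- function(optimum_densities = c(4.5, 6, 7.5, 9, 10.5, 12),
                                  max_yields = c(5.25, 7.5, 9.75, 12, 14.25),
                                  sensitivities = c(16, 48, 80, 112),
                                  rates = c(0.75, 0.85, 0.9, 0.95),
                                  n_replicates = 200,
                                  row_spacing = 0.6,
                                  field_width = 36, field_height = 36,
                                  seed = 1) {
  stopifnot(n_replicates >= 2, length(optimum_densities) >= 1,
            length(max_yields) >= 1, length(sensitivities) >= 1,
            length(rates) >= 1)
  A_by_sens <- vapply(sensitivities, sensitivity_to_coefficient, numeric(1))
  combos <- expand.grid(max_yield = max_yields, sensitivity = sensitivities,
                        KEEP.OUT.ATTRS = FALSE)
  combos$A <- A_by_sens[match(combos$sensitivity, sensitivities)]
  field_hm2 <- field_width * field_height / 1e4

  out <- list()
  sim_index <- 0L
  for (Dm in optimum_densities) {
    for (rate in rates) {
      for (method in 1:2) {
        sow <- sowing_density(method, Dm * 1e4, rate)  # plants/hm^2
        lay <- layout_from_density(sow, row_spacing, field_width,
                                   field_height)
        fm2 <- prod(layout_dims(lay))
        tot <- matrix(0, nrow(combos), 2)  # sum, sum of squares
        for (r in seq_len(n_replicates)) {
          sim_index <- sim_index + 1L
          g <- simulate_emergence(lay, rate,
                                  seed = derive_seed(seed, sim_index))
          if (sum(g$cells) == 0L) {
            y <- rep(0, nrow(combos))
          } else if (all(g$cells == 1L)) {
            # full stand: per-plant yield set by the planting density itself
            d <- 1 / (lay$row_spacing * lay$plant_spacing)
            y <- combos$A * (d - Dm)^2 + combos$max_yield
          } else {
            a <- voronoi_areas_cpp(g$cells, lay$row_spacing,
                                   lay$plant_spacing)
            q <- (1 / a - Dm)^2
            y <- vapply(seq_len(nrow(combos)), function(ci) {
              sum(pmax(0, combos$A[ci] * q + combos$max_yield[ci]) * a)
            }, numeric(1)) / 1e4 / (fm2 / 1e4)
          }
          tot[, 1] <- tot[, 1] + y
          tot[, 2] <- tot[, 2] + y^2
        }
        mean_y <- tot[, 1] / n_replicates
        var_y <- pmax(0, (tot[, 2] - n_replicates * mean_y^2) /
                        (n_replicates - 1))
        out[[length(out) + 1L]] <- data.frame(
          optimum_density = Dm, max_yield = combos$max_yield,
          sensitivity = combos$sensitivity, rate = rate, method = method,
          mean_yield = mean_y, sd_yield = sqrt(var_y),
          n_replicates = n_replicates)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "field") <- c(width = field_width, height = field_height,
                          row_spacing = row_spacing)
  class(res) <- c("method_comparison", "data.frame")
  res
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "Sowing-policy comparison: %d cells x 2 methods, %d replicates each\n",
    nrow(x) / 2L, x$n_replicates[1]))
  gap <- with(x, tapply(mean_yield, method, mean))
  cat(sprintf("  grand mean yield: method 1 %.3f, method 2 %.3f t/hm^2\n",
              gap[["1"]], gap[["2"]]))
  cat("First rows:\n")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Regression of yield reduction on the emergence rate
#'
#' Yield reduction is the configured maximum yield minus the simulated
#' mean yield. For each optimum density and method (at one fixed
#' sensitivity, pooling maximum-yield levels), the reduction is regressed
#' on the emergence rate by OLS. Higher emergence leaves less to lose, so
#' slopes are negative, and the inflated-sowing policy (method 2) loses
#' yield more slowly — its slope is smaller in magnitude.
#'
#' @param results a [run_method_comparison()] table.
#' @param sensitivity the sensitivity (degrees) to condition on; default
#'   112.
#' @return A data frame of class `"reduction_regression"`: one row per
#'   (optimum density, method) with `intercept`, `slope`, `r_squared`.
#' @export
yield_reduction_regression <- function(results, sensitivity = 112) {
  stopifnot(inherits(results, "data.frame"))
  sub <- results[results$sensitivity == sensitivity, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows at the requested sensitivity")
  if (length(unique(sub$rate)) < 2L)
    stop("need at least 2 distinct emergence rates")
  sub$reduction <- sub$max_yield - sub$mean_yield
  cells <- unique(sub[, c("optimum_density", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    s <- sub[sub$optimum_density == cells$optimum_density[k] &
               sub$method == cells$method[k], ]
    fit <- lm(reduction ~ rate, data = s)
    data.frame(optimum_density = cells$optimum_density[k],
               method = cells$method[k],
               intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]),
               r_squared = summary(fit)$r.squared)
  }))
  rownames(out) <- NULL
  class(out) <- c("reduction_regression", "data.frame")
  out
}

#' Multiple regression of yield reduction on sensitivity and rate
#'
#' For each optimum density and method (pooling maximum-yield levels and
#' rates), regresses the yield reduction on the sensitivity and the
#' sensitivity x rate interaction. Steeper parabolas lose more
#' (positive sensitivity main effect), but a high emergence rate damps
#' the loss (negative interaction).
#'
#' @param results a [run_method_comparison()] table with at least two
#'   sensitivities and two rates.
#' @return A data frame of class `"reduction_regression"`: one row per
#'   (optimum density, method) with `intercept`, `sensitivity`,
#'   `sensitivity_x_rate`, `r_squared`, `mean_reduction`.
#' @export
sensitivity_rate_regression <- function(results) {
  stopifnot(inherits(results, "data.frame"))
  if (length(unique(results$sensitivity)) < 2L ||
      length(unique(results$rate)) < 2L)
    stop("need at least 2 sensitivities and 2 rates")
  results$reduction <- results$max_yield - results$mean_yield
  cells <- unique(results[, c("optimum_density", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    s <- results[results$optimum_density == cells$optimum_density[k] &
                   results$method == cells$method[k], ]
    fit <- lm(reduction ~ sensitivity + sensitivity:rate, data = s)
    cf <- coef(fit)
    if (anyNA(cf)) stop("rank-deficient design")
    data.frame(optimum_density = cells$optimum_density[k],
               method = cells$method[k],
               intercept = unname(cf[1]),
               sensitivity = unname(cf["sensitivity"]),
               sensitivity_x_rate = unname(cf["sensitivity:rate"]),
               r_squared = summary(fit)$r.squared,
               mean_reduction = mean(s$reduction))
  }))
  rownames(out) <- NULL
  class(out) <- c("reduction_regression", "data.frame")
  out
}
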