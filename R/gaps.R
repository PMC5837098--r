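#' Label seedling-missing spots
#'
#' A *seedling-missing spot* is a maximal connected region of non-emerged
#' positions (zeros) in the planting grid. Under 4-connectivity two zeros
#' are neighbors when they share an edge of the lattice; under
#' 8-connectivity diagonal contact also joins them. Labels are assigned
#' `1..n_spots` in row-major first-encounter order; emerged cells keep 0.
#'
#' @param grid an [emergence_grid()] (or a 0/1 matrix).
#' @param connectivity 4 or 8 (default 8; see Details).
#' @details The default is 8-connectivity: the spot counts it produces on
#'   i.i.d. Bernoulli grids agree with the Euler-characteristic
#'   approximation and with published reference simulations
#'   ([reference_spot_table()]), whereas 4-connectivity over-counts by
#'   splitting diagonal contacts.
#' @return An object of class `"spot_labeling"`: list with the integer
#'   `labels` matrix, `n_spots` and `connectivity`.
#' @examples
#' g <- emergence_grid(matrix(c(0, 1, 1, 0), 2))
#' label_spots(g, connectivity = 4)$n_spots  # 2: diagonal zeros separate
#' label_spots(g, connectivity = 8)$n_spots  # 1: diagonal contact joins
#' @export
label_spots <- function(grid, connectivity = 8) {
  cells <- if (inherits(grid, "emergence_grid")) grid$cells else {
    grid <- emergence_grid(grid)
    grid$cells
  }
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8")
  res <- label_components_cpp(cells, as.integer(connectivity))
  structure(list(labels = res$labels, n_spots = res$n_spots,
                 connectivity = as.integer(connectivity)),
            class = "spot_labeling")
}

#' @export
print.spot_labeling <- function(x, ...) {
  cat(sprintf("Spot labeling: %d spot(s), %d-connectivity, %d x %d grid\n",
              x$n_spots, x$connectivity, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Missing-spot statistics of replicate grids
#'
#' Summarizes a set of replicate grids (same layout and emergence rate):
#' the mean number of missing seedlings, the mean number of spots, the
#' number of *hundred-dot spots* (spots per 100 planting points,
#' `100 * mean_spots / n_positions`) and the number of *spot missing
#' seedlings* (mean missing count divided by mean spot count, i.e. the
#' ratio of means — defined even when individual replicates have no spot).
#'
#' @param grids a list of [emergence_grid()]s with identical layout and
#'   rate.
#' @param connectivity 4 or 8.
#' @return A one-row data frame of class `"spot_stats"` with columns
#'   `rate`, `mean_missing`, `mean_spots`, `hundred_dot_spot`,
#'   `spot_missing_seedling`, `sd_missing`, `sd_spots`, `n_replicates`.
#'   `spot_missing_seedling` is `NA` when no replicate has a spot.
#' @export
spot_statistics <- function(grids, connectivity = 8) {
  if (!is.list(grids) || length(grids) == 0L ||
      !all(vapply(grids, inherits, logical(1), "emergence_grid")))
    stop("`grids` must be a non-empty list of emergence grids")
  dims <- vapply(grids, function(g) dim(g$cells), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all grids must share one layout")
  rates <- vapply(grids, `[[`, numeric(1), "rate")
  if (any(rates != rates[1]))
    stop("all grids must share one emergence rate")
  missing <- vapply(grids, function(g) length(g$cells) - sum(g$cells),
                    numeric(1))
  spots <- vapply(grids, function(g)
    count_components_cpp(g$cells, as.integer(connectivity)), numeric(1))
  .spot_record(rates[1], missing, spots, prod(dims[, 1]))
}

.spot_record <- function(rate, missing, spots, n_positions) {
  mm <- mean(missing)
  ms <- mean(spots)
  out <- data.frame(
    rate = rate,
    mean_missing = mm,
    mean_spots = ms,
    hundred_dot_spot = 100 * ms / n_positions,
    spot_missing_seedling = if (ms > 0) mm / ms else NA_real_,
    sd_missing = if (length(missing) > 1L) sd(missing) else NA_real_,
    sd_spots = if (length(spots) > 1L) sd(spots) else NA_real_,
    n_replicates = length(missing))
  class(out) <- c("spot_stats", "data.frame")
  out
}

#' Sweep missing-spot statistics over emergence rates
#'
#' For each rate, simulates `n_replicates` independent emergence grids on
#' `layout` and accumulates [spot_statistics()]. Replicate `r` of rate `k`
#' draws from a deterministic stream derived from `(seed, k, r)`, so the
#' sweep is exactly reproducible.
#'
#' @param layout a [field_layout()]; the reference configuration is 60
#'   rows x 120 columns with row spacing twice the plant spacing (see
#'   [gap_reference_layout()]).
#' @param rates emergence rates to sweep (default the reference sweep
#'   0.95, 0.925, 0.9, 0.85, 0.8, 0.75, 0.7).
#' @param n_replicates grids per rate (default 1000).
#' @param connectivity 4 or 8.
#' @param seed base RNG seed.
#' @return A data frame of class `c("spot_sweep", "spot_stats",
#'   "data.frame")`, one row per rate (columns as in
#'   [spot_statistics()]).
#' @examples
#' sw <- spot_rate_sweep(gap_reference_layout(), rates = c(0.9, 0.8),
#'                       n_replicates = 20, seed = 1)
#' sw[, 1:5]
#' @export
spot_rate_sweep <- function(layout = gap_reference_layout(),
                            rates = c(0.95, 0.925, 0.9, 0.85, 0.8, 0.75, 0.7),
                            n_replicates = 1000, connectivity = 8,
                            seed = 1) {
  stopifnot(inherits(layout, "field_layout"), n_replicates >= 1)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("`rates` must lie in [0, 1]")
  n_cells <- layout$n_rows * layout$n_cols
  rows <- vector("list", length(rates))
  for (k in seq_along(rates)) {
    missing <- numeric(n_replicates)
    spots <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      g <- simulate_emergence(layout, rates[k],
                              seed = derive_seed(seed, (k - 1L) * n_replicates + r))
      missing[r] <- n_cells - sum(g$cells)
      spots[r] <- count_components_cpp(g$cells, as.integer(connectivity))
    }
    rows[[k]] <- .spot_record(rates[k], missing, spots, n_cells)
  }
  out <- do.call(rbind, rows)
  attr(out, "connectivity") <- as.integer(connectivity)
  attr(out, "seed") <- seed
  class(out) <- c("spot_sweep", "spot_stats", "data.frame")
  out
}

#' Reference layout and published spot statistics
#'
#' `gap_reference_layout()` returns the 60-row x 120-column lattice with
#' row spacing twice the plant spacing used for the missing-spot study.
#' `reference_spot_table()` returns published reference values: the means
#' of 1000 simulations per emergence rate on that lattice — mean missing
#' seedlings, mean spot count, hundred-dot spots and spot missing
#' seedlings — used as the deterministic input of the worked curve-fit
#' example and as a cross-check for fresh sweeps.
#'
#' @param row_spacing row spacing in m (plant spacing is half of it).
#' @return A [field_layout()], or a 7 x 5 data frame.
#' @export
gap_reference_layout <- function(row_spacing = 0.6) {
  field_layout(60, 120, row_spacing = row_spacing,
               plant_spacing = row_spacing / 2)
}

#' @rdname gap_reference_layout
#' @export
reference_spot_table <- function() {
  data.frame(
    rate = c(0.95, 0.925, 0.9, 0.85, 0.8, 0.75, 0.7),
    mean_missing = c(360.8, 541.5, 720.7, 1080.5, 1438.7, 1799.1, 2159.4),
    mean_spots = c(293.3, 393.4, 465.6, 538.8, 533.4, 468.7, 368),
    hundred_dot_spot = c(4.1, 5.5, 6.5, 7.5, 7.4, 6.5, 5.1),
    spot_missing_seedling = c(1.2, 1.4, 1.5, 2, 2.7, 3.8, 5.9))
}

#' Least-squares curve fits for the spot-distribution laws
#'
#' `fit_quadratic()` fits \eqn{y = a x^2 + b x + c} by ordinary least
#' squares; the hundred-dot-spot count follows such a parabola in the
#' emergence rate, peaking near 0.81. `fit_exponential()` fits
#' \eqn{y = \alpha e^{\beta x}}, the law of the spot-missing-seedling
#' count; `method = "log-linear"` runs OLS on \eqn{(x, \log y)},
#' `method = "nonlinear"` refines that fit by least squares on the
#' original scale via [stats::nls()].
#'
#' @param x,y numeric vectors of equal length.
#' @param method exponential fitting method, `"log-linear"` (default) or
#'   `"nonlinear"`.
#' @return An object of class `"curve_fit"`: list with `model_kind`,
#'   `coefficients` (named `a`, `b`, `c` for the quadratic; `alpha`,
#'   `beta` for the exponential), `r_squared`, `vertex` (quadratic only),
#'   `x_range`, `y_range`.
#' @examples
#' ref <- reference_spot_table()
#' fit_quadratic(ref$rate, ref$hundred_dot_spot)
#' fit_exponential(ref$rate, ref$spot_missing_seedling)
#' @export
fit_quadratic <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points for a quadratic fit")
  fit <- lm(y ~ x + I(x^2))
  if (anyNA(coef(fit))) stop("rank-deficient design: x values degenerate")
  cf <- c(a = unname(coef(fit)[3]), b = unname(coef(fit)[2]),
          c = unname(coef(fit)[1]))
  vertex <- c(x = -cf[["b"]] / (2 * cf[["a"]]),
              y = cf[["c"]] - cf[["b"]]^2 / (4 * cf[["a"]]))
  .curve_fit("quadratic", cf, .r_squared(y, fitted(fit)), x, y,
             vertex = vertex)
}

#' @rdname fit_quadratic
#' @export
fit_exponential <- function(x, y, method = c("log-linear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points")
  if (any(y <= 0))
    stop("exponential fit requires positive y values")
  lfit <- lm(log(y) ~ x)
  alpha <- exp(unname(coef(lfit)[1]))
  beta <- unname(coef(lfit)[2])
  if (method == "nonlinear") {
    nfit <- nls(y ~ alpha * exp(beta * x),
                start = list(alpha = alpha, beta = beta))
    alpha <- unname(coef(nfit)[["alpha"]])
    beta <- unname(coef(nfit)[["beta"]])
  }
  .curve_fit("exponential", c(alpha = alpha, beta = beta),
             .r_squared(y, alpha * exp(beta * x)), x, y)
}

.r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum((y - yhat)^2) / tss))
}

.curve_fit <- function(kind, coefficients, r_squared, x, y, vertex = NULL) {
  structure(list(model_kind = kind, coefficients = coefficients,
                 r_squared = r_squared, vertex = vertex,
                 x_range = range(x), y_range = range(y)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, digits = 5, ...) {
  eq <- if (x$model_kind == "quadratic") {
    sprintf("y = %.*g x^2 + %.*g x + %.*g", digits,
            x$coefficients[["a"]], digits, x$coefficients[["b"]], digits,
            x$coefficients[["c"]])
  } else {
    sprintf("y = %.*g exp(%.*g x)", digits, x$coefficients[["alpha"]],
            digits, x$coefficients[["beta"]])
  }
  cat(sprintf("%s least-squares fit: %s\n", x$model_kind, eq))
  cat(sprintf("  R^2 = %.4f on x in [%.4g, %.4g]\n", x$r_squared,
              x$x_range[1], x$x_range[2]))
  if (!is.null(x$vertex))
    cat(sprintf("  vertex (%.4f, %.4f)\n", x$vertex[["x"]], x$vertex[["y"]]))
  invisible(x)
}

#' @export
coef.curve_fit <- function(object, ...) object$coefficients
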