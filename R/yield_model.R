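#' Vertex-form yield-density model
#'
#' Yield per unit area is modeled as a downward parabola in planting
#' density, written in vertex form \eqn{Y(D) = A (D - Dm)^2 + Ym}: the
#' maximum yield `Ym` (t/hm\eqn{^2}) is attained at the optimum density
#' `Dm` (plants/m\eqn{^2}) and falls off quadratically on either side with
#' curvature `A < 0`. Instead of `A` the model can be parameterized by its
#' *density sensitivity* `theta`: the angle (degrees) between the two
#' tangents drawn at one plant/m\eqn{^2} on either side of the optimum,
#' where the tangent slopes are \eqn{\pm 2A} (see
#' [sensitivity_to_coefficient()]).
#'
#' @param Dm optimum planting density, plants/m^2 (> 0).
#' @param Ym maximum yield, t/hm^2 (> 0), attained at `Dm`.
#' @param A quadratic coefficient, t/hm^2 per (plants/m^2)^2; must be
#'   negative. Exactly one of `A` and `theta` must be supplied.
#' @param theta density sensitivity: tangent angle in degrees, in (0, 180).
#'
#' @return An object of class `"yield_model"`: a list with elements `A`,
#'   `Dm`, `Ym` and, when constructed from an angle, `theta`.
#'
#' @examples
#' m <- yield_model(Dm = 6, Ym = 7.5, theta = 90)
#' yield_at_density(m, 6)        # the maximum: 7.5 t/hm^2
#' yield_at_density(m, 4)        # 5.5 t/hm^2
#' @seealso [yield_at_density()], [per_plant_yield()],
#'   [expanded_coefficients()]
#' @export
yield_model <- function(Dm, Ym, A = NULL, theta = NULL) {
  if (is.null(A) == is.null(theta))
    stop("supply exactly one of `A` and `theta`")
  if (!is.null(theta)) A <- sensitivity_to_coefficient(theta)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(Dm), length(Dm) == 1L, is.finite(Dm),
            is.numeric(Ym), length(Ym) == 1L, is.finite(Ym))
  if (A >= 0) stop("`A` must be negative (downward parabola)")
  if (Dm <= 0) stop("`Dm` must be positive")
  if (Ym <= 0) stop("`Ym` must be positive")
  structure(list(A = A, Dm = Dm, Ym = Ym, theta = theta),
            class = "yield_model")
}

#' Convert a density-sensitivity angle to the quadratic coefficient
#'
#' The two tangents of the yield parabola at unit density offsets from the
#' optimum have slopes \eqn{\pm 2A}; the sensitivity is the angle they
#' subtend. A larger angle means a steeper yield loss per unit density
#' deviation. Inverting the angle gives
#' \eqn{A = -\tan(\theta/2)/2}.
#'
#' @param theta_degrees angle between the two tangents, degrees, in (0, 180).
#' @return The (negative) quadratic coefficient `A`.
#' @examples
#' sensitivity_to_coefficient(90)   # -0.5
#' @export
sensitivity_to_coefficient <- function(theta_degrees) {
  stopifnot(is.numeric(theta_degrees), length(theta_degrees) == 1L)
  if (!is.finite(theta_degrees) || theta_degrees <= 0 || theta_degrees >= 180)
    stop("`theta_degrees` must lie strictly between 0 and 180")
  -tan(theta_degrees / 2 * pi / 180) / 2
}

#' Evaluate the yield parabola and its derivative
#'
#' `yield_at_density()` returns \eqn{A (D - Dm)^2 + Ym} (t/hm^2);
#' `yield_derivative()` returns \eqn{dY/dD = 2 A (D - Dm)}, the marginal
#' yield per unit density. The raw parabola is returned unclamped, so it
#' can be negative far from the optimum; see [per_plant_yield()] for the
#' clamped per-plant conversion.
#'
#' @param model a [yield_model()].
#' @param D planting density, plants/m^2 (vectorized, all >= 0).
#' @return Numeric vector of yields (t/hm^2) or slopes (t/hm^2 per
#'   plants/m^2).
#' @export
yield_at_density <- function(model, D) {
  stopifnot(inherits(model, "yield_model"), is.numeric(D))
  if (any(!is.finite(D)) || any(D < 0)) stop("`D` must be non-negative")
  model$A * (D - model$Dm)^2 + model$Ym
}

#' @rdname yield_at_density
#' @export
yield_derivative <- function(model, D) {
  stopifnot(inherits(model, "yield_model"), is.numeric(D))
  if (any(!is.finite(D)) || any(D < 0)) stop("`D` must be non-negative")
  2 * model$A * (D - model$Dm)
}

#' Per-plant yield from a nutrition area
#'
#' A plant occupying `area` m^2 grows as if it stood in a uniform stand at
#' its *equivalent density* \eqn{d = 1/area} plants/m^2: the field-level
#' parabola is evaluated at `d` and converted to a per-plant mass by
#' dividing by `d` plants/m^2 and the 10^4 m^2/hm^2 area factor. Negative
#' parabola values (very large areas) are clamped to zero — a plant cannot
#' produce negative mass.
#'
#' @param model a [yield_model()].
#' @param area nutrition area per plant, m^2 (vectorized, all > 0).
#' @return Yield per plant in tonnes.
#' @examples
#' m <- yield_model(Dm = 6, Ym = 7.5, A = -0.5)
#' per_plant_yield(m, 1 / 6)   # vertex: Ym/(Dm * 1e4)
#' per_plant_yield(m, 0.2)     # d = 5, Y = 7.0, 1.4e-4 t
#' @export
per_plant_yield <- function(model, area) {
  stopifnot(inherits(model, "yield_model"), is.numeric(area))
  if (any(!is.finite(area)) || any(area <= 0)) stop("`area` must be positive")
  d <- 1 / area
  pmax(0, yield_at_density(model, d)) / (d * 1e4)
}

#' Expanded-form coefficients of the yield parabola
#'
#' The vertex form \eqn{A (D - Dm)^2 + Ym} expands to
#' \eqn{A D^2 + B D + C} with \eqn{B = -2 A Dm} and
#' \eqn{C = A Dm^2 + Ym}. `expanded_coefficients()` returns `(A, B, C)`;
#' `yield_model_from_expanded()` inverts the expansion
#' (\eqn{Dm = -B/2A}, \eqn{Ym = C - B^2/4A}), so the round trip is the
#' identity.
#'
#' @param model a [yield_model()].
#' @return A named numeric vector `c(A, B, C)`.
#' @export
expanded_coefficients <- function(model) {
  stopifnot(inherits(model, "yield_model"))
  c(A = model$A,
    B = -2 * model$A * model$Dm,
    C = model$A * model$Dm^2 + model$Ym)
}

#' @rdname expanded_coefficients
#' @param A,B,C expanded quadratic coefficients, `A < 0`.
#' @export
yield_model_from_expanded <- function(A, B, C) {
  if (A >= 0) stop("`A` must be negative")
  yield_model(Dm = -B / (2 * A), Ym = C - B^2 / (4 * A), A = A)
}

#' @export
print.yield_model <- function(x, ...) {
  cat("Yield-density model: Y(D) = A*(D - Dm)^2 + Ym\n")
  cat(sprintf("  A  = %.6g t/hm^2 per (plants/m^2)^2%s\n", x$A,
              if (!is.null(x$theta))
                sprintf("  (sensitivity %.6g deg)", x$theta) else ""))
  cat(sprintf("  Dm = %.6g plants/m^2 (optimum density)\n", x$Dm))
  cat(sprintf("  Ym = %.6g t/hm^2 (maximum yield)\n", x$Ym))
  invisible(x)
}

#' @export
coef.yield_model <- function(object, ...) expanded_coefficients(object)

#' @param object a `yield_model`.
#' @param newdata numeric vector of densities (plants/m^2); defaults to the
#'   optimum density.
#' @rdname yield_at_density
#' @export
predict.yield_model <- function(object, newdata = object$Dm, ...) {
  yield_at_density(object, newdata)
}
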