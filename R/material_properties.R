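# Temperature-dependent carrier properties. Viscosity drops steeply with
# temperature for mineral oils; a Vogel-Fulcher-Tammann law through three
# measured points captures that curvature exactly, while density is well
# described by a linear law over 0-100 degC.

.C_to_K <- function(T_C) T_C + 273.15

#' Fit a viscosity-temperature model through measured points
#'
#' With exactly three points, fits the Vogel-Fulcher-Tammann (VFT) law
#' `eta(T) = A exp(B / (T - T0))` (temperatures in kelvin) exactly through
#' them by closed-form elimination of `T0`. If the VFT solution is degenerate
#' (non-positive `B`, or `T0` inside the evaluation range) or the number of
#' points is not three, an Arrhenius law `eta(T) = A exp(B / T)` is fitted by
#' least squares on `log(eta)` instead (exact for two points; constant when
#' the two values are equal).
#'
#' @param temperatures Measurement temperatures, degrees Celsius, strictly
#'   increasing, length >= 2.
#' @param values Measured dynamic viscosities, Pa s (> 0).
#' @param valid_range Evaluation range in degrees Celsius, default `c(0, 100)`.
#' @return Object of class `"property_model"` with fields `kind`
#'   (`"viscosity-VFT"` or `"viscosity-Arrhenius"`), `params`, `valid_range`
#'   and the input `points`.
#' @examples
#' fit_viscosity(c(20, 40, 60), c(75e-3, 40e-3, 24e-3))
#' @export
fit_viscosity <- function(temperatures, values, valid_range = c(0, 100)) {
  .check_points(temperatures, values)
  if (any(values <= 0)) stop("viscosities must be > 0")
  if (any(diff(values) > 0))
    warning("viscosity increasing with temperature: unusual for a simple ",
            "carrier liquid; fitting anyway", call. = FALSE)
  TK <- .C_to_K(temperatures)
  lo_K <- .C_to_K(valid_range[1])
  if (length(values) == 3L) {
    l12 <- log(values[1] / values[2]); l23 <- log(values[2] / values[3])
    if (l23 != 0) {
      r <- l12 / l23
      den <- (TK[2] - TK[1]) - r * (TK[3] - TK[2])
      if (abs(den) > .Machine$double.eps * max(TK)) {
        T0 <- ((TK[2] - TK[1]) * TK[3] - r * (TK[3] - TK[2]) * TK[1]) / den
        if (T0 < lo_K) {
          B <- l12 / (1 / (TK[1] - T0) - 1 / (TK[2] - T0))
          A <- values[1] * exp(-B / (TK[1] - T0))
          if (B > 0 && A > 0)
            return(.property_model("viscosity-VFT",
                                   c(A = A, B = B, T0 = T0), valid_range,
                                   temperatures, values))
        }
      }
    }
  }
  # Arrhenius fallback / general least squares on log(eta) ~ 1/T
  if (stats::sd(values) == 0) {
    par <- c(A = values[1], B = 0)
  } else {
    fit <- stats::lm(log(values) ~ I(1 / TK))
    par <- c(A = exp(unname(stats::coef(fit)[1])),
             B = unname(stats::coef(fit)[2]))
  }
  .property_model("viscosity-Arrhenius", par, valid_range,
                  temperatures, values)
}

#' Fit a linear density-temperature model
#'
#' Ordinary least squares `rho(T) = a + b T` (T in degrees Celsius), the
#' usual description of liquid density over a modest temperature span.
#'
#' @inheritParams fit_viscosity
#' @param values Measured densities, kg/m^3.
#' @return A `"property_model"` of kind `"density-linear"`, with residuals
#'   stored in `params$residuals`.
#' @examples
#' fit_density(c(20, 40, 60), c(1187, 1172, 1158))
#' @export
fit_density <- function(temperatures, values, valid_range = c(0, 100)) {
  .check_points(temperatures, values)
  fit <- stats::lm(values ~ temperatures)
  .property_model("density-linear",
                  list(a = unname(stats::coef(fit)[1]),
                       b = unname(stats::coef(fit)[2]),
                       residuals = unname(stats::residuals(fit))),
                  valid_range, temperatures, values)
}

.check_points <- function(temperatures, values) {
  if (length(temperatures) != length(values) || length(values) < 2)
    stop("need at least 2 (temperature, value) points of equal length")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  invisible(NULL)
}

.property_model <- function(kind, params, valid_range, temperatures, values) {
  structure(list(kind = kind, params = params, valid_range = valid_range,
                 points = data.frame(T_C = temperatures, value = values)),
            class = "property_model")
}

#' Evaluate a fitted carrier-property model
#'
#' @param model A `"property_model"` from [fit_viscosity()] or [fit_density()].
#' @param T_C Temperature(s) in degrees Celsius, inside the model's
#'   `valid_range`.
#' @return Property value(s): Pa s for viscosity models, kg/m^3 for density.
#' @examples
#' m <- fit_viscosity(c(20, 40, 60), c(75e-3, 40e-3, 24e-3))
#' evaluate(m, 37)
#' @export
evaluate <- function(model, T_C) {
  stopifnot(inherits(model, "property_model"))
  rng <- model$valid_range
  if (any(T_C < rng[1] | T_C > rng[2]))
    stop("temperature outside the model's valid range [", rng[1], ", ",
         rng[2], "] degC")
  p <- model$params
  switch(model$kind,
    "viscosity-VFT" = p[["A"]] * exp(p[["B"]] / (.C_to_K(T_C) - p[["T0"]])),
    "viscosity-Arrhenius" = p[["A"]] * exp(p[["B"]] / .C_to_K(T_C)),
    "density-linear" = p$a + p$b * T_C,
    stop("unknown model kind: ", model$kind))
}

#' @export
predict.property_model <- function(object, newdata, ...) {
  evaluate(object, newdata)
}

#' @export
coef.property_model <- function(object, ...) {
  p <- object$params
  if (is.list(p)) unlist(p[setdiff(names(p), "residuals")]) else p
}

#' @export
print.property_model <- function(x, ...) {
  cat(sprintf("Carrier property model: %s on [%g, %g] degC\n",
              x$kind, x$valid_range[1], x$valid_range[2]))
  print(signif(coef(x), 6))
  invisible(x)
}
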