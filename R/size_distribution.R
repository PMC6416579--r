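#' Total volume fraction from fluid magnetization
#'
#' The total volume fraction of magnetic material in a dilute suspension is
#' the ratio of the fluid's saturation magnetization to the bulk saturation
#' magnetization of the magnetic phase, `phi = M_s_fluid / M_d`.
#'
#' @param M_s_fluid Saturation magnetization of the fluid, A/m.
#' @param M_d Bulk saturation magnetization of the magnetic material, A/m.
#' @return Dimensionless volume fraction in `[0, 1)`.
#' @examples
#' total_volume_fraction(42.3e3, 400e3)   # 0.10575
#' @export
total_volume_fraction <- function(M_s_fluid, M_d) {
  stopifnot(M_d > 0, M_s_fluid >= 0)
  if (M_s_fluid >= M_d)
    stop("M_s_fluid >= M_d is non-physical: fluid cannot be more magnetic ",
         "than the bulk material")
  M_s_fluid / M_d
}

#' Number-weighted to volume-weighted histogram conversion
#'
#' Converts a (diameter, count) histogram of particle sizes into volume
#' weights: each class is weighted by `count * d^3` (the volume of a sphere
#' up to the common factor pi/6), normalized to sum 1.
#'
#' @param diameters Class diameters, any consistent length unit.
#' @param counts Non-negative counts per class (default 1 each).
#' @return Numeric vector of volume weights summing to 1.
#' @examples
#' number_to_volume_weights(c(1, 2), c(1, 1))   # c(1/9, 8/9)
#' @export
number_to_volume_weights <- function(diameters, counts = rep(1, length(diameters))) {
  stopifnot(length(diameters) == length(counts), all(diameters > 0),
            all(counts >= 0))
  v <- counts * diameters^3
  s <- sum(v)
  if (s <= 0) stop("all counts are zero")
  v / s
}

#' Fit a log-normal distribution to particle-size observations
#'
#' Maximum-likelihood fit on log-diameters (closed form: weighted mean and
#' standard deviation of `log(d)`), optionally after volume weighting
#' (`weight ~ count * d^3`), the transformation applied to TEM
#' number-weighted empirical distributions before volume-weighted fitting.
#' The log-scale parameters are converted to arithmetic mean and standard
#' deviation through the standard moment relations
#' `mean = exp(mu + sigma^2/2)`, `sd = mean * sqrt(exp(sigma^2) - 1)`.
#'
#' For an ideal log-normal sample, volume weighting shifts the median up by
#' the factor `exp(3 sigma^2)` while leaving the shape unchanged.
#'
#' @param diameters Observed equivalent diameters, m (> 0); at least 10
#'   distinct observations unless a histogram is supplied.
#' @param counts Optional histogram counts (same length as `diameters`).
#' @param weighting `"number"` or `"volume"`.
#' @return Object of class `"lognormal_fit"`: list with `meanlog`, `sdlog`
#'   (log-scale MLE), `median`, `d_mean`, `d_sd` (arithmetic scale, m),
#'   `weighting` and `n` (total observation weight).
#' @examples
#' d <- sample_diameters(500, median = 9e-9, shape = 0.25, seed = 1)
#' fit_lognormal(d)
#' @export
fit_lognormal <- function(diameters, counts = NULL,
                          weighting = c("number", "volume")) {
  weighting <- match.arg(weighting)
  if (any(diameters <= 0)) stop("diameters must be > 0")
  if (is.null(counts)) counts <- rep(1, length(diameters))
  stopifnot(length(counts) == length(diameters), all(counts >= 0))
  if (sum(counts) < 10) stop("need at least 10 observations")
  w <- if (weighting == "volume") counts * diameters^3 else counts
  w <- w / sum(w)
  x <- log(diameters)
  mu <- sum(w * x)
  sigma <- sqrt(sum(w * (x - mu)^2))   # MLE (no Bessel correction)
  m <- exp(mu + sigma^2 / 2)
  structure(list(meanlog = mu, sdlog = sigma, median = exp(mu),
                 d_mean = m, d_sd = m * sqrt(expm1(sigma^2)),
                 weighting = weighting, n = sum(counts)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Log-normal size fit (%s-weighted, n = %g):\n", x$weighting, x$n))
  cat(sprintf("  median %.4g nm, shape sigma %.4g\n", x$median * 1e9, x$sdlog))
  cat(sprintf("  arithmetic mean %.4g nm, sd %.4g nm\n",
              x$d_mean * 1e9, x$d_sd * 1e9))
  invisible(x)
}

#' @export
coef.lognormal_fit <- function(object, ...) {
  c(meanlog = object$meanlog, sdlog = object$sdlog)
}

#' Per-group volume fractions from relative group volumes
#'
#' Scales a vector of relative per-group volumes so the groups partition the
#' total volume fraction of the suspension:
#' `phi_d[i] = V_actual[i] * phi / sum(V_actual)`. The output sums to `phi`
#' exactly (up to floating point), for any positive rescaling of the input.
#'
#' @param V_actual Non-negative relative volumes per size group.
#' @param phi Total volume fraction of magnetic material.
#' @return Numeric vector of per-group volume fractions summing to `phi`.
#' @examples
#' group_volume_fractions(rep(1, 12), 0.1057)
#' @export
group_volume_fractions <- function(V_actual, phi) {
  stopifnot(all(V_actual >= 0), phi > 0, phi < 1)
  s <- sum(V_actual)
  if (s <= 0) stop("V_actual must have a positive sum")
  V_actual * (phi / s)
}

#' Arithmetic grid of size-group diameters
#'
#' @param d_min,d_max Grid endpoints, inclusive (m).
#' @param step Grid step (m, > 0).
#' @return Strictly increasing diameter grid; `(3.5, 14.5, 1)` nm gives
#'   exactly twelve groups.
#' @examples
#' make_group_grid(3.5e-9, 14.5e-9, 1e-9)
#' @export
make_group_grid <- function(d_min, d_max, step) {
  stopifnot(step > 0)
  if (d_min > d_max) stop("d_min must be <= d_max: empty grid")
  n <- floor((d_max - d_min) / step + 1e-9)
  d_min + step * (0:n)
}

#' Assign raw diameters to the nearest grid point
#'
#' Nearest-grid-point binning with ties (exact midpoints) resolved to the
#' lower bin. Observations beyond the outer midpoints are clamped to the end
#' bins.
#'
#' @param diameters Observed diameters, m.
#' @param d_grid Strictly increasing group grid, m.
#' @return Integer bin index per observation.
#' @export
bin_to_grid <- function(diameters, d_grid) {
  stopifnot(length(d_grid) >= 1, !is.unsorted(d_grid, strictly = TRUE) || length(d_grid) == 1)
  if (length(d_grid) == 1L) return(rep(1L, length(diameters)))
  mids <- (d_grid[-1] + d_grid[-length(d_grid)]) / 2
  findInterval(diameters, mids, left.open = TRUE) + 1L
}

#' Empirical relative group volumes from a diameter sample
#'
#' Bins observations onto the group grid and accumulates per-particle volume
#' (`~ d^3`) in each bin, the empirical analogue of the actual-volume vector
#' that feeds [group_volume_fractions()].
#'
#' @inheritParams bin_to_grid
#' @param counts Optional per-observation counts.
#' @return Numeric vector of relative volumes, one per grid point.
#' @export
empirical_group_volumes <- function(diameters, d_grid,
                                    counts = rep(1, length(diameters))) {
  idx <- bin_to_grid(diameters, d_grid)
  v <- counts * diameters^3
  as.numeric(tapply(v, factor(idx, levels = seq_along(d_grid)), sum,
                    default = 0))
}
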