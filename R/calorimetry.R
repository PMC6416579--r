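#' Calorimetric heating curve
#'
#' Container for a temperature-time record of a magnetic-fluid sample after
#' field switch-on, together with the thermal properties needed by the
#' initial-slope SAR estimator.
#'
#' @param t Sample times, s; strictly increasing, at least 3 samples.
#' @param T Temperatures, degrees Celsius.
#' @param c Specific heat capacity of the sample, J/(kg K).
#' @param rho Density of the sample, kg/m^3.
#' @param m_Fe Mass of magnetic nanoparticles per unit volume of fluid, kg/m^3.
#' @param t0 Optional switch-on time, s: samples before `t0` are dropped and
#'   the time axis re-zeroed.
#' @return List of class `"heating_curve"`.
#' @export
heating_curve <- function(t, T, c, rho, m_Fe, t0 = NULL) {
  stopifnot(length(t) == length(T))
  if (!is.null(t0)) { keep <- t >= t0; t <- t[keep] - t0; T <- T[keep] }
  if (length(t) < 3) stop("need at least 3 samples")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (c <= 0 || rho <= 0 || m_Fe <= 0) stop("c, rho and m_Fe must be > 0")
  structure(list(t = t, T = T, c = c, rho = rho, m_Fe = m_Fe),
            class = "heating_curve")
}

#' Maximum initial slope of a heating curve
#'
#' The SAR-relevant temperature derivative is the maximal dT/dt, which occurs
#' within the first seconds after field switch-on. Pointwise finite
#' differences amplify probe noise, so the default estimator slides a
#' least-squares linear fit of fixed duration over the initial search horizon
#' and takes the steepest window; `method = "pointwise"` gives the raw
#' finite-difference maximum for comparison.
#'
#' @param curve A [heating_curve()].
#' @param window_seconds Duration of the sliding fit window, s (default 5).
#' @param search_horizon_seconds Portion of the curve searched, s (default 30).
#' @param method `"window"` (least-squares, default) or `"pointwise"`.
#' @return Object of class `"slope_estimate"`: list with `dTdt_max` (K/s),
#'   `window` (index range of the winning window) and `r_squared` of the
#'   winning fit (`NA` for pointwise).
#' @export
max_initial_slope <- function(curve, window_seconds = 5,
                              search_horizon_seconds = 30,
                              method = c("window", "pointwise")) {
  stopifnot(inherits(curve, "heating_curve"))
  method <- match.arg(method)
  t <- curve$t - curve$t[1]
  y <- curve$T
  horizon <- min(search_horizon_seconds, max(t))
  if (method == "pointwise") {
    keep <- which(t <= horizon)
    if (length(keep) < 2) stop("search horizon contains fewer than 2 samples")
    sl <- diff(y[keep]) / diff(t[keep])
    i <- which.max(sl)
    return(structure(list(dTdt_max = sl[i], window = c(keep[i], keep[i + 1]),
                          r_squared = NA_real_), class = "slope_estimate"))
  }
  if (horizon < window_seconds)
    stop("search horizon (", horizon, " s) is shorter than the fit window (",
         window_seconds, " s)")
  best <- -Inf; best_win <- c(NA_integer_, NA_integer_); best_r2 <- NA_real_
  starts <- which(t + window_seconds <= horizon + 1e-12)
  for (i in starts) {
    j <- max(which(t <= t[i] + window_seconds + 1e-12))
    if (j - i < 1) next
    tt <- t[i:j]; yy <- y[i:j]
    tc <- tt - mean(tt); yc <- yy - mean(yy)
    sxx <- sum(tc^2)
    slope <- sum(tc * yc) / sxx
    if (slope > best) {
      best <- slope
      best_win <- c(i, j)
      syy <- sum(yc^2)
      best_r2 <- if (syy > 0) sum(tc * yc)^2 / (sxx * syy) else 1
    }
  }
  if (!is.finite(best)) stop("no complete fit window inside the horizon")
  structure(list(dTdt_max = best, window = best_win, r_squared = best_r2),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("Max initial slope: %.5g K/s (samples %d-%d, R^2 = %.4f)\n",
              x$dTdt_max, x$window[1], x$window[2],
              ifelse(is.na(x$r_squared), NaN, x$r_squared)))
  invisible(x)
}

#' Calorimetric SAR from the initial slope
#'
#' The initial-slope estimator `SAR = c rho (dT/dt)_max / m_Fe`: immediately
#' after switch-on all absorbed power goes into sensible heat of the sample,
#' so the maximal temperature derivative, scaled by the volumetric heat
#' capacity and normalized per mass of magnetic material, gives the SAR.
#'
#' @param curve A [heating_curve()].
#' @param slope A [max_initial_slope()] estimate for this curve; computed
#'   with default settings if missing.
#' @return SAR in W per kg of magnetic material.
#' @examples
#' cv <- generate_heating_curve(sar_true = 180, c = 2000, rho = 900,
#'                              m_Fe = 500, tau_c = 300, noise_sigma = 0,
#'                              seed = 1)
#' sar_from_curve(cv)
#' @export
sar_from_curve <- function(curve, slope = max_initial_slope(curve)) {
  stopifnot(inherits(curve, "heating_curve"),
            inherits(slope, "slope_estimate"))
  curve$c * curve$rho * slope$dTdt_max / curve$m_Fe
}

#' Compare modelled and measured SAR sweeps
#'
#' Joins two sweep tables on the field conditions `(H_kA_per_m, f_kHz, mode)`
#' and reports the per-point percent deviation
#' `(model - measured) / measured * 100` together with its maximum magnitude
#' and mean.
#'
#' @param model_table,measured_table `data.frame`s with columns
#'   `H_kA_per_m`, `f_kHz`, `mode` and `SAR_W_per_g`.
#' @return List of class `"sar_comparison"`: `table` (joined, with
#'   `dev_percent`), `max_abs_dev`, `mean_dev`.
#' @export
compare_model_measurement <- function(model_table, measured_table) {
  need <- c("H_kA_per_m", "f_kHz", "mode", "SAR_W_per_g")
  for (nm in list(model_table, measured_table))
    if (!all(need %in% names(nm)))
      stop("sweep tables need columns: ", paste(need, collapse = ", "))
  key <- function(d) paste(d$H_kA_per_m, d$f_kHz, d$mode, sep = "|")
  km <- key(model_table); kx <- key(measured_table)
  missing_pts <- setdiff(km, kx)
  if (length(missing_pts) || length(setdiff(kx, km)))
    stop("field-condition keys do not match; unmatched: ",
         paste(union(missing_pts, setdiff(kx, km)), collapse = "; "))
  i <- match(km, kx)
  tab <- model_table[, c("H_kA_per_m", "f_kHz", "mode")]
  tab$SAR_model <- model_table$SAR_W_per_g
  tab$SAR_measured <- measured_table$SAR_W_per_g[i]
  tab$dev_percent <- (tab$SAR_model - tab$SAR_measured) / tab$SAR_measured * 100
  structure(list(table = tab, max_abs_dev = max(abs(tab$dev_percent)),
                 mean_dev = mean(tab$dev_percent)),
            class = "sar_comparison")
}

#' @export
print.sar_comparison <- function(x, ...) {
  cat(sprintf("Model vs measurement over %d field points: max |dev| %.2f%%, mean dev %+.2f%%\n",
              nrow(x$table), x$max_abs_dev, x$mean_dev))
  print(x$table, row.names = FALSE)
  invisible(x)
}
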