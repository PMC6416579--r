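#' Langevin function
#'
#' `L(alpha) = coth(alpha) - 1/alpha`, the equilibrium magnetization of an
#' ensemble of thermally agitated moments. Evaluated by its Taylor series
#' `alpha/3 - alpha^3/45` below `alpha = 1e-4`, where the coth form loses
#' precision to cancellation; the two branches agree to relative error
#' < 1e-12 at the switch point.
#'
#' @param alpha Langevin parameter(s), dimensionless, `>= 0`.
#' @return Values in `[0, 1)`.
#' @examples
#' langevin(c(0, 1, 10))
#' @export
langevin <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  small <- alpha < 1e-4
  out <- numeric(length(alpha))
  out[small] <- alpha[small] / 3 - alpha[small]^3 / 45
  a <- alpha[!small]
  out[!small] <- 1 / tanh(a) - 1 / a
  out
}

#' Langevin parameter
#'
#' Ratio of magnetic to thermal energy for a single-domain particle,
#' `alpha = mu0 V_p M_d H / (k_B T)`. Linear in the field amplitude `H`.
#'
#' @param V_p Core volume, m^3.
#' @param M_d Bulk saturation magnetization, A/m.
#' @param H Field amplitude, A/m (`>= 0`).
#' @param T Absolute temperature, K.
#' @return Dimensionless Langevin parameter.
#' @examples
#' langevin_alpha(pi / 6 * (7.5e-9)^3, 4e5, 4.3e3, 293)
#' @export
langevin_alpha <- function(V_p, M_d, H, T) {
  stopifnot(all(V_p > 0), M_d > 0, all(H >= 0), T > 0)
  .mu0 * V_p * M_d * H / (.kB * T)
}

#' Chord susceptibility at field amplitude H
#'
#' The linearized (chord) susceptibility used by the Debye response:
#' `chi = (phi_d M_d / H) * L(alpha)`, evaluated at the amplitude of the
#' field component. Bounded above by `phi_d M_d / H` (full saturation).
#' At `H = 0` the expression is 0/0; the analytic small-field limit
#' `chi_0 = phi_d mu0 V_p M_d^2 / (3 k_B T)` is returned instead, which
#' requires `V_p` and `T` to be supplied.
#'
#' @param phi_d Volume fraction of the size class, dimensionless.
#' @param M_d Bulk saturation magnetization, A/m.
#' @param H Field amplitude, A/m.
#' @param alpha Langevin parameter for this class at `H` (see
#'   [langevin_alpha()]). Ignored when `H = 0`.
#' @param V_p,T Core volume (m^3) and temperature (K); only needed for the
#'   `H = 0` initial-susceptibility limit.
#' @return Dimensionless chord susceptibility.
#' @examples
#' a <- langevin_alpha(pi / 6 * (7.5e-9)^3, 4e5, 4.3e3, 293)
#' chord_susceptibility(0.01611, 4e5, 4.3e3, a)
#' @export
chord_susceptibility <- function(phi_d, M_d, H, alpha, V_p = NULL, T = NULL) {
  stopifnot(all(phi_d >= 0), M_d > 0, all(H >= 0))
  if (any(H == 0)) {
    if (is.null(V_p) || is.null(T))
      stop("H = 0 requires V_p and T for the initial-susceptibility limit")
    chi0 <- phi_d * .mu0 * V_p * M_d^2 / (3 * .kB * T)
    if (all(H == 0)) return(chi0 + 0 * phi_d)
    return(ifelse(H == 0, chi0, phi_d * M_d / pmax(H, .Machine$double.xmin) *
                    langevin(alpha)))
  }
  phi_d * M_d / H * langevin(alpha)
}

#' Complex magnetization phasor (Debye response)
#'
#' First-order response of the magnetization to a sinusoidal field phasor:
#' `M = chi h / (1 + i omega tau)`. The modulus never exceeds `chi |h|`
#' and the phase lag lies in `(-pi/2, 0]`.
#'
#' @param chi Chord susceptibility, dimensionless.
#' @param h Complex field phasor, A/m.
#' @param omega Angular frequency, rad/s.
#' @param tau Effective relaxation time, s (`> 0`).
#' @return Complex magnetization phasor, A/m.
#' @examples
#' complex_magnetization(0.1, 4.3e3 + 0i, 2 * pi * 395e3, 1e-6)
#' @export
complex_magnetization <- function(chi, h, omega, tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  chi * h / (1 + 1i * omega * tau)
}

#' Per-size-class susceptibility response to a field excitation
#'
#' Computes, for every size class, the per-axis Langevin parameters and chord
#' susceptibilities for the given excitation. In rotating mode each axis uses
#' its own amplitude; in alternating mode only the x axis is active.
#'
#' @param group A [particle_group()] (phi_d per class set).
#' @param material A [material_spec()].
#' @param field A [field_excitation()].
#' @param cond An [operating_conditions()].
#' @return `data.frame` of class `"susceptibility_response"` with columns
#'   `d_core`, `alpha_x`, `alpha_y`, `chi_x`, `chi_y`.
#' @export
susceptibility_response <- function(group, material, field, cond) {
  stopifnot(inherits(group, "particle_group"),
            inherits(material, "material_spec"),
            inherits(field, "field_excitation"),
            inherits(cond, "operating_conditions"))
  ax <- langevin_alpha(group$V_p, material$M_d, field$H_x, cond$T)
  ay <- langevin_alpha(group$V_p, material$M_d, field$H_y, cond$T)
  cx <- chord_susceptibility(group$phi_d, material$M_d, field$H_x, ax,
                             V_p = group$V_p, T = cond$T)
  cy <- chord_susceptibility(group$phi_d, material$M_d, field$H_y, ay,
                             V_p = group$V_p, T = cond$T)
  out <- data.frame(d_core = group$d_core, alpha_x = ax, alpha_y = ay,
                    chi_x = cx, chi_y = cy)
  class(out) <- c("susceptibility_response", "data.frame")
  out
}

#' Time-averaged volumetric heating power
#'
#' Evaluates the loss power of the suspension through the complex phasor
#' expression `P = (mu0/2) Re(sum_i i omega (M_xi h_x* + M_yi h_y*))`, with
#' `h_x = H_x` and `h_y = i H_y` (quadrature for a rotating field) and the
#' per-class Debye magnetization `M = chi h / (1 + i omega tau)`. The total
#' is the sum over size classes.
#'
#' A warning (not an error) is issued when the inputs leave the validity
#' envelope of linear response theory: core diameters above 20 nm or field
#' inductions `mu0 H` above 10 mT.
#'
#' @param responses A [susceptibility_response()] table (one row per class).
#' @param field The [field_excitation()] the responses were computed for.
#' @param taus Effective relaxation times per class, s.
#' @return List of class `"power_result"` with elements `P` (W/m^3),
#'   `per_group` (W/m^3 per class) and the `field` used.
#' @examples
#' g <- particle_group(10e-9, phi_d = 0.1057)
#' m <- material_spec(4e5, phi = 0.1057)
#' fld <- field_excitation(4.3e3, f = 395e3)
#' cnd <- operating_conditions(293, 0.075)
#' r <- susceptibility_response(g, m, fld, cnd)
#' tau <- effective_time(neel_time(g, cnd), brownian_time(g, cnd))
#' volumetric_power(r, fld, tau)
#' @export
volumetric_power <- function(responses, field, taus) {
  stopifnot(inherits(responses, "susceptibility_response"),
            inherits(field, "field_excitation"))
  if (nrow(responses) == 0L) stop("empty group set")
  if (length(taus) != nrow(responses))
    stop("length(taus) must match the number of size classes (",
         nrow(responses), ")")
  .lrt_guard(responses$d_core, max(field$H_x, field$H_y))
  w <- field$omega
  hx <- complex(real = field$H_x)       # x component: real phasor
  hy <- 1i * field$H_y                  # y component: quadrature
  Mx <- complex_magnetization(responses$chi_x, hx, w, taus)
  My <- complex_magnetization(responses$chi_y, hy, w, taus)
  per <- .mu0 / 2 * Re(1i * w * (Mx * Conj(hx) + My * Conj(hy)))
  structure(list(P = sum(per), per_group = per, field = field),
            class = "power_result")
}

.lrt_guard <- function(d_core, H) {
  if (any(d_core > 20e-9))
    warning("core diameter(s) above 20 nm: outside the linear-response ",
            "validity envelope", call. = FALSE)
  if (.mu0 * H > 10e-3)
    warning("field induction mu0*H above 10 mT: outside the linear-response ",
            "validity envelope", call. = FALSE)
  invisible(NULL)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Volumetric heating power: %.6g W/m^3 (%d size class(es), %s field, f = %g kHz)\n",
              x$P, length(x$per_group), x$field$mode, x$field$f / 1e3))
  invisible(x)
}

#' Specific absorption rate from volumetric power
#'
#' Normalizes the volumetric loss power to the mass of magnetic material.
#' The default convention divides `P` (per m^3 of fluid) by `phi * rho_m`,
#' the mass of magnetic nanoparticles per m^3 of fluid — the normalization
#' the calorimetric estimator uses, so model and measurement are
#' commensurable. `convention = "literal-eq7"` divides by `rho_m` alone.
#'
#' @param power A [volumetric_power()] result, or a plain numeric P in W/m^3.
#' @param material A [material_spec()].
#' @param convention `"per-magnetic-mass"` (default) or `"literal-eq7"`.
#' @return SAR in W per kg of magnetic material.
#' @examples
#' sar(1e6, material_spec(4e5, phi = 0.1057))
#' @export
sar <- function(power, material,
                convention = c("per-magnetic-mass", "literal-eq7")) {
  convention <- match.arg(convention)
  stopifnot(inherits(material, "material_spec"))
  P <- if (inherits(power, "power_result")) power$P else power
  if (convention == "per-magnetic-mass") P / (material$phi * material$rho_m)
  else P / material$rho_m
}

#' SAR sweep over a field grid
#'
#' Evaluates the polydisperse loss model on the Cartesian grid of field
#' amplitudes and frequencies and reports power and SAR per grid point.
#' Within the linear-response envelope SAR is non-decreasing in both `H`
#' and `f` for fixed relaxation times.
#'
#' @param group A [particle_group()] with per-class `phi_d`.
#' @param material A [material_spec()].
#' @param cond An [operating_conditions()].
#' @param H Vector of per-axis field amplitudes, A/m.
#' @param f Vector of frequencies, Hz.
#' @param mode `"alternating"` or `"rotating"` (rotating uses `H` on both axes).
#' @param convention SAR unit convention, see [sar()].
#' @return `data.frame` with columns `H_kA_per_m`, `f_kHz`, `mode`,
#'   `P_W_per_m3`, `SAR_W_per_g`.
#' @export
sar_sweep <- function(group, material, cond, H, f,
                      mode = c("alternating", "rotating"),
                      convention = c("per-magnetic-mass", "literal-eq7")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  grid <- expand.grid(H = H, f = f, KEEP.OUT.ATTRS = FALSE)
  tn <- neel_time(group, cond)
  tb <- brownian_time(group, cond)
  tau <- effective_time(tn, tb)
  P <- vapply(seq_len(nrow(grid)), function(i) {
    fld <- field_excitation(grid$H[i], f = grid$f[i], mode = mode)
    resp <- susceptibility_response(group, material, fld, cond)
    volumetric_power(resp, fld, tau)$P
  }, numeric(1))
  data.frame(H_kA_per_m = grid$H / 1e3, f_kHz = grid$f / 1e3, mode = mode,
             P_W_per_m3 = P,
             SAR_W_per_g = sar(P, material, convention) / 1e3)
}
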