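#' Define one or more particle size classes
#'
#' Builds the per-size-class description consumed by the relaxation and power
#' calculations. All arguments are recycled to the length of `d_core`, so a
#' single call describes a whole polydisperse group set. Core and hydrodynamic
#' volumes are derived assuming spherical particles:
#' `V_p = pi/6 d^3` and `V_h = pi/6 (d + 2 delta)^3`.
#'
#' @param d_core Magnetic core diameter(s), m. Must be positive.
#' @param phi_d Volume fraction of each size class in the suspension
#'   (dimensionless, in `[0, 1]`). Defaults to 0 (geometry-only group).
#' @param delta Surfactant (capping-agent) layer thickness, m. Fatty-acid
#'   surfactants on non-polar carriers are about 1 nm long, hence the default.
#' @param K_a Magnetic anisotropy constant, J/m^3. Default 4.7e4 J/m^3, the
#'   standard effective anisotropy for maghemite nanoparticles; see the
#'   methods vignette for why this calibration knob matters.
#' @param tau0 Attempt time of the Neel process, s. Default 1e-9 s.
#'
#' @return A `data.frame` of class `"particle_group"` with columns `d_core`,
#'   `delta`, `K_a`, `tau0`, `phi_d` and the derived volumes `V_p`, `V_h` (m^3).
#' @examples
#' particle_group(make_group_grid(3.5e-9, 14.5e-9, 1e-9))
#' @export
particle_group <- function(d_core, phi_d = 0, delta = 1e-9, K_a = 4.7e4,
                           tau0 = 1e-9) {
  stopifnot(is.numeric(d_core), length(d_core) >= 1L)
  g <- data.frame(d_core = d_core, delta = delta, K_a = K_a, tau0 = tau0,
                  phi_d = phi_d)
  if (any(g$d_core <= 0)) stop("d_core must be > 0")
  if (any(g$delta < 0)) stop("delta must be >= 0")
  if (any(g$K_a < 0)) stop("K_a must be >= 0")
  if (any(g$tau0 <= 0)) stop("tau0 must be > 0")
  if (any(g$phi_d < 0 | g$phi_d > 1)) stop("phi_d must lie in [0, 1]")
  g$V_p <- pi / 6 * g$d_core^3
  g$V_h <- pi / 6 * (g$d_core + 2 * g$delta)^3
  class(g) <- c("particle_group", "data.frame")
  g
}

#' Operating conditions of the suspension
#'
#' @param T Absolute temperature, K.
#' @param eta Dynamic viscosity of the carrier fluid at `T`, Pa s.
#' @return List of class `"operating_conditions"`.
#' @examples
#' operating_conditions(T = 293, eta = 0.075)
#' @export
operating_conditions <- function(T, eta) {
  if (!is.numeric(T) || T <= 0) stop("T must be a positive temperature in K")
  if (!is.numeric(eta) || eta <= 0) stop("eta must be a positive viscosity in Pa s")
  structure(list(T = T, eta = eta), class = "operating_conditions")
}

#' Magnetic material of the suspended nanoparticles
#'
#' Exactly one of `phi` (total volume fraction) or `M_s_fluid` (fluid
#' saturation magnetization) must be given; in the latter case the volume
#' fraction is resolved as `M_s_fluid / M_d` (see [total_volume_fraction()]).
#'
#' @param M_d Bulk (domain) saturation magnetization, A/m.
#' @param rho_m Mass density of the magnetic material, kg/m^3. Default
#'   4860 kg/m^3 (maghemite).
#' @param phi Total volume fraction of magnetic nanoparticles (0, 1).
#' @param M_s_fluid Saturation magnetization of the fluid, A/m.
#' @return List of class `"material_spec"` with fields `M_d`, `rho_m`, `phi`.
#' @examples
#' material_spec(M_d = 4e5, M_s_fluid = 42.3e3)
#' @export
material_spec <- function(M_d, rho_m = 4860, phi = NULL, M_s_fluid = NULL) {
  if (!is.numeric(M_d) || M_d <= 0) stop("M_d must be > 0")
  if (!is.numeric(rho_m) || rho_m <= 0) stop("rho_m must be > 0")
  if (is.null(phi) == is.null(M_s_fluid))
    stop("give exactly one of 'phi' or 'M_s_fluid'")
  if (!is.null(M_s_fluid)) phi <- total_volume_fraction(M_s_fluid, M_d)
  if (phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  structure(list(M_d = M_d, rho_m = rho_m, phi = phi), class = "material_spec")
}

#' Alternating or rotating field excitation
#'
#' An alternating field has a single linearly polarised component along x; a
#' rotating field has two orthogonal components in phase quadrature
#' (`h_x = H_x`, `h_y = i H_y` as complex phasors).
#'
#' @param H_x Amplitude of the x component, A/m.
#' @param H_y Amplitude of the y component, A/m; must be 0 in alternating
#'   mode. Defaults to `H_x` in rotating mode and 0 in alternating mode.
#' @param f Frequency, Hz.
#' @param mode `"alternating"` or `"rotating"`.
#' @return List of class `"field_excitation"` with `H_x`, `H_y`, `f`, `mode`
#'   and the derived angular frequency `omega`.
#' @examples
#' field_excitation(H_x = 4.3e3, f = 395e3)
#' field_excitation(H_x = 2e3, f = 402e3, mode = "rotating")
#' @export
field_excitation <- function(H_x, H_y = NULL, f,
                             mode = c("alternating", "rotating")) {
  mode <- match.arg(mode)
  if (is.null(H_y)) H_y <- if (mode == "rotating") H_x else 0
  if (!is.numeric(H_x) || H_x < 0 || !is.numeric(H_y) || H_y < 0)
    stop("field amplitudes must be >= 0")
  if (!is.numeric(f) || f <= 0) stop("f must be > 0")
  if (mode == "alternating" && H_y != 0)
    stop("alternating mode requires H_y = 0")
  structure(list(H_x = H_x, H_y = H_y, f = f, mode = mode, omega = 2 * pi * f),
            class = "field_excitation")
}

#' @export
print.particle_group <- function(x, ...) {
  cat(sprintf("Particle size classes: %d group(s), d = %.3g-%.3g nm, sum(phi_d) = %.4g%%\n",
              nrow(x), min(x$d_core) * 1e9, max(x$d_core) * 1e9,
              sum(x$phi_d) * 100))
  print.data.frame(x, ...)
  invisible(x)
}
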