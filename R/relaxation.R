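#' Neel relaxation time
#'
#' Internal moment-flip relaxation over the anisotropy energy barrier,
#' `tau_N = tau0 * exp(K_a V_p / (k_B T))`. Dominates small cores, where the
#' barrier `K_a V_p` is comparable to the thermal energy.
#'
#' When the exponent exceeds ~700 (where `exp()` would overflow double
#' precision) the result saturates to `Inf`: a particle whose moment is
#' thermally blocked simply does not relax through the Neel channel, and the
#' effective time degrades gracefully to the Brownian channel.
#'
#' @param group A [particle_group()].
#' @param cond An [operating_conditions()].
#' @return Numeric vector of relaxation times, s (one per size class).
#' @seealso [brownian_time()], [effective_time()], [crossover_diameter()]
#' @examples
#' g <- particle_group(10e-9, K_a = 1e4)
#' neel_time(g, operating_conditions(293, 0.075))
#' @export
neel_time <- function(group, cond) {
  stopifnot(inherits(group, "particle_group"),
            inherits(cond, "operating_conditions"))
  ex <- group$K_a * group$V_p / (.kB * cond$T)
  out <- ifelse(ex > 700, Inf, group$tau0 * exp(ex))
  as.numeric(out)
}

#' Brownian relaxation time
#'
#' Whole-particle rotational relaxation in the viscous carrier,
#' `tau_B = 3 V_h eta / (k_B T)`, with `V_h` the hydrodynamic volume
#' including the surfactant shell. Dominates large hydrodynamic volumes and
#' scales linearly with carrier viscosity.
#'
#' @inheritParams neel_time
#' @return Numeric vector of relaxation times, s.
#' @examples
#' g <- particle_group(10e-9, delta = 1e-9)
#' brownian_time(g, operating_conditions(293, 0.1))
#' @export
brownian_time <- function(group, cond) {
  stopifnot(inherits(group, "particle_group"),
            inherits(cond, "operating_conditions"))
  3 * group$V_h * cond$eta / (.kB * cond$T)
}

#' Effective relaxation time
#'
#' Parallel (harmonic) combination of the Neel and Brownian channels,
#' `tau = (tau_N^-1 + tau_B^-1)^-1`; the faster mechanism dominates, and the
#' result never exceeds either input. `Inf` inputs are allowed (one channel
#' closed); both infinite is an error, since such a system does not relax.
#'
#' @param tau_N Neel time(s), s; positive, `Inf` allowed.
#' @param tau_B Brownian time(s), s; positive, `Inf` allowed.
#' @return Numeric vector of effective times, s.
#' @examples
#' effective_time(2, 2)        # 1
#' effective_time(Inf, 1e-5)   # 1e-5
#' @export
effective_time <- function(tau_N, tau_B) {
  if (any(tau_N <= 0) || any(tau_B <= 0))
    stop("relaxation times must be positive")
  if (any(is.infinite(tau_N) & is.infinite(tau_B)))
    stop("both relaxation channels are blocked: system does not relax")
  1 / (1 / tau_N + 1 / tau_B)
}

#' Neel/Brownian crossover diameter
#'
#' Finds the core diameter at which the two relaxation channels are equally
#' fast (`tau_N = tau_B`) by a bracketed root search on
#' `log(tau_N) - log(tau_B)`, which stays finite even where `exp()` in the
#' Neel time would overflow. Below the crossover the Neel mechanism prevails;
#' above it, Brownian rotation.
#'
#' @param K_a Anisotropy constant, J/m^3.
#' @param tau0 Attempt time, s.
#' @param delta Surfactant thickness, m.
#' @param cond An [operating_conditions()].
#' @param interval Search bracket on core diameter, m. Default 1-100 nm.
#' @return Crossover core diameter, m (relative tolerance 1e-10).
#' @examples
#' crossover_diameter(4.7e4, 1e-9, 1e-9, operating_conditions(293, 0.075))
#' @export
crossover_diameter <- function(K_a, tau0, delta, cond,
                               interval = c(1e-9, 100e-9)) {
  stopifnot(K_a > 0, tau0 > 0, delta >= 0,
            inherits(cond, "operating_conditions"))
  # log tau_N - log tau_B, analytic so the Neel exponent never overflows
  g <- function(d) {
    Vp <- pi / 6 * d^3
    Vh <- pi / 6 * (d + 2 * delta)^3
    (log(tau0) + K_a * Vp / (.kB * cond$T)) -
      log(3 * Vh * cond$eta / (.kB * cond$T))
  }
  lo <- g(interval[1]); hi <- g(interval[2])
  if (sign(lo) == sign(hi))
    stop("no Neel/Brownian crossover in the search range [",
         interval[1] * 1e9, ", ", interval[2] * 1e9, "] nm")
  r <- stats::uniroot(g, interval, tol = 1e-10 * interval[1])
  r$root
}

#' Relaxation-time table over a diameter grid
#'
#' Convenience tabulation of Neel, Brownian and effective times, as emitted by
#' the `relax` command-line subcommand.
#'
#' @param d_grid Core diameters, m.
#' @param cond An [operating_conditions()].
#' @param delta,K_a,tau0 Particle parameters, see [particle_group()].
#' @return `data.frame` with columns `d_nm`, `T_K`, `tau_N_s`, `tau_B_s`, `tau_s`.
#' @export
relaxation_table <- function(d_grid, cond, delta = 1e-9, K_a = 4.7e4,
                             tau0 = 1e-9) {
  g <- particle_group(d_grid, delta = delta, K_a = K_a, tau0 = tau0)
  tn <- neel_time(g, cond)
  tb <- brownian_time(g, cond)
  data.frame(d_nm = d_grid * 1e9, T_K = cond$T, tau_N_s = tn, tau_B_s = tb,
             tau_s = effective_time(tn, tb))
}
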