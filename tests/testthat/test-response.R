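test_that("Langevin function matches high-precision values and stays in [0, 1)", {
  expect_identical(langevin(0), 0)
  expect_equal(langevin(1), 1 / tanh(1) - 1, tolerance = 1e-12)
  expect_equal(langevin(1), 0.3130353, tolerance = 1e-6)
  expect_lt(abs(langevin(1e6) - 1), 1e-5)
  expect_error(langevin(-0.1), "alpha")

  # around the branch switch the two forms agree; below it the naive coth
  # form loses digits to cancellation, so the oracle there is the series with
  # one extra term (truncation error ~ alpha^7)
  above <- c(1e-4, 1.01e-4, 1.1e-4)
  expect_equal(langevin(above), 1 / tanh(above) - 1 / above,
               tolerance = 1e-12)
  below <- c(1e-6, 1e-5, 0.99e-4)
  series5 <- below / 3 - below^3 / 45 + 2 * below^5 / 945
  expect_equal(langevin(below), series5, tolerance = 1e-12)

  set.seed(3)
  x <- 10^runif(100, -8, 3)
  L <- langevin(x)
  expect_true(all(L >= 0 & L < 1))
  expect_true(all(diff(langevin(sort(x))) > 0))  # monotone
})

test_that("Langevin parameter is the magnetic-to-thermal energy ratio", {
  Vp <- pi / 6 * (7.5e-9)^3
  expect_identical(langevin_alpha(Vp, 4e5, 0, 293), 0)
  expect_equal(langevin_alpha(Vp, 4e5, 4.3e3, 293), 0.1181, tolerance = 1e-3)
  expect_equal(langevin_alpha(Vp, 4e5, 8.6e3, 293),
               2 * langevin_alpha(Vp, 4e5, 4.3e3, 293))
})

test_that("chord susceptibility interpolates between initial and saturation limits", {
  Vp <- pi / 6 * (7.5e-9)^3
  a <- langevin_alpha(Vp, 4e5, 4.3e3, 293)
  expect_equal(chord_susceptibility(0.01611, 4e5, 4.3e3, a), 0.0589,
               tolerance = 1e-3)

  # saturation: L -> 1, chi -> phi_d M_d / H
  expect_equal(chord_susceptibility(0.01611, 4e5, 4.3e3, 1e8),
               0.01611 * 4e5 / 4.3e3, tolerance = 1e-6)

  # H = 0 dispatches to the analytic initial susceptibility, the H -> 0 limit
  chi0 <- chord_susceptibility(0.01611, 4e5, 0, 0, V_p = Vp, T = 293)
  Hs <- 10^seq(1, -3, by = -1)
  lim <- sapply(Hs, function(H)
    chord_susceptibility(0.01611, 4e5, H, langevin_alpha(Vp, 4e5, H, 293)))
  expect_equal(lim[length(lim)], chi0, tolerance = 1e-8)
  expect_error(chord_susceptibility(0.01611, 4e5, 0, 0), "V_p")

  # bound chi <= phi_d M_d / H for random fields
  set.seed(11)
  H <- 10^runif(50, 1, 5)
  chi <- chord_susceptibility(0.05, 4e5, H, langevin_alpha(Vp, 4e5, H, 293))
  expect_true(all(chi <= 0.05 * 4e5 / H + 1e-15))
})

test_that("complex magnetization is the Debye first-order response", {
  expect_equal(complex_magnetization(0.1, 100 + 0i, 2 * pi * 1e5, 1e-30),
               10 + 0i, tolerance = 1e-12)
  # omega tau = 1: amplitude / sqrt(2), phase -45 deg
  M <- complex_magnetization(0.1, 100 + 0i, 1e6, 1e-6)
  expect_equal(Mod(M), 10 / sqrt(2))
  expect_equal(Arg(M), -pi / 4)
  expect_error(complex_magnetization(0.1, 1 + 0i, 1, 0), "tau")
})

test_that("phasor solution matches numerically integrated Debye relaxation", {
  # steady state of tau dM/dt + M = chi H cos(w t), integrated over many
  # periods with deSolve, vs Re(M_phasor e^{i w t})
  chi <- 0.08; H <- 4.3e3; f <- 395e3; w <- 2 * pi * f; tau <- 4e-7
  Mph <- complex_magnetization(chi, H + 0i, w, tau)
  rhs <- function(t, y, p) list((chi * H * cos(w * t) - y) / tau)
  times <- seq(0, 40 / f, length.out = 8001)
  sol <- deSolve::ode(y = c(M = 0), times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-10)
  late <- sol[sol[, "time"] > 30 / f, ]
  expect_equal(unname(late[, "M"]),
               Re(Mph * exp(1i * w * late[, "time"])), tolerance = 1e-5)
})

test_that("volumetric power from complex phasors matches the closed form", {
  m <- material_spec(4e5, phi = 0.1057)
  cnd <- operating_conditions(293, 0.075)

  # single group with omega tau = 1: hand-arithmetic value
  f <- 395e3; w <- 2 * pi * f
  g <- particle_group(10e-9, phi_d = 0.1057)
  fld <- field_excitation(4.3e3, f = f)
  resp <- susceptibility_response(g, m, fld, cnd)
  resp$chi_x <- 0.1   # pin chi for the hand oracle
  pw <- volumetric_power(resp, fld, taus = 1 / w)
  expect_equal(pw$P, 1.4417e6, tolerance = 1e-4)
  expect_equal(pw$P, closed_form_power(0.1, 4.3e3, w, 1 / w), tolerance = 1e-12)

  # zero field amplitudes give zero power
  fld0 <- field_excitation(0, f = f)
  r0 <- susceptibility_response(particle_group(8e-9, phi_d = 0.01), m, fld0, cnd)
  expect_equal(volumetric_power(r0, fld0, 1e-7)$P, 0)

  # structural error on mismatched group vectors
  expect_error(volumetric_power(resp, fld, taus = c(1e-7, 1e-7)), "match")

  # oracle equivalence over 1000 random draws (alternating)
  set.seed(123)
  n <- 1000
  chi <- runif(n, 0, 0.2); H <- runif(n, 100, 7.5e3)
  w <- 2 * pi * 10^runif(n, 4, 6); tau <- 10^runif(n, -9, -3)
  P <- vapply(seq_len(n), function(k) {
    fl <- field_excitation(H[k], f = w[k] / (2 * pi))
    r <- data.frame(d_core = 10e-9, alpha_x = 1, alpha_y = 1,
                    chi_x = chi[k], chi_y = chi[k])
    class(r) <- c("susceptibility_response", "data.frame")
    volumetric_power(r, fl, tau[k])$P
  }, numeric(1))
  expect_equal(P, closed_form_power(chi, H, w, tau), tolerance = 1e-12)

  # rotating-mode equivalence: two equal axis terms
  set.seed(321)
  chi <- runif(200, 0, 0.2); H <- runif(200, 100, 7e3)
  w <- 2 * pi * 10^runif(200, 4, 6); tau <- 10^runif(200, -9, -3)
  Prot <- vapply(seq_len(200), function(k) {
    fl <- field_excitation(H[k], f = w[k] / (2 * pi), mode = "rotating")
    r <- data.frame(d_core = 10e-9, alpha_x = 1, alpha_y = 1,
                    chi_x = chi[k], chi_y = chi[k])
    class(r) <- c("susceptibility_response", "data.frame")
    volumetric_power(r, fl, tau[k])$P
  }, numeric(1))
  expect_equal(Prot, 2 * closed_form_power(chi, H, w, tau), tolerance = 1e-12)
})

test_that("power peaks at omega tau = 1 and groups add independently", {
  w <- 2 * pi * 3e5
  taus <- 10^seq(-9, -3, length.out = 601)
  P <- closed_form_power(0.1, 4e3, w, taus)
  m <- material_spec(4e5, phi = 0.1057)
  cnd <- operating_conditions(293, 0.075)
  fld <- field_excitation(4e3, f = 3e5)
  Ppkg <- vapply(taus, function(tt) {
    r <- data.frame(d_core = 1e-8, alpha_x = 1, alpha_y = 1,
                    chi_x = 0.1, chi_y = 0.1)
    class(r) <- c("susceptibility_response", "data.frame")
    volumetric_power(r, fld, tt)$P
  }, numeric(1))
  expect_equal(Ppkg, P, tolerance = 1e-12)
  expect_equal(taus[which.max(Ppkg)], 1 / w, tolerance = 0.03)

  # additivity: twelve-group power equals the sum of twelve single runs
  g <- make_group_grid(3.5e-9, 14.5e-9, 1e-9)
  v <- surrogate_group_vector(g, 7.5e-9, 0.01611, 0.1057)
  groups <- particle_group(g, phi_d = v)
  tau <- effective_time(neel_time(groups, cnd), brownian_time(groups, cnd))
  resp <- susceptibility_response(groups, m, fld, cnd)
  P12 <- volumetric_power(resp, fld, tau)
  singles <- vapply(1:12, function(i) {
    gi <- particle_group(g[i], phi_d = v[i])
    ri <- susceptibility_response(gi, m, fld, cnd)
    volumetric_power(ri, fld, tau[i])$P
  }, numeric(1))
  expect_equal(P12$P, sum(singles))
  expect_equal(P12$per_group, singles)
  expect_equal(P12$P, sum(P12$per_group))
})

test_that("SAR conventions normalize power per magnetic mass or per density", {
  m <- material_spec(4e5, phi = 0.1057, rho_m = 4860)
  expect_equal(sar(0, m), 0)
  expect_equal(sar(1e6, m) / 1e3, 1.947, tolerance = 1e-3)  # W/g
  expect_equal(sar(1e6, m, "literal-eq7"), 1e6 / 4860)
  expect_equal(sar(2e6, m), 2 * sar(1e6, m))
})

test_that("SAR sweeps behave per the linear-response scaling laws", {
  sys <- reference_system()
  one <- predict(sys, H = 3e3, f = 402e3)
  expect_equal(nrow(one), 1L)
  # single point agrees with direct power + sar composition
  s <- summary(sys, H = 3e3, f = 402e3)
  expect_equal(one$SAR_W_per_g * 1e3, attr(s, "SAR_W_per_kg"))

  alt <- predict(sys, H = c(1e3, 2e3, 3e3), f = 402e3)
  rot <- predict(sys, H = c(1e3, 2e3, 3e3), f = 402e3, mode = "rotating")
  expect_equal(rot$SAR_W_per_g, 2 * alt$SAR_W_per_g)

  # omega tau << 1 regime: doubling f quadruples SAR (within 2%)
  g1 <- particle_group(6e-9, phi_d = 0.01)   # tau ~ 4e-9 s: w tau ~ 1e-3
  mm <- material_spec(4e5, phi = 0.01)
  cnd <- operating_conditions(293, 0.075)
  s1 <- sar_sweep(g1, mm, cnd, H = 3e3, f = 50e3)
  s2 <- sar_sweep(g1, mm, cnd, H = 3e3, f = 100e3)
  expect_equal(s2$SAR_W_per_g / s1$SAR_W_per_g, 4, tolerance = 0.02)

  # monotone non-decreasing in H and f inside the validity envelope
  swH <- predict(sys, H = seq(5e2, 7e3, length.out = 10), f = 395e3)
  expect_true(all(diff(swH$SAR_W_per_g) > 0))
  swf <- predict(sys, H = 4.3e3, f = seq(1e5, 1e6, length.out = 10))
  expect_true(all(diff(swf$SAR_W_per_g) > 0))

  # SAR -> 0 with vanishing field
  tiny <- predict(sys, H = 1e-6, f = 395e3)
  expect_lt(tiny$SAR_W_per_g, 1e-12)
})

test_that("validity guard warns outside the linear-response envelope", {
  m <- material_spec(4e5, phi = 0.01)
  cnd <- operating_conditions(293, 0.075)
  gbig <- particle_group(25e-9, phi_d = 0.01)
  expect_warning(sar_sweep(gbig, m, cnd, H = 1e3, f = 1e5), "20 nm")
  gok <- particle_group(10e-9, phi_d = 0.01)
  expect_warning(sar_sweep(gok, m, cnd, H = 9e3, f = 1e5), "10 mT")
  expect_silent(sar_sweep(gok, m, cnd, H = 4.3e3, f = 395e3))
})
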