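write_config <- function(path, extra_material = "M_s_fluid: 42.3 kA/m",
                         groups = NULL, field_mode = "alternating") {
  if (is.null(groups))
    groups <- c("groups:",
                "  grid: {d_min: 3.5 nm, d_max: 14.5 nm, step: 1 nm}",
                "  distribution: {anchor_d: 7.5 nm, anchor_phi: 1.611 %}")
  writeLines(c(
    "material:",
    "  M_d: 400 kA/m",
    paste0("  ", extra_material),
    groups,
    "carrier:",
    "  viscosity_points:",
    "    T_C: [20, 40, 60]",
    "    eta: [75 mPa.s, 40 mPa.s, 24 mPa.s]",
    "  density_points:",
    "    T_C: [20, 40, 60]",
    "    rho: [1187, 1172, 1158]",
    "field:",
    "  H: [1 kA/m, 2 kA/m, 3 kA/m]",
    "  f: [402 kHz]",
    paste0("  mode: ", field_mode)), path)
  path
}

test_that("quantities with display units round-trip through SI", {
  expect_equal(parse_quantity("4.3 kA/m"), 4300)
  expect_equal(display_quantity(4300, "kA/m"), 4.3)
  expect_equal(parse_quantity("1 nm"), 1e-9)
  expect_equal(parse_quantity("395 kHz"), 395e3)
  expect_equal(parse_quantity("75 mPa.s"), 0.075)
  expect_equal(parse_quantity("10.57 %"), 0.1057)
  expect_equal(parse_quantity("47 kJ/m3"), 4.7e4)
  expect_equal(parse_quantity(1.5), 1.5)           # bare numbers are SI
  expect_equal(parse_quantity(list("1 nm", "2 nm")), c(1e-9, 2e-9))
  expect_error(parse_quantity("4.3 furlongs"), "unknown unit")
})

test_that("config loading resolves defaults and rejects contradictions", {
  cfg_path <- write_config(tempfile(fileext = ".yaml"))
  cfg <- load_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$options$tau0, 1e-9)
  expect_equal(cfg$options$delta, 1e-9)
  expect_equal(cfg$options$K_a, 4.7e4)
  expect_equal(cfg$material$phi * 100, 10.575)   # resolved from M_s / M_d
  expect_length(cfg$d_grid, 12)
  expect_s3_class(cfg$viscosity, "property_model")

  # both phi and M_s_fluid is contradictory
  bad <- write_config(tempfile(fileext = ".yaml"),
                      extra_material = "M_s_fluid: 42.3 kA/m\n  phi: 10.57 %")
  expect_error(load_config(bad), "exactly one")

  expect_error(load_config(tempfile()), "not found")
})

test_that("pipeline output is additive over groups, mode-consistent and deterministic", {
  cfg <- load_config(write_config(tempfile(fileext = ".yaml")))
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  res <- run_pipeline(cfg, out1, quiet = TRUE)

  # 12-group total equals the sum of 12 single-group runs
  tot <- res$sweep$SAR_W_per_g
  singles <- sapply(seq_along(cfg$d_grid), function(i) {
    mi <- material_spec(cfg$material$M_d, rho_m = cfg$material$rho_m,
                        phi = cfg$material$phi)
    gi <- particle_group(cfg$d_grid[i], phi_d = cfg$phi_d[i])
    cnd <- operating_conditions(20 + 273.15, evaluate(cfg$viscosity, 20))
    sar_sweep(gi, mi, cnd, H = cfg$field$H, f = cfg$field$f)$P_W_per_m3
  })
  expect_equal(res$sweep$P_W_per_m3, rowSums(singles), tolerance = 1e-12)

  # rotating run doubles every point of the alternating run
  cfg_rot <- load_config(write_config(tempfile(fileext = ".yaml"),
                                      field_mode = "rotating"))
  res_rot <- run_pipeline(cfg_rot, tempfile("rot"), quiet = TRUE)
  expect_equal(res_rot$sweep$SAR_W_per_g, 2 * tot)

  # reruns are byte-identical
  run_pipeline(cfg, out2, quiet = TRUE)
  for (f in c("sar_sweep.csv", "group_contributions.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("explicit group vectors and direct viscosity are accepted", {
  path <- write_config(
    tempfile(fileext = ".yaml"),
    groups = c("groups:",
               "  d: [6 nm, 8 nm, 10 nm]",
               "  phi_d: [2 %, 5 %, 3.575 %]"))
  cfg <- load_config(path)
  expect_equal(cfg$d_grid, c(6e-9, 8e-9, 10e-9))
  expect_equal(sum(cfg$phi_d), 0.10575)
  res <- run_pipeline(cfg, tempfile("x"), quiet = TRUE)
  expect_equal(nrow(res$groups), 3)
})

test_that("system object reports its resolved parameters", {
  sys <- reference_system()
  out <- capture.output(print(sys))
  expect_true(any(grepl("K_a = 47000", out)))       # calibration knob logged
  expect_true(any(grepl("rho_m = 4860", out)))      # surrogate density logged
  expect_true(any(grepl("phi = 10.57", out)))
  s <- summary(sys)
  expect_equal(nrow(s), 12)
  expect_equal(sum(s$P_W_per_m3), attr(s, "P_total"))

  # mismatched group fractions vs material phi are rejected
  m <- material_spec(4e5, phi = 0.1)
  expect_error(mfh_system(m, c(8e-9, 10e-9), c(0.01, 0.01), viscosity = 0.075),
               "sum to")
})
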