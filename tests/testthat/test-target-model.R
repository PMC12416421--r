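# Target compositions, parsing, solvent mixing, pulse profiles.

test_that("printed compositions parse with correct derived densities", {
  txt <- c("H 13942", "C 5056", "N 1576", "O 4386", "S 80",
           "density 1.2 g/cm3")
  comp <- parse_target_spec(txt)
  expect_equal(unname(comp$counts[c("H", "C", "N", "O", "S")]),
               c(13942, 5056, 1576, 4386, 80))
  # mass / volume consistency
  expect_equal(comp$density_g_cm3, 1.2)
  expect_gt(comp$ndens_cm3[["C"]], 1e22)
  expect_lt(comp$ndens_cm3[["C"]], 5e22)
})

test_that("doped-target densities follow from molar masses", {
  comp <- target_composition(c(C = 613, N = 193, O = 185, Zn = 10),
                             density_g_cm3 = 1.2)
  mass <- 613 * 12.011 + 193 * 14.007 + 185 * 15.999 + 10 * 65.38
  vol <- mass / 6.02214076e23 / 1.2
  expect_equal(unname(comp$ndens_cm3[["C"]]), 613 / vol, tolerance = 1e-10)
})

test_that("composition validation errors are specific", {
  expect_error(parse_target_spec(c("density 1.2 g/cm3")), "empty composition")
  expect_error(target_composition(c(C = 10)), "exactly one")
  expect_error(target_composition(c(C = 10), density_g_cm3 = 1,
                                  volume_a3 = 100), "exactly one")
  expect_error(parse_target_spec(c("Qq 5", "density 1 g/cm3")),
               "unknown element")
})

test_that("parse -> serialize -> parse round trip is the identity", {
  comp <- target_composition(c(C = 613, N = 203, O = 185),
                             density_g_cm3 = 1.2)
  comp2 <- parse_target_spec(format_target_spec(comp))
  expect_equal(comp2$counts, comp$counts, tolerance = 1e-12)
  expect_equal(comp2$ndens_cm3, comp$ndens_cm3, tolerance = 1e-10)
})

test_that("solvent mixing is linear in the number densities", {
  prot <- target_composition(c(C = 100, N = 30), density_g_cm3 = 1.35)
  solv <- target_composition(c(H = 2000, O = 1000), density_g_cm3 = 1.0)
  expect_equal(mix_solvent(prot, solv, 0)$ndens_cm3[c("C", "N")],
               prot$ndens_cm3[c("C", "N")], tolerance = 1e-12)
  expect_equal(unname(mix_solvent(prot, solv, 1)$ndens_cm3[c("H", "O")]),
               unname(solv$ndens_cm3[c("H", "O")]), tolerance = 1e-12)
  x <- 0.351
  mx <- mix_solvent(prot, solv, x)
  expect_equal(unname(mx$ndens_cm3[["C"]]),
               unname((1 - x) * prot$ndens_cm3[["C"]]), tolerance = 1e-12)
  expect_equal(unname(mx$ndens_cm3[["O"]]),
               unname(x * solv$ndens_cm3[["O"]]), tolerance = 1e-12)
  expect_error(mix_solvent(prot, solv, 1.2), "fraction")
})

test_that("pulse profiles integrate to the fluence and have correct shape", {
  pg <- pulse_profile(9, 3.3e11, fwhm_fs = 12)
  Ig <- stats::integrate(function(t) pulse_flux(pg, t), -80, 80,
                         rel.tol = 1e-10)$value
  expect_equal(Ig, 3.3e11, tolerance = 1e-8)
  ps <- pulse_profile(9, 3.3e11, shape = "square", fwhm_fs = 12)
  # integrate the smooth interior of the square window (exact support)
  Is <- stats::integrate(function(t) pulse_flux(ps, t), -6 + 1e-12,
                         6 - 1e-12, rel.tol = 1e-10)$value
  expect_equal(Is, 3.3e11, tolerance = 1e-8)
  expect_true(all(pulse_flux(ps, c(-7, 7)) == 0))
  pg10 <- pulse_profile(9, 1e12, fwhm_fs = 10)
  # FWHM definition: half the peak at +-FWHM/2
  expect_equal(pulse_flux(pg10, 5), pulse_flux(pg10, 0) / 2,
               tolerance = 1e-10)
  # square peak flux exceeds the gaussian peak by sigma*sqrt(2*pi)/FWHM
  ps10 <- pulse_profile(9, 1e12, shape = "square", fwhm_fs = 10)
  ratio <- pulse_flux(ps10, 0) / pulse_flux(pg10, 0)
  expect_equal(ratio, pg10$sigma_fs * sqrt(2 * pi) / 10, tolerance = 1e-12)
  expect_equal(ratio, 1.0645, tolerance = 1e-3)
})

test_that("fixture compositions are regression-locked to the printed values", {
  fx <- fixture_composition("lysozyme_gd_full")
  expect_equal(unname(fx$counts), c(13259, 5153, 1596, 4009, 80, 21, 93, 87))
  expect_equal(names(fx$counts), c("H", "C", "N", "O", "S", "Gd", "Na", "Cl"))
  lc <- fixture_composition("light_atom_control")
  expect_equal(unname(lc$counts), c(13942, 5056, 1656, 4386))
  lw <- fixture_composition("lysozyme_water")
  expect_equal(unname(lw$counts), c(13942, 5056, 1576, 4386, 80))
  cn <- fixture_composition("cno")
  expect_equal(unname(cn$counts), c(613, 203, 185))
  dz <- fixture_composition("doped_cno", dopant = "Se")
  expect_equal(unname(dz$counts), c(613, 193, 185, 10))
  expect_true("Se" %in% names(dz$counts))
  expect_error(fixture_composition("nope"), "unknown fixture")
})

test_that("fixture files round-trip through the parser", {
  dir <- tempfile("fx")
  paths <- make_fixture("cno", dir)
  comp <- parse_target_spec(paths[["target"]])
  expect_equal(comp$counts, fixture_composition("cno")$counts)
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$pulse$energy_kev, 7.112)
})
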