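# Observables: charge traces, intensity averages, EDR, ionization contrast,
# snapshots. Synthetic trajectories are assembled in code where the contract
# is purely arithmetic.

# minimal synthetic trajectory for observable arithmetic
synthetic_traj <- function(time_fs, charge, elements, pulse,
                           ndens = rep(1e22, length(elements))) {
  Z <- crplasma:::element_z(elements)
  bound <- sweep(-charge, 2, Z, "+")
  structure(list(time_fs = time_fs, charge = charge, bound = bound,
                 elements = data.frame(symbol = elements, Z = Z,
                                       ndens_cm3 = ndens,
                                       stringsAsFactors = FALSE),
                 pulse = pulse), class = "cr_trajectory")
}

test_that("intensity averaging is exact on constants and linear", {
  pulse <- pulse_profile(9, 1e12, fwhm_fs = 10)
  tt <- seq(-18, 18, by = 0.1)
  expect_equal(intensity_averaged(data.frame(time_fs = tt, x = rep(3.3, length(tt))),
                                  pulse), 3.3, tolerance = 1e-12)
  x1 <- sin(tt / 5) + 2
  x2 <- cos(tt / 7)
  a1 <- intensity_averaged(data.frame(time_fs = tt, x = x1), pulse)
  a2 <- intensity_averaged(data.frame(time_fs = tt, x = x2), pulse)
  a12 <- intensity_averaged(data.frame(time_fs = tt, x = 2 * x1 - x2), pulse)
  expect_equal(a12, 2 * a1 - a2, tolerance = 1e-10)
  # symmetric profile: an antisymmetric trace averages to the midpoint value
  xa <- tt^3
  expect_equal(intensity_averaged(data.frame(time_fs = tt, x = xa), pulse), 0,
               tolerance = 1e-6 * max(abs(xa)))
  # monotone: pointwise-ordered traces give ordered averages
  expect_lte(a2, intensity_averaged(data.frame(time_fs = tt, x = x2 + 0.1),
                                    pulse))
  # insufficient coverage errors
  expect_error(intensity_averaged(data.frame(time_fs = tt[tt < 0], x = x1[tt < 0]),
                                  pulse), "cover")
})

test_that("EDR of an undamaged target equals the neutral-count ratio", {
  pulse <- pulse_profile(7.112, 1e12, fwhm_fs = 10)
  tt <- seq(-15, 15, by = 0.5)
  q <- matrix(0, length(tt), 4,
              dimnames = list(NULL, c("C", "N", "O", "Gd")))
  traj <- synthetic_traj(tt, q, c("C", "N", "O", "Gd"), pulse)
  edr <- compute_edr(traj, "Gd", c(C = 20, N = 10, O = 10))
  expect_equal(edr$ratio, 64 / 270, tolerance = 1e-12)
  expect_equal(edr$undamaged_ratio, 64 / 270)
  # reference region = the heavy atom itself: ratio 1
  edr1 <- compute_edr(traj, "Gd", c(Gd = 1))
  expect_equal(edr1$ratio, 1, tolerance = 1e-12)
})

test_that("ionization contrast recovers a constructed charge difference", {
  pulse <- pulse_profile(7.112, 1e12, fwhm_fs = 10)
  tt <- seq(-15, 15, by = 0.25)
  phi <- pulse_flux(pulse, tt) / 1e12
  # frozen light atoms, Gd charge difference Delta = 7 at all times
  qh <- cbind(C = 0 * tt, N = 0 * tt, O = 0 * tt, Gd = 10 + 0 * tt)
  ql <- cbind(C = 0 * tt, N = 0 * tt, O = 0 * tt, Gd = 3 + 0 * tt)
  th <- synthetic_traj(tt, qh, c("C", "N", "O", "Gd"), pulse)
  tl <- synthetic_traj(tt, ql, c("C", "N", "O", "Gd"), pulse)
  expect_equal(ionization_contrast(th, tl), 7, tolerance = 1e-10)
  expect_equal(ionization_contrast(th, tl, correct_light = TRUE), 7,
               tolerance = 1e-10)
  # identical trajectories: zero
  expect_equal(ionization_contrast(th, th), 0, tolerance = 1e-12)
  # ionizing light atoms lower the corrected contrast below the actual one
  qh2 <- qh; qh2[, c("C", "N", "O")] <- 1.5   # high fluence ionizes light atoms
  th2 <- synthetic_traj(tt, qh2, c("C", "N", "O", "Gd"), pulse)
  un <- ionization_contrast(th2, tl)
  co <- ionization_contrast(th2, tl, correct_light = TRUE)
  expect_lt(co, un)
  # mismatched targets are rejected
  t3 <- synthetic_traj(tt, qh[, 1:3], c("C", "N", "O"), pulse)
  expect_error(ionization_contrast(th, t3), "mismatch")
})

test_that("charge traces and light-atom weighting come from populations", {
  comp <- fixture_composition("cno")
  pulse <- pulse_profile(9, 5e11, fwhm_fs = 10)
  traj <- cached_run("cno_9kev_5e11", run_simulation(
    comp, pulse, test_policy(), t_start_fs = -12, t_end_fs = 12))
  tr <- average_charge_trace(traj, "C")
  expect_equal(tr$charge[1], 0, tolerance = 1e-10)
  expect_true(all(diff(tr$charge) > -1e-6))
  expect_error(average_charge_trace(traj, "Xe"), "not present")
  la <- light_atom_charge_trace(traj)
  w <- traj$elements$ndens_cm3
  expect_equal(la$charge[10],
               sum(traj$charge[10, ] * w) / sum(w), tolerance = 1e-12)
})
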