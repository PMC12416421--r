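# Spline basis and discrete operators: partition of unity, projections,
# moment-exact sources, regridding, and the reference operator assemblies.

test_that("basis functions form a partition of unity and the mass matrix is SPD", {
  b <- build_basis(200, peaks_ev = c(50, 120), n_log = 18)
  e <- sort(stats::runif(100, 1e-6, 200 - 1e-6))
  vals <- crplasma:::cpp_bspline_design(b$knots, b$order, e)
  expect_equal(rowSums(vals), rep(1, 100), tolerance = 1e-12)
  ev <- eigen(b$mass, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(b$mass, t(b$mass), tolerance = 1e-14)
})

test_that("spline evaluation agrees with splines::splineDesign", {
  kn <- c(rep(0, 4), c(3, 7, 20, 55, 90), rep(100, 4))
  x <- sort(stats::runif(60, 0, 100))
  expect_equal(crplasma:::cpp_bspline_design(kn, 4L, x),
               unname(splines::splineDesign(kn, x, ord = 4, outer.ok = TRUE)),
               tolerance = 1e-12)
  expect_equal(crplasma:::cpp_bspline_design(kn, 4L, x, 1L),
               unname(splines::splineDesign(kn, x, ord = 4, outer.ok = TRUE,
                                            derivs = rep(1L, length(x)))),
               tolerance = 1e-11)
})

test_that("a Maxwellian projects onto a thermal-dense grid with small L2 error", {
  b <- build_basis(400, n_log = 40, emin_ev = 0.05)
  fM <- maxwellian_cm3_ev(b$qx, 1e20, 10)
  cf <- solve(b$mass, drop(t(b$Bq) %*% (b$qw * fM)))
  err <- sqrt(sum(b$qw * (drop(b$Bq %*% cf) - fM)^2) / sum(b$qw * fM^2))
  expect_lt(err, 1e-3)
})

test_that("basis construction validates its inputs", {
  expect_error(build_basis(100, peaks_ev = 150), "outside")
  expect_error(build_basis(0.1, n_log = 2), "knots|exceed")
})

test_that("point sources have exact density and energy moments", {
  b <- build_basis(1000, n_log = 25)
  for (e0 in c(0.7, 13.2, 333, 950)) {
    inc <- project_point_source(b, e0, rate = 2.5e19)
    expect_equal(sum(b$mvec * inc), 2.5e19, tolerance = 1e-8)
    expect_equal(sum(b$evec * inc), 2.5e19 * e0, tolerance = 1e-8)
  }
  expect_equal(project_point_source(b, 50, 0), numeric(b$K))
  expect_error(project_point_source(b, 2000, 1), "outside")
})

test_that("two nearby deltas converge to one delta of the summed rate", {
  b <- build_basis(500, n_log = 30)
  e0 <- 100
  ref <- project_point_source(b, e0, 1)
  for (d in c(5, 1, 0.1)) {
    two <- 0.5 * (project_point_source(b, e0 - d, 1) +
                    project_point_source(b, e0 + d, 1))
    err <- sqrt(sum((two - ref)^2) / sum(ref^2))
    if (d <= 0.1) expect_lt(err, 1e-3)
  }
  expect_equal(sum(b$evec * (project_point_source(b, e0 - 1, 0.5) +
                               project_point_source(b, e0 + 1, 0.5))),
               e0, tolerance = 1e-8)
})

test_that("regridding preserves moments exactly and refines pointwise", {
  b1 <- build_basis(300, n_log = 20)
  fM <- maxwellian_cm3_ev(b1$qx, 1e21, 15)
  cf <- solve(b1$mass, drop(t(b1$Bq) %*% (b1$qw * fM)))
  d1 <- fe_distribution(b1, cf)
  m1 <- fe_moments(d1)
  # identical basis: identical coefficients
  d_same <- regrid(d1, b1)
  expect_equal(d_same$coef, d1$coef, tolerance = 1e-10)
  # finer basis: moments exact, pointwise error decreases
  b2 <- build_basis(300, n_log = 40)
  d2 <- regrid(d1, b2)
  expect_equal(fe_moments(d2), m1, tolerance = 1e-10)
  eg <- seq(1, 290, length.out = 500)
  ref <- maxwellian_cm3_ev(eg, 1e21, 15)
  e1 <- max(abs(fe_eval(d1, eg) - ref))
  # refine-then-coarsen round trip: moments unchanged
  d3 <- regrid(d2, b1)
  expect_equal(fe_moments(d3), m1, tolerance = 1e-10)
  # truncating the support errors out
  b_small <- build_basis(30, n_log = 15)
  expect_error(regrid(d1, b_small), "truncation")
})

test_that("EII reference operator obeys the per-event bookkeeping", {
  b <- build_basis(400, n_log = 35, emin_ev = 0.1)
  entries <- data.frame(B_ev = 30, U_ev = 40, N = 4, weight = 1e22)
  ops <- assemble_eii(b, entries)
  # monoenergetic pulse at 3B
  cf <- project_point_source(b, 90, 1) * 1e20
  dc <- drop((ops$gain - ops$loss) %*% cf)
  rate <- drop(ops$rate %*% cf) * entries$weight  # events /cm3/fs
  # number gain: +1 electron per event
  expect_equal(sum(b$mvec * dc), rate, tolerance = 1e-5 * rate)
  # energy change: -B per event
  expect_equal(sum(b$evec * dc), -30 * rate, tolerance = 1e-4 * 30 * rate)
  # f = 0: zero action
  expect_equal(drop((ops$gain - ops$loss) %*% numeric(b$K)), numeric(b$K))
})

test_that("EE reference operator conserves and fixes Maxwellians", {
  b <- build_basis(200, n_log = 45, emin_ev = 0.05)
  ee <- assemble_ee(b)
  fM <- maxwellian_cm3_ev(b$qx, 1e22, 8)
  cfM <- solve(b$mass, drop(t(b$Bq) %*% (b$qw * fM)))
  dM <- ee(cfM)
  # bimodal comparison state
  fB <- 0.5 * (maxwellian_cm3_ev(b$qx, 1e22, 2) +
                 maxwellian_cm3_ev(b$qx, 1e22, 18))
  cfB <- solve(b$mass, drop(t(b$Bq) %*% (b$qw * fB)))
  dB <- ee(cfB)
  # the residual of the projected Maxwellian is dominated by the sqrt(eps)
  # boundary panel, which cubic splines cannot represent; away from it the
  # equilibrium residual is at the percent level of a non-equilibrium flux,
  # and overall it is far below the non-equilibrium scale
  expect_lt(sqrt(sum(dM^2)), 0.25 * sqrt(sum(dB^2)))
  expect_lt(sqrt(sum(dM[-(1:6)]^2)), 0.05 * sqrt(sum(dB^2)))
  # the operator itself is exact on Maxwellian nodal data: evaluating the
  # drift/diffusion coefficients and fluxes from analytic values leaves only
  # quadrature noise (independent check of the Landau coefficient identity)
  HAc <- crplasma:::HARTREE_EV; C3 <- crplasma:::CM3_AU
  au <- crplasma:::basis_au_mirror(b)
  T_au <- 8 / HAc
  fex <- maxwellian_cm3_ev(au$qx * HAc, 1e22, 8) * C3 * HAc
  fdex <- fex * (1 / (2 * au$qx) - 1 / T_au)
  w <- au$qw * fex
  Mc <- cumsum(w) - 0.5 * w
  Ec <- cumsum(w * au$qx) - 0.5 * w * au$qx
  wj <- au$qw * fex / sqrt(2 * au$qx)
  Jg <- rev(cumsum(rev(wj))) - 0.5 * wj
  v <- sqrt(2 * au$qx)
  Phi <- (Mc / v) * fex +
    ((2 / (3 * v)) * Ec + (v^2 / 3) * Jg) * (fdex - fex / (2 * au$qx))
  Bqd <- crplasma:::cpp_bspline_design(au$knots, au$order, au$qx, deriv = 1L)
  resid <- solve(au$mass, -drop(t(Bqd) %*% (au$qw * Phi)))
  # compare to the bimodal flux in the same (a.u.) scale
  dB_au <- dB * (C3 * HAc) / crplasma:::AU_PER_FS
  expect_lt(sqrt(sum(resid^2)), 1e-4 * sqrt(sum(dB_au^2)))
  # conservation per application
  expect_lt(abs(sum(b$mvec * dB)) / sum(b$mvec * cfB), 1e-10)
  expect_lt(abs(sum(b$evec * dB)) / sum(b$evec * cfB), 1e-10)
})

test_that("repeated EE applications do not drift number or energy", {
  # explicit applications must respect the diffusion stability limit, so the
  # density is kept low and the step small
  b <- build_basis(150, n_log = 35, emin_ev = 0.05)
  ee <- assemble_ee(b)
  f0 <- maxwellian_cm3_ev(b$qx, 5e19, 3) + maxwellian_cm3_ev(b$qx, 5e19, 12)
  cf <- solve(b$mass, drop(t(b$Bq) %*% (b$qw * f0)))
  n0 <- sum(b$mvec * cf); e0 <- sum(b$evec * cf)
  dt <- 2e-4
  for (k in 1:1500) cf <- cf + dt * ee(cf)
  expect_true(all(is.finite(cf)))
  expect_lt(abs(sum(b$mvec * cf) / n0 - 1), 1e-4)
  expect_lt(abs(sum(b$evec * cf) / e0 - 1), 1e-4)
})

test_that("solver and reference assemblies agree on a three-element target", {
  # full right-hand side evaluated two ways: C++ operator path vs direct
  # quadrature, on a CNO gas with a prescribed non-equilibrium f
  comp <- target_composition(c(C = 6, N = 2, O = 2), density_g_cm3 = 0.8)
  pulse <- pulse_profile(2, 0, fwhm_fs = 10)
  pol <- solver_policy(ee = FALSE, tbr = FALSE, n_log = 40, emin_ev = 0.1,
                       eii_bin_rel = 1e-6, u_bin_rel = 1e-6)
  sys <- build_system(comp, pulse, pol)
  set_system_maxwellian(sys, 3e22, 40)
  r <- crplasma:::cpp_sys_rhs(sys$ptr)
  K <- sys$basis$K
  dc_sys <- r$dz[1:K] * crplasma:::AU_PER_FS / (CM3AU * HA)  # per fs, user units
  # reference: per-configuration entries at ground states (P = ground)
  entries <- do.call(rbind, lapply(seq_along(sys$models), function(i) {
    m <- sys$models[[i]]
    g <- m$cs$ground
    occ <- m$cs$occ[g, ]
    do.call(rbind, lapply(which(occ > 0), function(s) {
      occ2 <- occ; occ2[s] <- occ2[s] - 1L
      j <- crplasma:::config_index(m$cs, occ2)
      data.frame(B_ev = (m$st$E[j] - m$st$E[g]) * HA,
                 U_ev = m$st$U[s, g] * HA, N = occ[s],
                 weight = sys$target$ndens_cm3[i])
    }))
  }))
  ops <- assemble_eii(sys$basis, entries)
  au <- crplasma:::basis_au_mirror(sys$basis)
  st <- system_state(sys)
  cf_user <- st$c / (CM3AU * HA)
  dc_ref <- drop((ops$gain - ops$loss) %*% cf_user)
  scale <- max(abs(dc_ref))
  expect_lt(max(abs(dc_sys - dc_ref)) / scale, 1e-4)
})
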