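# Atomic-structure module: configuration enumeration, mean field,
# photoionization, decay channels, BEB cross-sections.

test_that("configuration enumeration counts match the combinatorial product", {
  expect_equal(enumerate_configurations(1)$n, 2L)
  cs6 <- enumerate_configurations(6)
  expect_equal(cs6$n, 27L)
  expect_equal(nrow(unique(cs6$occ)), 27L)
  # ground configuration flagged and correct
  expect_equal(unname(cs6$occ[cs6$ground, ]), c(2L, 2L, 2L))
  # every occupancy between 0 and ground
  expect_true(all(cs6$occ >= 0))
  expect_true(all(t(cs6$occ) <= cs6$shells$occ))
})

test_that("collapsed-shell enumeration of Gd gives the documented set", {
  cs <- enumerate_configurations(64)
  expect_true(cs$collapse)
  expect_equal(unname(cs$shells$occ), c(2L, 8L, 18L, 25L, 9L, 2L))
  expect_equal(cs$n, prod(c(2, 8, 18, 25, 9, 2) + 1))  # 400140
  expect_equal(cs$n, 400140L)
  # exhaustive check on a smaller collapsed structure (Zn)
  cz <- enumerate_configurations(30)
  expect_equal(cz$n, prod(cz$shells$occ + 1))
  expect_equal(nrow(unique(cz$occ)), cz$n)
})

test_that("unsupported elements are rejected", {
  expect_error(enumerate_configurations(93), "unsupported")
  expect_error(enumerate_configurations(0), "unsupported")
})

test_that("mean field reproduces exact one-electron limits", {
  h <- solve_mean_field(1, c(1))
  expect_equal(h$B[1], 13.6057, tolerance = 1e-3)
  expect_equal(h$U[1], 13.6057, tolerance = 1e-3)
  fe <- solve_mean_field(26, c(1), shells = crplasma:::ground_subshells(26)[1, ])
  expect_equal(fe$B[1], 13.6057 * 26^2, tolerance = 2e-3)
  # bare nucleus: zero-orbital result, not an error
  bare <- solve_mean_field(6, c(0, 0, 0))
  expect_equal(bare$E_total, 0)
})

test_that("carbon K-shell binding is near tabulated free-atom values", {
  g <- solve_mean_field(6, c(2, 2, 2))
  k <- solve_mean_field(6, c(1, 2, 2))
  dB <- k$E_total - g$E_total
  expect_lt(abs(dB - 296) / 296, 0.10)
  # orbital energies positive and ordered
  expect_true(all(g$B > 0))
  expect_true(g$B[1] > g$B[2], g$B[2] > g$B[3])
})

test_that("total energy increases monotonically along ionization paths", {
  for (Z in c(6, 8)) {
    m <- crplasma:::element_model(Z, 1000)
    occ <- m$cs$occ
    E <- m$st$E
    for (i in seq_len(m$cs$n)) {
      for (s in which(occ[i, ] > 0)) {
        occ2 <- occ[i, ]
        occ2[s] <- occ2[s] - 1L
        j <- crplasma:::config_index(m$cs, occ2)
        expect_gt(E[j], E[i])
      }
    }
  }
})

test_that("hydrogen photoionization matches the exact threshold value", {
  # 6.30e-18 cm^2 at threshold (numeric dipole; WKB-normalized continuum)
  s <- photoionization_cross_section(1, c(1), 1, 13.6058 * 1.0001)
  expect_equal(s, 6.30e-18, tolerance = 0.04)
})

test_that("K-shell cross-section grows steeply with Z at fixed photon energy", {
  zs <- c(6, 8, 10, 13, 16)
  sg <- sapply(zs, function(Z) {
    sh <- crplasma:::ground_subshells(Z)
    photoionization_cross_section(Z, sh$occ, 1, 8000, shells = sh)
  })
  fit <- stats::lm(log(sg) ~ log(zs))
  expo <- unname(stats::coef(fit)[2])
  expect_gt(expo, 4)
  expect_lt(expo, 6)
})

test_that("photoionization is zero below threshold and errors on bad input", {
  expect_equal(photoionization_cross_section(6, c(2, 2, 2), 1, 100), 0)
  expect_error(photoionization_cross_section(6, c(2, 2, 2), 1, -5),
               "non-negative")
  # empty subshell: zero, not an error
  expect_equal(photoionization_cross_section(6, c(2, 2, 0), 3, 8000), 0)
})

test_that("BEB total cross-section matches an independent evaluation", {
  B <- 13.6; U <- 13.6; N <- 1
  # independent R implementation of the closed form
  beb_ref <- function(T) {
    t <- T / B; u <- U / B
    a0 <- 0.529177210903e-8
    S <- 4 * pi * a0^2 * N * (13.6057 / B)^2
    S / (t + u + 1) * (log(t) / 2 * (1 - 1 / t^2) + 1 - 1 / t -
                         log(t) / (t + 1))
  }
  for (T in c(20, 50, 100, 1000)) {
    expect_equal(eii_cross_section(B, U, N, T), beb_ref(T), tolerance = 1e-10)
  }
  expect_equal(eii_cross_section(B, U, N, B), 0)
  expect_error(eii_cross_section(-1, U, N, 50), "positive")
})

test_that("BEB cross-section is unimodal and decays like ln(T)/T", {
  B <- 20; U <- 30; N <- 2
  Tg <- exp(seq(log(B * 1.01), log(100 * B), length.out = 400))
  sg <- eii_cross_section(B, U, N, Tg)
  imax <- which.max(sg)
  expect_gt(imax, 1)
  expect_lt(imax, length(Tg))
  d <- diff(sg)
  expect_true(all(d[1:(imax - 1)] > 0))
  expect_true(all(d[imax:length(d)] < 0))
  # asymptotic ratio test: sigma(T) * T / ln(T) approaches a constant
  r1 <- sg[length(Tg)] * Tg[length(Tg)] / log(Tg[length(Tg)] / B)
  r2 <- sg[imax + 250] * Tg[imax + 250] / log(Tg[imax + 250] / B)
  expect_equal(r1 / r2, 1, tolerance = 0.25)
})

test_that("BEB secondary spectrum is symmetric and integrates to the total", {
  B <- 30; U <- 40; N <- 4; T <- 400
  sg <- eii_cross_section(B, U, N, T)
  intg <- stats::integrate(function(w) eii_sdcs(B, U, N, T, w), 0, (T - B) / 2,
                           rel.tol = 1e-9)$value
  expect_equal(intg, sg, tolerance = 1e-6)
  w <- c(5, 20, 60, 120)
  expect_equal(eii_sdcs(B, U, N, T, w), eii_sdcs(B, U, N, T, T - B - w),
               tolerance = 1e-12)
})

test_that("slow secondaries dominate the BEB spectrum far above threshold", {
  B <- 30; U <- 40; N <- 4; T <- 3000
  wg <- seq(0.1, (T - B) / 2, length.out = 200)
  sd <- eii_sdcs(B, U, N, T, wg)
  expect_equal(which.max(sd), 1L)
  expect_gt(sd[1] / sd[100], 10)
  # outside the kinematic range: zero
  expect_equal(eii_sdcs(B, U, N, T, T), 0)
})

test_that("TBR kernel is non-negative and vanishes without free electrons", {
  B <- 20; U <- 25; N <- 2
  e1 <- rep(exp(seq(log(0.1), log(500), length.out = 50)), 50)
  e2 <- rep(exp(seq(log(0.1), log(500), length.out = 50)), each = 50)
  k <- tbr_kernel(B, U, N, e1, e2, g_ratio = 1.5)
  expect_true(all(k >= 0))
  expect_true(any(k > 0))
  expect_equal(tbr_kernel(B, U, 0, 10, 10), 0)
})

test_that("decay channels obey the structural selection rules", {
  # ground state: no vacancy below an occupied shell -> empty set
  d <- decay_rates(6, c(2, 2, 2))
  expect_equal(nrow(d), 0L)
  # K hole with a single electron above: fluorescence only
  d1 <- decay_rates(6, c(1, 1, 0))
  expect_true(all(d1$type == "fluor"))
  expect_true(all(d1$rate_fs >= 0))
  # K hole with full L shell: Auger dominates for carbon
  d2 <- decay_rates(6, c(1, 2, 2))
  expect_true("auger" %in% d2$type)
  rA <- sum(d2$rate_fs[d2$type == "auger"])
  rF <- sum(d2$rate_fs[d2$type == "fluor"])
  expect_gt(rA, 100 * rF)
  expect_true(all(d2$energy_ev > 0))
  # carbon K lifetime ~ 10 fs; sulfur K hole decays within ~1 fs
  expect_equal(1 / sum(d2$rate_fs), 10.6, tolerance = 0.25)
  sh <- crplasma:::ground_subshells(16)
  occS <- sh$occ; occS[1] <- 1L
  dS <- decay_rates(16, occS, shells = sh)
  expect_lt(1 / sum(dS$rate_fs), 1.3)
})

test_that("Auger moves one electron down and ejects one", {
  d <- decay_rates(8, c(1, 2, 4))
  aug <- d[d$type == "auger", ]
  for (k in seq_len(nrow(aug))) {
    dst <- aug$dst[[k]]
    expect_equal(sum(dst), 6)          # one electron lost
    expect_equal(dst[1], 2)            # hole filled
  }
  fl <- d[d$type == "fluor", ]
  for (k in seq_len(nrow(fl))) {
    expect_equal(sum(fl$dst[[k]]), 7)  # electron count unchanged
  }
})

test_that("atomic tables are reproducible from settings", {
  m1 <- crplasma:::element_model(6, 5000)
  m2 <- crplasma:::element_model(6, 5000)
  expect_identical(m1$st$E, m2$st$E)
  expect_identical(m1$st$sigma, m2$st$sigma)
  expect_identical(m1$st$U, m2$st$U)
})
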