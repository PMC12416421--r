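# Reference (direct-quadrature) assemblies of the collision and source
# operators on a spline basis. These mirror the solver's C++ operators and
# serve as the independent assembly route for verification, and as the module
# API for small systems. User units: eV, fs, cm^-3, cm^2.
#
# Internally everything is converted to atomic units on a mirrored basis
# (B-splines are affine-invariant, so coefficients carry over with a unit
# factor).

# conversion factor: coefficient (cm^-3 eV^-1) -> a.u.
.FAU <- function() CM3_AU * HARTREE_EV

basis_au_mirror <- function(basis) {
  mirror <- attr(basis, "au_mirror")
  if (!is.null(mirror)) return(mirror)
  m <- basis_from_knots(basis$knots / HARTREE_EV, basis$order)
  m
}

#' Assemble electron-impact-ionization operators (reference route)
#'
#' Direct Galerkin quadrature of the EII loss and gain terms for a set of
#' (configuration, subshell) entries. Acting on f, the loss removes density
#' at energy eps at rate n sigma(eps) v(eps); the gain adds the two outgoing
#' electrons distributed by the BEB secondary spectrum. Each event adds one
#' net free electron and removes B from the free kinetic energy.
#'
#' @param basis a [build_basis()] object (eV domain)
#' @param entries data.frame with columns B_ev, U_ev, N (occupancy), and
#'   weight (atoms cm^-3 of the configuration)
#' @return list with `loss` and `gain` (K x K matrices; dc/dt = (gain-loss) c
#'   in fs^-1) and `rate` (entries x K matrix of per-atom ionization-rate
#'   functionals, fs^-1 when dotted with f)
#' @export
assemble_eii <- function(basis, entries) {
  stopifnot(all(c("B_ev", "U_ev", "N", "weight") %in% names(entries)))
  au <- basis_au_mirror(basis)
  K <- au$K
  A <- matrix(0, K, K)
  G <- matrix(0, K, K)
  R <- matrix(0, nrow(entries), K)
  glx <- c(-0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
           -0.4333953941292472, -0.14887433898163122, 0.14887433898163122,
           0.4333953941292472, 0.6794095682990244, 0.8650633666889845,
           0.9739065285171717)
  glw <- c(0.06667134430868814, 0.1494513491505806, 0.21908636251598204,
           0.2692667193099963, 0.29552422471475287, 0.29552422471475287,
           0.2692667193099963, 0.21908636251598204, 0.1494513491505806,
           0.06667134430868814)
  for (i in seq_len(nrow(entries))) {
    B <- entries$B_ev[i] / HARTREE_EV
    U <- entries$U_ev[i] / HARTREE_EV
    N <- entries$N[i]
    w_at <- entries$weight[i] * CM3_AU     # atoms / bohr^3
    sg <- cpp_beb_sigma(B, U, 1, au$qx)    # per electron
    v <- sqrt(2 * au$qx)
    wl <- au$qw * sg * v
    Ai <- t(au$Bq) %*% (au$Bq * wl)
    R[i, ] <- N * drop(t(au$Bq) %*% wl)
    Gi <- matrix(0, K, K)
    for (q in which(wl > 0)) {
      eps <- au$qx[q]
      half <- 0.5 * (eps - B)
      # log-mapped nodes u = ln(1 + w/B): resolves the near-zero peak
      umax <- log(1 + half / B)
      un <- 0.5 * umax * (1 + glx)
      wn <- B * (exp(un) - 1)
      sv <- 0.5 * umax * glw * (wn + B) * cpp_beb_sdcs(B, U, 1, eps, wn)
      tot <- sum(sv)
      if (tot <= 0) next
      sv <- sv * (sg[q] / tot)
      Bw <- cpp_bspline_design(au$knots, au$order, c(wn, eps - B - wn))
      dep <- colSums((c(sv, sv)) * Bw)
      Gi[, ] <- Gi + outer(dep, au$qw[q] * v[q] * au$Bq[q, ])
    }
    A <- A + w_at * N * Ai
    G <- G + w_at * N * Gi
  }
  Minv <- solve(au$mass)
  # dc/dt_fs = dc/dt_au * (a.u. per fs)
  list(loss = Minv %*% A * AU_PER_FS, gain = Minv %*% G * AU_PER_FS,
       rate = R * AU_PER_FS * .FAU())
}

#' Assemble the three-body recombination operator (reference route)
#'
#' Bilinear in f: each event removes two free electrons at (w, e2) with the
#' microreversible kernel and deposits one electron at B + w + e2. With a
#' Maxwellian f and Saha-balanced populations, the EII/TBR pair is stationary.
#'
#' @param basis a [build_basis()] object
#' @param entries data.frame with B_ev, U_ev, N, weight (recombining ions
#'   cm^-3), g_ratio
#' @param n_quad nodes per dimension for the (w, e2) quadrature
#' @return function(coef) -> list(dcdt (fs^-1), rate (per-ion fs^-1 per entry))
#' @export
assemble_tbr <- function(basis, entries, n_quad = 61) {
  au <- basis_au_mirror(basis)
  # log-spaced Simpson grid
  if (n_quad %% 2 == 0) n_quad <- n_quad + 1
  emin <- max(au$emin, 1e-3 / HARTREE_EV)
  emax <- min(au$emax, 1500 / HARTREE_EV)
  x <- seq(log(emin * 1.02), log(emax * 0.6), length.out = n_quad)
  eg <- exp(x)
  sw <- rep(c(4, 2), length.out = n_quad - 2)
  wx <- (x[2] - x[1]) / 3 * c(1, sw, 1)
  wq <- wx * eg                       # d eps = eps dx
  Bg <- cpp_bspline_design(au$knots, au$order, eg)
  Vc <- solve(au$mass, cbind(au$mvec, au$evec))
  C2 <- solve(crossprod(cbind(au$mvec, au$evec), Vc))
  pp <- function(e0) {
    b <- drop(cpp_bspline_design(au$knots, au$order, e0))
    p <- solve(au$mass, b)
    al <- C2 %*% c(1 - sum(au$mvec * p), e0 - sum(au$evec * p))
    p + drop(Vc %*% al)
  }
  sink_proj <- sapply(eg, pp)         # K x n
  ker <- list()
  depm <- list()
  for (i in seq_len(nrow(entries))) {
    B <- entries$B_ev[i] / HARTREE_EV
    U <- entries$U_ev[i] / HARTREE_EV
    N <- entries$N[i]
    gre <- expand.grid(e1 = eg, e2 = eg)
    kv <- entries$g_ratio[i] * N *
      cpp_tbr_kernel0(B, U, 1, gre$e1, gre$e2)
    Km <- matrix(kv, n_quad, n_quad) * outer(wq, wq)
    edep <- B + outer(eg, eg, "+")
    Km[edep >= au$emax] <- 0
    ker[[i]] <- Km
    # deposit projections for grid points with non-zero kernel
    nz <- which(Km > 0)
    Dm <- matrix(0, au$K, length(nz))
    for (r in seq_along(nz)) Dm[, r] <- pp(edep[nz[r]])
    depm[[i]] <- list(nz = nz, Dm = Dm)
  }
  function(coef) {
    cau <- coef * .FAU()
    fg <- drop(Bg %*% cau)
    fg[fg < 0] <- 0
    dc <- numeric(au$K)
    rates <- numeric(nrow(entries))
    for (i in seq_len(nrow(entries))) {
      S <- outer(fg, fg) * ker[[i]]
      tot <- sum(S)
      rates[i] <- tot
      if (tot <= 0) next
      w_ion <- entries$weight[i] * CM3_AU
      rs <- rowSums(S) + colSums(S)
      dc <- dc - w_ion * drop(sink_proj %*% rs)
      dc <- dc + w_ion * drop(depm[[i]]$Dm %*% S[depm[[i]]$nz])
    }
    list(dcdt = dc * AU_PER_FS / .FAU(), rate = rates * AU_PER_FS)
  }
}

#' Assemble the electron-electron collision operator
#'
#' Isotropic energy-space Fokker-Planck (Rosenbluth/Landau) operator for
#' pairwise Coulomb collisions among the free electrons. Conserves density
#' exactly (flux form) and kinetic energy to quadrature accuracy; Maxwellians
#' are stationary. The Coulomb logarithm is evaluated from the instantaneous
#' density and effective temperature (2/3 mean energy) and floored.
#'
#' @param basis a [build_basis()] object
#' @param lnL_floor lower bound on the Coulomb logarithm
#' @param conserve apply the two-moment projection that pins number and
#'   energy drift to zero (as in the solver)
#' @return function(coef) -> dc/dt (fs^-1)
#' @export
assemble_ee <- function(basis, lnL_floor = 2, conserve = TRUE) {
  au <- basis_au_mirror(basis)
  Bqd <- cpp_bspline_design(au$knots, au$order, au$qx, deriv = 1L)
  Vc <- solve(au$mass, cbind(au$mvec, au$evec))
  C2 <- solve(crossprod(cbind(au$mvec, au$evec), Vc))
  function(coef) {
    cau <- coef * .FAU()
    fq <- drop(au$Bq %*% cau)
    fd <- drop(Bqd %*% cau)
    n0 <- sum(au$qw * fq)
    if (n0 <= 1e-18) return(numeric(au$K))
    E0 <- sum(au$qw * pmax(fq, 0) * au$qx)
    Teff <- max(2 * E0 / (3 * n0), 1e-4)
    lnL <- 23.5 - log(sqrt(n0 / CM3_AU) * (Teff * HARTREE_EV)^-1.25) -
      sqrt(1e-5 + (log(Teff * HARTREE_EV) - 2)^2 / 16)
    lnL <- max(lnL, lnL_floor)
    Gam <- 4 * pi * lnL
    w <- au$qw * fq
    Mc <- cumsum(w) - 0.5 * w
    we <- w * au$qx
    Ec <- cumsum(we) - 0.5 * we
    wj <- au$qw * fq / sqrt(2 * au$qx)
    Jg <- rev(cumsum(rev(wj))) - 0.5 * wj
    v <- sqrt(2 * au$qx)
    a <- Gam * Mc / v
    d <- Gam * ((2 / (3 * v)) * Ec + (v^2 / 3) * Jg)
    Phi <- a * fq + d * (fd - fq / (2 * au$qx))
    rhs <- -drop(t(Bqd) %*% (au$qw * Phi))
    dc <- solve(au$mass, rhs)
    if (conserve) {
      al <- C2 %*% c(-sum(au$mvec * dc), -sum(au$evec * dc))
      dc <- dc + drop(Vc %*% al)
    }
    dc * AU_PER_FS / .FAU()
  }
}
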