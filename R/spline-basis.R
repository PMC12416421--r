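# B-spline representation of the free-electron energy distribution f(eps, t)
# (number density per unit energy). User-facing units: eV, cm^-3, fs.

#' Build a B-spline basis for the free-electron energy distribution
#'
#' Knots are dense in the thermal (low-energy) region via logarithmic spacing
#' and additionally clustered around requested peak energies (primary
#' photo/Auger lines). The domain starts at 0 so that slow secondaries are
#' representable.
#'
#' @param emax_ev upper edge of the energy domain (eV); must lie above the
#'   highest primary electron energy
#' @param peaks_ev energies (eV) of expected sharp injection peaks
#' @param n_log number of logarithmically spaced interior knots
#' @param emin_ev first interior knot (thermal resolution scale)
#' @param order spline order (degree + 1); cubic splines by default
#' @return object of class `spline_basis` with knot vector, mass matrix and
#'   moment vectors
#' @examples
#' b <- build_basis(100, n_log = 15)
#' b$K
#' @export
build_basis <- function(emax_ev, peaks_ev = numeric(), n_log = 40,
                        emin_ev = 0.12, order = 4) {
  if (emax_ev <= emin_ev) stop("emax must exceed emin")
  if (length(peaks_ev) && any(peaks_ev <= 0 | peaks_ev >= emax_ev)) {
    stop("requested peak energies outside the basis domain [0, emax]")
  }
  kn <- c(0, exp(seq(log(emin_ev), log(emax_ev), length.out = n_log)))
  for (p in peaks_ev) {
    kn <- c(kn, p * c(0.97, 0.99, 1.01, 1.03))
  }
  kn <- sort(unique(kn))
  kn <- kn[kn <= emax_ev]
  if (kn[length(kn)] < emax_ev) kn <- c(kn, emax_ev)
  # drop nearly coincident knots
  keep <- c(TRUE, diff(kn) > 1e-6 * emax_ev * 1e-3 + 1e-9)
  kn <- kn[keep]
  if (length(kn) < order + 1) stop("need at least order + 1 distinct knots")
  knots <- c(rep(kn[1], order - 1), kn, rep(kn[length(kn)], order - 1))
  basis_from_knots(knots, order)
}

# internal: build the object from a full knot vector
basis_from_knots <- function(knots, order) {
  K <- length(knots) - order
  # Gauss-Legendre (8 pt) per interval
  gl <- list(x = c(-0.9602898564975363, -0.7966664774136267, -0.525532409916329,
                   -0.18343464249564978, 0.18343464249564978, 0.525532409916329,
                   0.7966664774136267, 0.9602898564975363),
             w = c(0.10122853629037626, 0.22238103445337448, 0.31370664587788727,
                   0.362683783378362, 0.362683783378362, 0.31370664587788727,
                   0.22238103445337448, 0.10122853629037626))
  iv <- unique(knots)
  qx <- qw <- numeric(0)
  for (i in seq_len(length(iv) - 1)) {
    a <- iv[i]; b <- iv[i + 1]
    qx <- c(qx, 0.5 * (a + b) + 0.5 * (b - a) * gl$x)
    qw <- c(qw, 0.5 * (b - a) * gl$w)
  }
  Bq <- cpp_bspline_design(knots, order, qx)
  M <- t(Bq) %*% (Bq * qw)
  structure(list(knots = knots, order = order, K = K, qx = qx, qw = qw,
                 Bq = Bq, mass = M, mvec = drop(t(Bq) %*% qw),
                 evec = drop(t(Bq) %*% (qw * qx)),
                 emin = knots[1], emax = knots[length(knots)]),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> K =", x$K, "order", x$order, "domain [",
      signif(x$emin, 3), ",", signif(x$emax, 5), "] eV\n")
  invisible(x)
}

#' Free-electron distribution on a spline basis
#'
#' @param basis a [build_basis()] object
#' @param coef coefficient vector (length `basis$K`); f(eps) = sum c_k B_k(eps)
#'   in cm^-3 eV^-1
#' @export
fe_distribution <- function(basis, coef = numeric(basis$K)) {
  stopifnot(length(coef) == basis$K)
  structure(list(basis = basis, coef = as.numeric(coef)),
            class = "fe_distribution")
}

#' Evaluate a distribution at given energies
#' @param dist an [fe_distribution()]
#' @param e_ev energies (eV)
#' @export
fe_eval <- function(dist, e_ev) {
  drop(cpp_bspline_design(dist$basis$knots, dist$basis$order, e_ev) %*% dist$coef)
}

#' Density and energy moments of a distribution
#' @param dist an [fe_distribution()]
#' @return c(density cm^-3, energy density eV cm^-3)
#' @export
fe_moments <- function(dist) {
  c(density = sum(dist$basis$mvec * dist$coef),
    energy = sum(dist$basis$evec * dist$coef))
}

# moment-exact point projection (shared with the C++ solver)
point_projection <- function(basis, e0) {
  b <- drop(cpp_bspline_design(basis$knots, basis$order, e0))
  p <- solve(basis$mass, b)
  V <- solve(basis$mass, cbind(basis$mvec, basis$evec))
  al <- solve(crossprod(cbind(basis$mvec, basis$evec), V),
              c(1 - sum(basis$mvec * p), e0 - sum(basis$evec * p)))
  p + drop(V %*% al)
}

#' Weak-form projection of a monoenergetic source
#'
#' Projects a delta source at `e0_ev` onto the basis with the zeroth and
#' first moments matched exactly (rate and rate * e0).
#'
#' @param basis a [build_basis()] object
#' @param e0_ev source energy (eV); must lie inside the basis domain
#' @param rate source strength (cm^-3 fs^-1)
#' @return coefficient increment per fs
#' @export
project_point_source <- function(basis, e0_ev, rate) {
  if (e0_ev < basis$emin || e0_ev > basis$emax) {
    stop("source energy ", e0_ev, " eV outside basis domain; regrid needed")
  }
  if (rate == 0) return(numeric(basis$K))
  rate * point_projection(basis, e0_ev)
}

#' Transfer a distribution to a new basis
#'
#' Constrained least-squares projection: minimizes the L2 difference subject
#' to exact preservation of the density and energy moments.
#'
#' @param dist an [fe_distribution()]
#' @param new_basis target basis; its domain must cover the support of `dist`
#' @param tol maximum tolerated relative density outside the new domain
#' @export
regrid <- function(dist, new_basis, tol = 1e-8) {
  old <- dist$basis
  n0 <- fe_moments(dist)
  # density outside new domain
  outside <- old$qx > new_basis$emax | old$qx < new_basis$emin - 1e-12
  f_old_q <- drop(old$Bq %*% dist$coef)
  lost <- sum(old$qw[outside] * abs(f_old_q[outside]))
  if (lost > tol * max(abs(n0[1]), 1e-300)) {
    stop("support truncation in regrid: relative density ",
         signif(lost / max(abs(n0[1]), 1e-300), 3), " outside new domain")
  }
  # evaluate old f on new basis quadrature
  fq <- drop(cpp_bspline_design(old$knots, old$order, new_basis$qx) %*% dist$coef)
  b <- drop(t(new_basis$Bq) %*% (new_basis$qw * fq))
  cnew <- solve(new_basis$mass, b)
  # constrain moments
  V <- solve(new_basis$mass, cbind(new_basis$mvec, new_basis$evec))
  al <- solve(crossprod(cbind(new_basis$mvec, new_basis$evec), V),
              c(n0[1] - sum(new_basis$mvec * cnew),
                n0[2] - sum(new_basis$evec * cnew)))
  fe_distribution(new_basis, cnew + drop(V %*% al))
}
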