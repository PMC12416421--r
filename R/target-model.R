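# Targets (composition, density) and pulses (photon energy, fluence,
# temporal profile).

#' Describe a target composition
#'
#' Element counts per unit cell (or per arbitrary reference volume) together
#' with exactly one of a mass density or a cell volume, from which per-element
#' number densities are derived.
#'
#' @param counts named numeric vector: atoms per unit cell, names are element
#'   symbols
#' @param density_g_cm3 mass density (g/cm^3)
#' @param volume_a3 unit-cell volume (Angstrom^3)
#' @return object of class `target_composition` with derived number densities
#'   (cm^-3)
#' @examples
#' target_composition(c(C = 613, N = 193, O = 185), density_g_cm3 = 1.2)
#' @export
target_composition <- function(counts, density_g_cm3 = NULL, volume_a3 = NULL) {
  if (length(counts) == 0 || all(counts <= 0)) stop("empty composition")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector of element symbols")
  }
  counts <- counts[counts > 0]
  Z <- element_z(names(counts))
  if (is.null(density_g_cm3) == is.null(volume_a3)) {
    stop("exactly one of density_g_cm3 or volume_a3 must be given")
  }
  mass_amu <- sum(counts * ATOMIC_WEIGHTS[Z])
  if (is.null(volume_a3)) {
    if (density_g_cm3 <= 0) stop("density must be positive")
    volume_cm3 <- mass_amu / AVOGADRO / density_g_cm3
  } else {
    if (volume_a3 <= 0) stop("volume must be positive")
    volume_cm3 <- volume_a3 * 1e-24
    density_g_cm3 <- mass_amu / AVOGADRO / volume_cm3
  }
  structure(list(counts = counts, Z = Z, density_g_cm3 = density_g_cm3,
                 volume_cm3 = volume_cm3,
                 ndens_cm3 = counts / volume_cm3),
            class = "target_composition")
}

#' @export
print.target_composition <- function(x, ...) {
  cat("<target_composition>",
      paste0(names(x$counts), "_", signif(x$counts, 6), collapse = " "),
      "\n  density:", signif(x$density_g_cm3, 4), "g/cm3 | volume:",
      signif(x$volume_cm3 / 1e-24, 6), "A3\n")
  invisible(x)
}

#' Parse a plain-text target description
#'
#' Format: one `Element count` pair per line, plus either a
#' `density <value> g/cm3` or a `volume <value> A3` line. Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param text character vector of lines, a single string with newlines, or a
#'   file path
#' @return a [target_composition()]
#' @export
parse_target_spec <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text)
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n")[[1]]
  }
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  counts <- numeric()
  density <- NULL
  volume <- NULL
  for (ln in text) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tolower(tok[1]) == "density") {
      density <- as.numeric(tok[2])
    } else if (tolower(tok[1]) == "volume") {
      volume <- as.numeric(tok[2])
    } else {
      if (length(tok) < 2) stop("malformed line: ", ln)
      counts[tok[1]] <- as.numeric(tok[2])
    }
  }
  if (length(counts) == 0) stop("empty composition")
  element_z(names(counts))  # validates symbols
  target_composition(counts, density_g_cm3 = density, volume_a3 = volume)
}

#' Serialize a target composition to the plain-text format
#' @param target a [target_composition()]
#' @export
format_target_spec <- function(target) {
  c(paste(names(target$counts),
          format(target$counts, trim = TRUE, digits = 15)),
    paste("volume", format(target$volume_cm3 / 1e-24, trim = TRUE,
                           digits = 15), "A3"))
}

#' Volume-weighted solvent mixing
#'
#' Combines two compositions by volume fraction: number densities mix
#' linearly, n = (1 - x) n_protein + x n_solvent.
#'
#' @param protein,solvent [target_composition()] objects
#' @param solvent_fraction volume fraction of solvent in [0, 1]
#' @export
mix_solvent <- function(protein, solvent, solvent_fraction) {
  if (solvent_fraction < 0 || solvent_fraction > 1) {
    stop("solvent fraction must be in [0, 1]")
  }
  x <- solvent_fraction
  els <- union(names(protein$ndens_cm3), names(solvent$ndens_cm3))
  nd <- sapply(els, function(e) {
    (1 - x) * ifelse(e %in% names(protein$ndens_cm3), protein$ndens_cm3[e], 0) +
      x * ifelse(e %in% names(solvent$ndens_cm3), solvent$ndens_cm3[e], 0)
  })
  names(nd) <- els
  nd <- nd[nd > 0]
  # represent on the protein's reference volume
  vol <- protein$volume_cm3
  target_composition(nd * vol, volume_a3 = vol / 1e-24)
}

#' Define an X-ray pulse
#'
#' @param energy_kev photon energy (keV)
#' @param fluence_um2 fluence (photons per um^2, time-integrated)
#' @param shape "gaussian" or "square"
#' @param fwhm_fs full width at half maximum (fs); for a square pulse, the
#'   window length
#' @param t0_fs pulse peak (gaussian) or window centre (square); time origin
#'   of the simulation is the pulse peak by convention
#' @return object of class `pulse_profile`
#' @export
pulse_profile <- function(energy_kev, fluence_um2, shape = c("gaussian", "square"),
                          fwhm_fs = 15, t0_fs = 0) {
  shape <- match.arg(shape)
  stopifnot(energy_kev > 0, fluence_um2 >= 0, fwhm_fs > 0)
  structure(list(energy_kev = energy_kev, energy_ev = 1000 * energy_kev,
                 fluence_um2 = fluence_um2, shape = shape, fwhm_fs = fwhm_fs,
                 t0_fs = t0_fs, sigma_fs = fwhm_fs / (2 * sqrt(2 * log(2)))),
            class = "pulse_profile")
}

#' @export
print.pulse_profile <- function(x, ...) {
  cat("<pulse_profile>", x$energy_kev, "keV,", format(x$fluence_um2),
      "ph/um2,", x$shape, "FWHM", x$fwhm_fs, "fs\n")
  invisible(x)
}

#' Instantaneous photon flux of a pulse
#'
#' J(t) = F * Phi(t) with the normalized temporal profile Phi. Gaussian:
#' peak flux F / (sigma sqrt(2 pi)); square: F / FWHM inside the window.
#'
#' @param pulse a [pulse_profile()]
#' @param t_fs times (fs)
#' @return photons um^-2 fs^-1
#' @export
pulse_flux <- function(pulse, t_fs) {
  if (pulse$shape == "gaussian") {
    pulse$fluence_um2 * stats::dnorm(t_fs, pulse$t0_fs, pulse$sigma_fs)
  } else {
    ifelse(abs(t_fs - pulse$t0_fs) <= pulse$fwhm_fs / 2,
           pulse$fluence_um2 / pulse$fwhm_fs, 0)
  }
}
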