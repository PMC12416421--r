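# Fixture registry: the printed target compositions used throughout, plus
# matching run configurations. Compositions are regression-locked by tests.

.fixture_registry <- list(
  lysozyme_gd_full = list(
    counts = c(H = 13259, C = 5153, N = 1596, O = 4009, S = 80, Gd = 21,
               Na = 93, Cl = 87),
    density = 1.2,
    note = "Gd-derivative lysozyme unit cell incl. 0.1 M Gd 10% NaCl solvent"),
  lysozyme_gd_solvent = list(
    counts = c(H = 13846, C = 5143, N = 1596, O = 4300, S = 80, Gd = 21),
    density = 1.2,
    note = "lysozyme.Gd in 0.1 M Gd solution"),
  lysozyme_water = list(
    counts = c(H = 13942, C = 5056, N = 1576, O = 4386, S = 80),
    density = 1.2,
    note = "lysozyme in water"),
  light_atom_control = list(
    counts = c(H = 13942, C = 5056, N = 1656, O = 4386),
    density = 1.2,
    note = "light-atom control"),
  cno = list(
    counts = c(C = 613, N = 203, O = 185),
    density = 1.2,
    note = "pure light-atom target for cascade studies"),
  doped_cno = list(
    counts = c(C = 613, N = 193, O = 185, X = 10),
    density = 1.2,
    note = "doped target; X replaced by the requested dopant"),
  toy_one_shell = list(
    counts = c(H = 1),
    density = 0.1,
    note = "single element, single subshell; analytic tests"))

#' Composition of a named fixture
#'
#' @param name fixture name (see [make_fixture()])
#' @param dopant element symbol substituted for the `X` placeholder of doped
#'   fixtures
#' @return a [target_composition()]
#' @export
fixture_composition <- function(name, dopant = NULL) {
  fx <- .fixture_registry[[name]]
  if (is.null(fx)) {
    stop("unknown fixture: ", name, " (available: ",
         paste(names(.fixture_registry), collapse = ", "), ")")
  }
  counts <- fx$counts
  if ("X" %in% names(counts)) {
    if (is.null(dopant)) stop("fixture ", name, " needs a dopant element")
    names(counts)[names(counts) == "X"] <- dopant
  }
  target_composition(counts, density_g_cm3 = fx$density)
}

#' Write fixture target and run-configuration files
#'
#' @param name fixture name: one of `lysozyme_gd_full`, `lysozyme_gd_solvent`,
#'   `lysozyme_water`, `light_atom_control`, `cno`, `doped_cno`,
#'   `toy_one_shell`
#' @param dir output directory
#' @param dopant dopant symbol for `doped_cno`
#' @return invisibly, the paths written
#' @export
make_fixture <- function(name, dir = ".", dopant = NULL) {
  comp <- fixture_composition(name, dopant)
  fx <- .fixture_registry[[name]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpath <- file.path(dir, paste0(name, ".target"))
  writeLines(c(paste("#", fx$note),
               paste(names(comp$counts), comp$counts),
               paste("density", fx$density, "g/cm3")), tpath)
  cfg <- list(
    target = basename(tpath),
    pulse = list(energy_kev = 7.112, fluence_per_um2 = 1.75e12,
                 shape = "gaussian", fwhm_fs = 15),
    window = list(start_fs = -18, end_fs = 18),
    toggles = list(ee = TRUE, tbr = TRUE, heavy_processes = "all",
                   hydrogen_ionization = TRUE))
  cpath <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(cfg, cpath)
  invisible(c(target = tpath, config = cpath))
}
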