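# Physical constants and unit conversions. Internally the solver works in
# hartree atomic units; all user-facing interfaces use eV, fs, cm^2, g/cm^3,
# photons/um^2.

HARTREE_EV <- 27.211386245988
FS_PER_AU <- 0.02418884326509      # 1 a.u. of time in fs
AU_PER_FS <- 1 / FS_PER_AU
BOHR_CM <- 0.529177210903e-8
AU_CM2 <- BOHR_CM^2                # bohr^2 in cm^2 (2.8003e-17)
UM2_AU <- (1e-4 / BOHR_CM)^2       # um^2 in bohr^2 (3.5711e8)
CM3_AU <- BOHR_CM^3                # cm^-3 -> bohr^-3 multiply by this
AVOGADRO <- 6.02214076e23
RYDBERG_EV <- 13.605693122994

ev_to_au <- function(x) x / HARTREE_EV
au_to_ev <- function(x) x * HARTREE_EV
fs_to_au <- function(x) x * AU_PER_FS
au_to_fs <- function(x) x * FS_PER_AU
cm2_to_au <- function(x) x / AU_CM2
au_to_cm2 <- function(x) x * AU_CM2
percm3_to_au <- function(x) x * CM3_AU
au_to_percm3 <- function(x) x / CM3_AU
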