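---
title: "Methods: non-thermal collisional-radiative modelling of femtosecond X-ray damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-thermal collisional-radiative modelling of femtosecond X-ray damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`crplasma` simulates the electronic response of a homogeneous (zero-dimensional)
biomolecular target to a femtosecond X-ray pulse. Two coupled unknowns are
evolved:

* per element, the population vector $P_\xi(t)$ over ionic electronic
  configurations $\xi$ (subshell occupancy vectors), normalized to one per
  atom;
* the free-electron energy distribution $f(\varepsilon, t)$, a number density
  per unit energy, represented as a cubic B-spline expansion
  $f(\varepsilon) = \sum_k c_k B_k(\varepsilon)$.

The equations of motion are the radially averaged rate/Boltzmann system

$$\frac{dP_\xi}{dt} = \sum_\eta \Gamma_{\eta\to\xi}[f, J]\, P_\eta
  - \sum_\eta \Gamma_{\xi\to\eta}[f, J]\, P_\xi, \qquad
  \frac{df}{dt} = Q_{\rm photo} + Q_{\rm Auger} + Q_{\rm EII} + Q_{\rm TBR}
  + Q_{\rm EE},$$

with couplings $\Gamma$ for photoionization (proportional to the instantaneous
photon flux $J(t)$), Auger decay and fluorescence, electron-impact ionization
(EII, rates $\int f \sigma v\, d\varepsilon$), and three-body recombination
(TBR, bilinear in $f$). $Q_{\rm EE}$ is the pairwise Coulomb electron-electron
collision operator. Nuclear motion is outside the model's scope: on the
10 fs scale of interest the change of ionic state is the dominant damage
channel, and the frozen-geometry assumption is shared with the plasma codes
this package follows.

The free-electron distribution is strongly non-Maxwellian during the pulse:
keV photoelectron and Auger peaks coexist with an eV-scale thermal bulk. The
spline basis covers $[0, \omega]$ with logarithmically spaced knots (dense in
the thermal region) plus clusters of knots at the primary photoline energies
of the neutral ground configurations.

# Atomic data

All atomic inputs are generated internally from a configuration-average
self-consistent mean field: Slater (X$\alpha$) local exchange with the Latter
tail correction, solved on a logarithmic radial grid by two-sided Numerov
integration with node counting.

* **Thresholds and transition energies** are total-energy differences between
  SCF solutions of the two configurations ($\Delta$SCF). Using the same
  energies in the kinematics and in the bookkeeping makes the energy ledger
  close identically.
* **Exchange coefficient.** $\alpha_x$ is the one tunable constant of the
  mean field. It was calibrated once against NIST successive ionization
  energies and neutral K-shell binding energies of C, N, O and S;
  $\alpha_x = 0.80$ minimizes the bias (mean error $+0.5\%$, rms $7.5\%$ over
  that reference set) and is the package default.
* **Photoionization** uses numeric dipole matrix elements between the SCF
  bound orbital and a continuum wave computed in the same potential,
  normalized by a WKB envelope averaged over the last oscillation. Against
  Cromer-Liberman tabulations at 7.112 keV the totals agree to within about
  $+7\%$ for H through Cl, and the absorbed dose of a full protein target is
  within $+6\%$ of published dose-calculator values for the same pulse.
* **Impact ionization** uses the binary-encounter-Bethe (BEB) closed form
  $\sigma = \tfrac{S}{t+u+1}\left[\tfrac{\ln t}{2}(1 - t^{-2}) + 1 - t^{-1}
  - \tfrac{\ln t}{t+1}\right]$ with $t = T/B$, $u = U/B$,
  $S = 4\pi a_0^2 N (R/B)^2$, and a singly differential spectrum constructed
  from the same ingredients so that it integrates exactly to the total and is
  symmetric under exchange of the outgoing pair. BEB is the standard member
  of the binary-encounter family when differential oscillator strengths are
  not available.
* **Auger and fluorescence** rates are scaled tabulated level widths
  (Krause-type K widths, effective L/M widths for heavy elements) split by
  fluorescence-yield fits and distributed over final configurations in
  proportion to the available electron pairs; channels with non-positive
  ejection energy are suppressed. Lifetimes, not line structure, drive the
  dynamics at these timescales.
* **Three-body recombination** is constructed from the BEB differential
  cross-section by microreversibility. For the symmetrized kernel integrated
  over the full $(\varepsilon_1, \varepsilon_2)$ plane a factor $1/2$ accounts
  for double counting of the unordered pair. A closed two-configuration system
  held in a Maxwellian bath relaxes to the analytic Saha ratio to about
  $0.2\%$, which fixes every constant in the construction.

## Heavy elements

For $Z \ge 30$ each principal shell is collapsed to a single level (ground
occupancies e.g. 2, 8, 18, 25, 9, 2 for Gd), which reduces Gd to 400140
configurations. Two refinements keep the collapsed model quantitative:

* The collapsed (single-$l$) orbitals misrepresent the dipole couplings of
  merged p/d/f electrons. Per-shell photoionization and orbital kinetic
  energies are therefore anchored to a one-time subshell-resolved SCF of the
  neutral ground configuration ($U$ is the occupancy-weighted subshell mean).
  After anchoring, the Gd total photoabsorption at 7.112 keV is within
  $+2\%$ of the Cromer-Liberman tabulation.
* Configuration energies come from a quadratic occupancy surrogate
  $E(n) = \sum_s \varepsilon_s n_s + \tfrac12\sum_{st} J_{st} n_s (n_t -
  \delta_{st})$ — the exact frozen-orbital form of the configuration-average
  energy — least-squares fitted to SCF samples along the outermost-first
  ionization ladder and its one- and two-hole neighbourhoods (the region the
  dynamics actually visits under Auger cycling). Realistic held-out
  configurations reproduce SCF ionization thresholds to a few eV at
  hundred-eV scales. Configurations are instantiated lazily once their
  population exceeds a threshold (default $10^{-10}$).

# Discretization and conservation

Source terms and collision operators are discretized in Galerkin (weak) form
on the spline basis:

* Monoenergetic photo/Auger injections are projected with a two-moment
  correction so density and energy of each source are represented exactly;
  deposits are snapped to a dense precomputed node grid (about 1% energy
  resolution).
* EII loss/gain pairs are cached per $(B, U)$ bin (relative widths 3% in
  $B$, 25% in $U$) with the occupancy and population entering as scalar
  weights. The secondary spectrum is integrated with nodes mapped by
  $u = \ln(1 + w/B)$; an unmapped Gauss rule misses the $w \ll B$ peak at
  keV impact energies and makes the discrete secondaries far too energetic.
* TBR is evaluated on a fixed logarithmic two-dimensional quadrature grid
  (41 Simpson nodes per axis from 0.003 eV; the kernel has integrable
  $\varepsilon^{-1/2}$ support at very low energy, and truncating it biases
  the Saha balance).
* The EE operator is the isotropic energy-space Landau/Rosenbluth
  Fokker-Planck form, with the Coulomb logarithm evaluated from the
  instantaneous density and effective temperature ($2/3$ of the mean energy)
  and floored at 2.

Every $f$-side contribution carries analytic number/energy moment targets;
after assembling the raw right-hand side, a two-moment projection enforces
the targets exactly. Together with structurally identical rate expressions
on the $P$ and $f$ sides, this closes the particle ledger to rounding error
($\sim 10^{-14}$ relative in full runs) and the energy ledger (absorbed =
$\Delta$binding + free kinetic + radiated) to a few $10^{-4}$.

# Time integration

The coupled system is only moderately stiff apart from EE: Auger rates reach
a few fs$^{-1}$ against a 10 fs pulse. The solver therefore uses an adaptive
embedded Dormand-Prince 5(4) step for photo/decay/EII/TBR, and an
operator-split, linearly implicit (backward-Euler, coefficient-frozen)
update for EE after each accepted step. The implicit EE update is L-stable,
which is essential: at solid density the thermal-bulk diffusion time is
$\sim 10^{-5}$ a.u., five orders below the pulse scale. The EE splitting
error is bounded by the maximum step (default 0.2 fs); number and kinetic
energy are pinned exactly by the same moment projection. Step-size underflow
is reported as a stiffness failure with the time reached.

The production simulations are deterministic: no random numbers enter the
pipeline (the Monte Carlo used in the test suite is a test oracle with an
explicit seed).

# Cascade partition

Auxiliary distributions $g_n(\varepsilon, t)$ with $\sum_n g_n = f$ attribute
free-electron density to the primary process that seeded each lineage
(element $\times$ photo/Auger channels, plus optional tracers). The
attribution rules follow the stated decomposition: photo/Auger sources feed
their own channels; EII applies the same linear operator to each channel, so
secondaries are credited to the impactor's channel in proportion to its
share $g_n(\varepsilon)/f(\varepsilon)$ of the impacting density; TBR sinks
are share-weighted and each deposit is split evenly between the two consumed
electrons' channels. In the implicit EE substep all channels are transported
by the same coefficient-frozen operator, which preserves the sum rule
identically; the small cross-channel energy-exchange term of the symmetrized
bilinear form is neglected there (its density attribution is zero by
construction). The sum rule is additionally repaired at orchestration
boundaries by distributing any residual in proportion to channel magnitude;
in practice the residual is at rounding level.

Tracers are injected either as an impulse (default density $10^{-8}$ of the
total atom density — small enough for linear response, large enough to
condition the channel share) or at a rate proportional to the pulse
intensity scaled to a multiple of the undamaged target's photoionization
rate.

# Numerical choices and degenerate inputs

* Spline order 4 (cubic); small negative undershoots of the spline
  representation are tolerated during integration and clipped only in
  observable evaluation, with a warning when they exceed $10^{-6}$ of the
  total density. Preserving moments is more valuable than pointwise
  positivity.
* Polynomials cannot represent the $\sqrt{\varepsilon}$ behaviour of an
  equilibrium distribution at $\varepsilon \to 0$. The resulting
  boundary-panel artifact sets the effective stationarity level of the
  discrete EE operator: the projected Maxwellian's residual sits at a few
  percent of a comparable non-equilibrium flux (concentrated in the first
  panel), while the operator evaluated on analytic Maxwellian data is exact
  to quadrature accuracy. The affected region carries negligible density,
  so the impact on observables is below the solver tolerance.
* The energy grid is static per run (log-dense thermal region plus photoline
  clusters); `regrid()` provides constrained moment-preserving transfer
  between bases for workflows that need it. For the pulse parameters studied
  here, halving the solver tolerance changes the +10 fs carbon charge by
  well under 1%, which is the convergence criterion used in place of a
  prescribed integrator.
* Bare nuclei are valid configurations (zero-orbital SCF); one-electron ions
  are solved exactly (hydrogenic).
* Dopant ions (e.g. a Zn$^{2+}$-like dopant) are modeled as neutral atoms of
  the dopant element; at keV photon energies the inner-shell cross-sections
  that drive damage seeding are insensitive to the outer-charge difference.

# Problem sizes

Default production runs use about 60 logarithmic knots (basis size
$K \approx 75$ after photoline clustering), an 800-node deposit grid, 41
TBR quadrature nodes per axis, and relative step tolerance $10^{-6}$. The
routine test suite runs the same physics at reduced resolution (about 45
knots, tolerance $10^{-5}$, reduced TBR grids) and smaller windows; these
sizes are stated in the test helpers. Full-target runs (five to eight
elements, $10^3$-$10^4$ active configurations) complete in minutes on one
core; the large collapsed Gd configuration space is handled by the lazy
surrogate machinery described above.

# What the synthetic conditions do and do not show

The bundled target compositions reproduce printed unit-cell stoichiometries
of a Gd-derivative lysozyme system, its solvent variants, and generic doped
C/N/O targets at biomolecular density (1.2 g cm$^{-3}$; the density is
derived from composition mass when no cell volume is supplied). Passing
tests on these targets validates the kinetics, bookkeeping and observables
under realistic compositions and pulse parameters. They do not validate
spatial effects absent from a zero-dimensional model: beam-profile
inhomogeneity, crystal-boundary electron escape, local damage environments
around heavy sites, bound-to-bound electron transport between neighbouring
atoms, or ionization-potential depression. Those are known limitations of
the model class, not of the implementation.

# Known limitations

* The mean field is a local-exchange average-of-configuration model;
  individual thresholds carry $\sim$5-15% errors relative to spectroscopic
  data, which propagates into few-percent-level systematic offsets in
  charge-state observables.
* Fine structure and resonant bound-bound photoexcitation near absorption
  edges are not modeled; photon energies should be chosen away from
  resonances when scanning edges.
* The collapsed-shell surrogate for heavy elements is accurate in the region
  the dynamics visits; exotic far-off-manifold configurations (deeply
  core-stripped with full valence) carry larger energy errors but acquire no
  population.
* Relativistic corrections are neglected throughout; for the K shells of
  lanthanides this matters at the several-percent level but those shells are
  not ionized at the photon energies studied.
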