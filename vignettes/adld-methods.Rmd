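---
title: "Methods and design of the adld package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the adld package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adld)
```

# The scientific problem

London dispersion is the universally attractive force produced by
correlated instantaneous dipole fluctuations.  In any pairwise
semiclassical treatment the total dispersion energy of a molecule is a sum
over atom pairs,

$$E_\mathrm{tot} = \sum_{A<B} E_{AB}, \qquad
  E_{AB} \approx -\frac{C_6^{AB}}{r_{AB}^6} - \frac{C_8^{AB}}{r_{AB}^8},$$

which makes an *atomic* decomposition natural: assigning half of every pair
term to each of its two atoms,

$$\varepsilon_A = \tfrac12 \sum_{B \ne A} E_{AB},$$

yields per-atom contributions that sum to the total by construction.  This
half-assignment is the pairwise analog of decomposition schemes that split
electron-pair correlation energies between the two participating electrons
and then map orbital contributions onto atoms via a population analysis.
`adld` does not compute such wavefunction-level decompositions; externally
computed per-atom values can instead be imported through the interchange
table (`read_contributions()`) and fed to the same aggregation and
visualization machinery.  Everything downstream of the pair matrix —
fragments, dimer splits, difference maps, densities, mass-scaling fits —
is agnostic to where the per-atom values came from.

# The two engines and their assumptions

**London engine.**  The classic combination rule
$C_6 = \tfrac32\,\alpha_A\alpha_B\,\frac{I_A I_B}{I_A+I_B}$
with tabulated atomic static polarizabilities (Å³) and first ionization
energies (eV), and the undamped pair energy $-C_6/r^6$.  Assumptions: the
atoms retain their free-atom response inside the molecule, and no pair gets
close enough for the missing damping and higher multipoles to matter.  It
is the engine of choice for asymptotic and scaling arguments precisely
because it has *no* environment dependence: monomer energies are strictly
independent of the partner, and $E(2R)/E(R) = 2^{-6}$ holds identically
for a pair.

**Coordination-number (cnd) engine.**  Each atom's environment is measured
by the smooth logistic count
$\mathrm{CN}_A = \sum_{B\neq A} \left[1 + e^{-k_1(k_2(R_A+R_B)/r_{AB}-1)}\right]^{-1}$
over packaged covalent radii, homoatomic reference $C_6$ values tabulated
against reference CNs are combined geometrically and Gaussian-interpolated
(width $k_3$), $C_8 = 3 C_6 \sqrt{Q_A Q_B}$ with
$Q_A = \tfrac12\sqrt{Z_A}\,\langle r^4\rangle/\langle r^2\rangle_A$, and
the pair energy is Becke–Johnson damped.  Assumptions: dispersion
coefficients depend on geometry only (through CN), and the published
damping presets transfer to the systems at hand.  The parameter tables
adopt the published constants of the D3 family of models, stored with
their sources in `inst/extdata/params/` and never hard-coded in logic;
bit-exact agreement with any particular released implementation is
explicitly not a goal (our CN→C6 interpolation uses homoatomic references
with geometric combination rather than full pair-reference tables).

One numerical subtlety is worth recording: the logistic counting function
never decays below $1/(1+e^{k_1}) \approx 1.1\times10^{-7}$, so without
intervention every atom in the universe would contribute to every CN.  We
therefore zero the count beyond a 20 Å neighbour cutoff (packaged as
`cn_cutoff_A`), the same kind of thresholding the reference D3
implementation applies.  The induced discontinuity is of the order of the
floor itself and is invisible at the accuracy level of these models; it is
what makes monomer properties *exactly* separable at large distances.

# Charge scaling

Geometry-only dispersion models cannot distinguish Li from Li⁺.  The
package models charge sensitivity through a deliberately simple,
contract-governed layer: a scaler $s(q)$ multiplies each atom's C6 input,
with the contract $s(0) = 1$ exactly, $s$ strictly decreasing for $q > 0$,
and $s > 0$ on the physical range.  The default is the one-parameter
exponential $s(q) = e^{-bq}$ with
$b = \ln[\alpha(\mathrm{Li})/\alpha(\mathrm{Li}^+)] \approx 6.75$, chosen
so the packaged Li⁺ polarizability is reproduced at $q = +1$.  This is a
modelling choice, not a fit to any reference data beyond that single
anchor: more sophisticated charge models couple the scaling to a
self-consistent electronegativity equilibration, which is out of scope
here.  Published charge-aware models also show an abrupt short-range
feature caused by discontinuous switching of C6 coefficients along a
dissociation coordinate; our smooth exponential deliberately does not
emulate that non-smoothness.

Running an engine *without* charges never consults the scaler, so the
"charge-blind" behaviour of geometry-only models is reproduced by
construction rather than by setting $q = 0$ — though doing the latter
gives bitwise-identical results, which the tests assert.

# Dispersion densities

For visualization, atomic contributions are smeared with normalized
Gaussians:

$$\rho_\mathrm{disp}(r) = \left(\frac{\alpha}{\pi}\right)^{3/2}
  \sum_A \varepsilon_A\, e^{-\alpha (r - R_A)^2}.$$

The prefactor deserves a prominent note.  With $(\alpha/\pi)^{3/2}$ each
atom's term integrates analytically to $\varepsilon_A$, so the field
integrates to the total dispersion energy — a property the quadrature
tests rely on.  Some published figures instead use the prefactor
$(\pi\alpha)^{-3/2}$, which coincides with the normalizing constant only
at $\alpha = 1$ and otherwise rescales the field by $\alpha^3$.  We treat
the conserving form as the definition and provide
`prefactor = "plain"` for users who need to reproduce figure scales built
on the other convention.

Units of $\alpha$ are Å⁻², consistent with Å coordinates throughout the
API.  Defaults: $\alpha = 0.5$ for single-structure maps and $0.3$ for
difference maps (softer smearing reads better when positive and negative
lobes interleave), grid spacing 0.2 Å, padding 4 Å.  Difference maps are
anchored to the *first* structure's coordinates by default, with an option
for the second; the choice is arbitrary and only affects where the
Gaussians sit, not the weights.  Cube files are written in bohr with the z
index fastest, per the format convention; values are written as-is
(kcal mol⁻¹ Å⁻³) with 8 significant digits so round-trips are faithful
well beyond plotting accuracy.  A guard refuses grids beyond 512³ points
unless the spacing/padding is adjusted.

# The dimer split and its two conventions

For a two-fragment system, `supramolecular_split()` reports
$E_\mathrm{tot} = E_1 + E_2 + E_\mathrm{int}$ under two conventions:

* **pair-classified** (default): pairs computed on the full system are
  classified by fragment membership.  The reported $E_\mathrm{tot}$ is
  defined as the sum of the three classes, so the identity is *exact as
  summed* (and agrees with the engine's own upper-triangle total to
  floating-point reproducibility, asserted at 1e-10 relative).
* **isolated-monomer**: $E_1$, $E_2$ are recomputed on each monomer alone
  and are therefore independent of the separation; $E_\mathrm{int}$ is the
  remainder.  Monomer geometries are kept frozen at their in-dimer
  coordinates — re-optimizing them would mix geometric relaxation into a
  decomposition that is about dispersion assignment, and would also make
  the split depend on an external optimizer.

For the London engine the conventions coincide (no environment
dependence); for the cnd engine they differ exactly by the CN shift the
partner induces in the monomers, which the tests verify by direct
recomputation.

# Mass-scaling analysis

The regressions are ordinary least squares with an intercept (a
no-intercept option exists, since published fits do not always state their
convention): `E_tot ~ M1*M2/R` (gravitational-like), `E_tot ~ M1^2+M2^2`
(generalized; slope β in kcal mol⁻¹ amu⁻², intercept γ in kcal mol⁻¹,
absorbing the average intermolecular contribution), `E1+E2 ~ M1*M2`,
`E_int ~ M1*M2/R` (a diagnostic where *low* R² is the expected finding)
and `E_tot ~ M1+M2` (the linear regime of large systems, where
short-range neighbour pairs dominate and scale with atom count rather
than its square).  R² is $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ about the
mean; a constant response reports R² = 0 with a warning (diagnostic
context) while a constant predictor is a hard error.  OLS itself is
delegated to `stats::lm`; the test suite checks every fit against a
closed-form normal-equations oracle at 1e-10.

The chain of reasoning the diagnostics probe: for a compact monomer whose
pair distances vary within a narrow range, $E_1 \propto (\sum_A
\alpha_A)^2 \propto M_1^2$ (mass tracks polarizability for neutral
atoms); if intermolecular dispersion is small compared to intramolecular,
$E_\mathrm{tot} \approx \beta(M_1^2+M_2^2)+\gamma$; and when monomer
masses are equal, $M_1^2+M_2^2 = 2M_1M_2$, collapsing the generalized law
onto the gravitational-like one at a common separation (the factor-2R slope
relation is asserted in the tests).

# Synthetic generators: what they emulate and what they do not

All test inputs are generated in code; nothing is downloaded.

* `make_ring` / `make_chain` / `make_simplex`: closed-form scaffolds whose
  pair distances are known analytically (chord lengths, equal edges) —
  the oracles for geometry and for the simplex closed form
  $E_1 = -C_6\binom{n}{2}/d^6$.
* `make_cluster`: rejection-sampled random clusters with a minimum pair
  distance, used for property-based conservation and oracle-equivalence
  tests.  Deterministic under its seed, and it restores the caller's RNG
  state.
* `make_shell`: Fibonacci-sphere shells.  With the default radius
  $2.0\,(n/12)^{1/3}$ Å the family has constant volume density, which is
  what keeps $E_1/(\sum\alpha)^2$ flat (to well under the 25% fixture
  tolerance) across $n = 8, 12, 16$.  A fixed-radius family was
  considered and rejected: crowding the same sphere makes nearest
  neighbours dominate the $r^{-6}$ sum and the ratio drifts roughly as
  $n^2$, which tests the fixture rather than the physics.
* `make_dimer_benchmark`: five equal-mass homodimers of increasing shell
  size at narrowly varying separations (6.0–7.0 Å) plus three
  hetero-dimers with ≥3× monomer mass ratios.  It is built to have the
  *structure* of a representative dimer study — intramolecular dominance,
  equal-mass subset following the gravitational-like law, heteromass
  dimers breaking it while the generalized law survives — not to
  reproduce any published geometry or energy.

Passing tests on these fixtures therefore demonstrate internal
consistency, exact conservation laws, and the qualitative mass-law
structure.  They do not demonstrate chemical accuracy for real molecules:
the shells and clusters are not minima of any potential, all-carbon
compositions sidestep heteroatom parameter coverage, and the London
engine's free-atom polarizabilities overestimate in-molecule dispersion.
Published R²/β/γ values from studies on real dimer sets require those
studies' geometries and reference energies and are out of scope here.

# Numerical choices and problem sizes

* Unit constants are fixed: 1 Å = 1.8897261254578281 bohr, 1 hartree =
  627.5094740631 kcal/mol, 1 hartree = 27.211386245988 eV.  Atomic units
  are confined to engine interiors and the cube writer.
* Conservation and oracle tests run on ~100 random clusters of 4–10 atoms
  plus 50-atom clusters; density quadrature uses 0.2 Å spacing with
  $5/\sqrt\alpha$ padding (about 10⁶ grid points per field).  These sizes
  keep the full suite in seconds while exercising every code path; all of
  them are the package's own choices and scale up trivially.
* Degenerate inputs: single atoms give empty pair sums (zero totals, zero
  CN); a 1×1×1 cube grid is legal; empty fragment selections sum to zero
  mass; two-record regressions are refused (underdetermined).
* The r⁻⁶ decay check uses the London engine because it isolates the C6
  asymptote exactly; in the cnd engine the C8/r⁸ term still contributes
  ~1% at 20 Å, which is physics, not error.

# Known limitations

* Two-body terms only: the three-body Axilrod–Teller–Muto contribution is
  omitted.  It matters for dense clusters and lattice energies at the
  few-percent level.
* No self-consistent charge model: the exponential scaler is a contract
  implementation, not an electronegativity-equilibration treatment, and
  it does not reproduce abrupt short-range C6 switching.
* Element coverage is the packaged table (H–Ne plus Li⁺); extending it is
  a matter of appending rows to the documented parameter files.
* No periodic boundary conditions or lattice sums; systems are molecular.
* XYZ and cube are the only geometry/volumetric formats; PDB/CIF/SDF are
  out of scope.
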