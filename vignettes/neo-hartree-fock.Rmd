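---
title: "Multicomponent Hartree–Fock with local density fitting: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicomponent Hartree-Fock with local density fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`neoscf` implements nuclear–electronic orbital restricted Hartree–Fock
(NEO-RHF): selected nuclei — in this package protons or deuterons — are
promoted from classical point charges to quantum particles expanded in
Gaussian basis sets, alongside the electrons.  The multicomponent
Hamiltonian contains the electronic terms, the quantum nuclei's kinetic
energy scaled by `1/m`, their attraction/repulsion against the remaining
classical point charges, the electron–proton Coulomb coupling and the
proton–proton Coulomb repulsion.  The reference wave function is a product:
a closed-shell electronic determinant times one spatial orbital per quantum
proton.

Assumptions baked into this reference:

* **Distinguishable quantum nuclei.** Each proton has its own Fock equation
  over its own centre's basis; nuclear–nuclear exchange is neglected (it is
  far below the energy convergence thresholds at typical proton overlaps).
  A "combined" single-Fock mode over the union basis exists for
  starting-guess experiments; see *Limitations*.
* **Fixed nuclear basis centres.** Nuclear basis functions sit at the
  classical positions of the quantised atoms; no basis-centre optimisation.
  Single-point energies on given geometries are the use case.
* **Closed-shell electrons.** The electron count must be even.
* **Quantised nuclei are removed from the classical point-charge list**, so
  every interaction involving them flows through their densities — nothing
  is double counted.

The stepwise driver alternates: (1) nuclear SCF with the electronic density
frozen — in distinguishable mode each proton's Fock is static, so this is a
diagonalisation per proton; (2) electronic SCF with the proton densities
frozen.  Coupling potentials refresh once per macro-iteration, after the
complementary subsystem has converged.  The macro loop starts on the nuclear
side, seeded by the electronic guess.  The assembled total energy is

```
E = E_elec[D_e] + sum_p Tr(D_p h_p) + E_pp + E_coupling + E_classical
```

with the electron–proton coupling counted exactly once, recomputed from the
final densities through a single designated route (the electronic-side fit,
or exactly in direct mode) so either subsystem's bookkeeping yields the same
number.

## Density fitting

All Coulomb and exchange builds can run through the resolution of the
identity with the Coulomb metric.  The expansion coefficients minimise the
Coulomb-norm (electric-field-weighted) least-squares error of the fitted
density; with one shared fitting basis per contraction the robust-fit
correction terms collapse onto the plain RI expressions, so fitted Coulomb
energies are wrong only to second order in the fitting residual.  Exchange
uses occupied-orbital half-transformed 3-index integrals.  Metric solves go
through a pivoted symmetric eigen-factorisation with a relative eigenvalue
floor of 1e-10 — even-tempered ladders are near-singular by construction
and the floor simply discards directions the double-precision metric cannot
resolve.

The electron–proton coupling is fitted from both sides, as the stepwise
algorithm requires:

* inside the **electronic** SCF, the frozen proton densities are expanded in
  the electronic JK fitting basis;
* inside the **nuclear** SCF, the frozen electronic density is expanded in
  the proton-centred even-tempered fitting ladders.

Two non-obvious consequences drove design choices here:

* The electronic JK sets must also represent *proton* pair densities, whose
  exponents reach twice the largest nuclear exponent — far tighter than any
  electronic product on a hydrogen.  `basis_assignment()` therefore augments
  the JK ladders on quantised sites up to `2 * alpha_max(nuclear)`.
* The error of the nuclear-side coupling fit is a *product* of two
  residuals: the proton density's radial fitting residual times the (large,
  irreducible) residual of the molecular electronic density in proton-site
  functions.  Radial density of the nuclear fitting ladder is therefore the
  accuracy knob, which motivates the default below.

## Local exchange fitting

The occupied electronic orbitals are localised to intrinsic bond orbitals
(IBOs): intrinsic atomic orbitals are built from a bundled minimal
reference basis, and Jacobi 2×2 sweeps maximise the fourth power of the
per-atom charges, with a fixed sweep order and sign convention for
determinism.  Each orbital then receives an AO domain and a fitting domain,
and its exchange contribution is assembled with a per-domain metric solve.
The localised half-transform runs over the *full* AO index with the LMO
coefficients; the domain restricts the two free indices (AO and fitting
function).  Restricting the transformed index as well would truncate
orbital tails and produce first-order, multi-kcal/mol errors even on the
water dimer, which is why the package rejects that reading.

Domains are defined by three controls (`neo_config()` arguments):

* `charge_threshold` (default 0.05): atoms carrying at least this IAO
  charge form the core of the domain;
* `fit_extension` (default 1): bonded-neighbour shells added to the core
  (bond = distance below 1.2× the covalent-radius sum);
* `domain_radius` (default 8 bohr): every atom within this distance of a
  core atom joins the domain.  The distance term is essential: exchange
  couples across *non-bonded* contacts (hydrogen bonds) through diffuse
  functions, so a purely bond-topological rule leaves multi-kcal errors on
  something as small as the water dimer.  For small molecules the distance
  rule makes domains span the whole system — exactly the "far-reaching
  domains" regime expected for small and medium molecules — and genuine
  savings appear for extended chains.

With `charge_threshold = 0` the domains are full and the local build
reproduces the conventional fitted exchange to machine precision; the test
suite asserts both this limit and the cal/mol-scale accuracy of default
domains on a six-monomer hydrogen-bonded chain.

## Tunable parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| proton / deuteron mass | 1836.15267343 / 3670.48296788 m_e | CODATA values |
| nuclear AO basis | even-tempered 8s8p8d, `alpha_max` 32 bohr^-2, ratio 2 | covers proton ground-state widths (effective exponents ~10–20) with margin on both ends; user-overridable by a Gaussian94 file (e.g. a PB4-F2 file, which this package does not bundle) |
| nuclear fitting basis | even-tempered 18 per l up to f, `alpha_max` 64, ratio 1.42 | same exponent window [0.125, 64] as a classic 10-per-l ratio-2 ladder, at doubled radial density.  The coupling-fit error scales with the proton-density radial residual (see above); ratio-2 ladders leave ~1e-4 Eh-scale errors on the Zundel fixture, the denser ladder ~1e-5.  The angular ceiling f and the 64 bohr^-2 ceiling are kept |
| electronic thresholds | 1e-8 au on energy, density and gradient, all three simultaneously; macro threshold 1e-7 Eh | the "tight" profile; a "loose" profile (1e-7/1e-6) for larger systems |
| DIIS | history 10, extrapolation from the second iteration | standard convergence accelerator settings |
| metric floor | 1e-10 relative | see *Density fitting* |
| integral-direct screening | Schwarz × density-element, 1e-10 | the default for nuclear iterations; proton densities are strongly local so the screening is effective |
| four-index cap | 40 000 AO pair products | keeps the exact-integral oracle desk-scale |

A numerical detail worth recording: the DIIS linear system is normalised by
the largest error overlap and solved by SVD pseudo-inverse.  Near
convergence the raw error-overlap block is ~1e-14 next to the constraint
row; an unscaled `solve()` rejects it as singular and the accelerator
silently degrades to plain Roothaan steps, which stalls tightly-converged
nuclear problems.

## Bundled and synthetic basis sets

The package ships STO-3G (H, He, C, N, O, F) and 6-31G (H, O) as plain-text
Gaussian94 files; STO-3G doubles as the minimal reference for the intrinsic
atomic orbitals.  Beyond these, the electronic sets are *synthetic*:
`sv-synth` (split-valence + polarisation quality) and `tz-synth` (one more
s/p shell and, on hydrogen, a second p and a d shell).  The JK fitting sets
`tz-synth-jkfit` / `qz-synth-jkfit` are generated by a product-span rule:
for each angular momentum `L` the ladder covers the exponent range of all
AO pair products with `|la-lb| <= L <= la+lb`, with geometric ratio 2.2
(TZ level) or 1.7 (QZ level), up to `L = 4`.  These stand in for the
correlation-consistent and JK-fit families, which are not bundled; all
quantities the package reports are internally consistent comparisons
(fitted versus exact on the *same* basis), so the stand-ins affect scale,
not meaning.

## Fixtures: what they emulate and what they do not

`generate_fixture()` provides deterministic geometries: `h2`, `hehplus`,
`water`, `water_dimer`, the Zundel cation `h5o2+` (the canonical
strong-NQE benchmark: a proton shared between two waters), the Eigen cation
`h9o4+`, `gc_pair_toy` (a doubly hydrogen-bonded carboxylic dimer standing
in for a base pair with two transferable protons) and `chainN` — a
hydrogen-bonded (HF)_N zigzag chain as the scalable monomer-chain model.
With a nonzero seed a deterministic perturbation of at most 0.01 bohr per
coordinate lifts exact symmetries.

These are idealised, hand-built geometries, not optimised structures: bond
lengths and angles are chemically reasonable but not stationary points of
any potential surface.  Tests passing on them demonstrate the correctness
and internal consistency of the machinery (fitting errors, reductions,
invariances, oracle agreement) — they do not reproduce literature energies
for optimised clusters, chains of quinonediimine molecules, or DNA
fragments, which are far beyond desk scale for the in-tree integral engine.
Problem sizes used by the shipped checks, chosen to keep everything
runnable on one CPU in minutes: the Zundel comparisons run 116 electronic
AOs with the 8s8p8d proton basis in the acceptance script and a 6s6p ladder
in the test suite; the chain comparison uses six HF units at `sv-synth`
(114 AOs); the guess experiment a 6s6p ladder (120 union functions).

## Degenerate and edge inputs

Zero quantum nuclei reduces the driver to plain (fitted or exact) RHF on
the same code path; zero electrons (bare quantum protons in a classical
field) is supported and exercised by a dense-diagonalisation oracle test.
Duplicate fitting functions, near-singular metrics and singular overlaps
are handled by the eigenvalue floors; coincident basis centres and point
charges are legal (integrals stay finite).  Empty localisation domains
raise an error naming the orbital; macro non-convergence and SCF
non-convergence raise errors carrying the iteration trace, and
sign-alternating macro energies trigger a warning suggesting tighter
micro-thresholds.

## Known limitations

* **Combined (single-Fock) nuclear mode is an experiment, not a production
  path.**  All protons share one Fock built as a high-spin determinant
  (`J - K`, unit occupations) so each proton's Coulomb self-interaction
  cancels exactly.  The fixed-point map of this formulation is close to
  marginally stable for compact unit-charge densities — the
  occupied→virtual response gain `[(vi|vi) - (vv|ii)]/gap` approaches one —
  so plain iteration barely contracts.  DIIS converges it, but slowly, and
  both starting guesses share that slow phase: the block-versus-full guess
  iteration ratio the acceptance script measures is far
  below the fold-reductions reported for production multicomponent codes,
  even though the block guess demonstrably starts every centre occupied
  while full diagonalisation piles protons onto one centre.  This is the
  same convergence pathology that motivates the distinguishable-particle
  default in the first place.
* Angular momentum is capped at g (l = 4); basis sets with h functions are
  not supported.
* Electronic reference is closed-shell RHF only; no gradients, no
  correlated multicomponent methods — higher-level electronic energies are
  consumed as plain numbers by the composite correction
  `nqe_correction()`.
* Inter-proton Coulomb potentials are frozen within a nuclear micro-cycle
  and refreshed each macro-cycle; this is a convention of this
  implementation (the alternatives differ at the macro-convergence level,
  not in the converged answer).
* The 0.01-density-contour style of published volumetric plots is not
  reproduced; cube files carry the raw density and leave contouring to the
  viewer.
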