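# neoscf — nuclear–electronic orbital Hartree–Fock with local density fitting

`neoscf` computes nuclear quantum effects (NQEs) — zero-point motion and
delocalisation of protons — by treating selected hydrogen nuclei as quantum
particles in Gaussian basis sets on the same footing as the electrons.  It
is aimed at molecular modellers who want proton quantum effects (hydrogen
bonds, proton transfer, isotope effects in e.g. DNA base pairs) without
path-integral dynamics: one multicomponent SCF calculation per geometry.

## The method

The system is split into `N_e` electrons plus `N_n` quantum nuclei
(protons/deuterons) and `N_c` classical point-charge nuclei.  The reference
wave function is a product of an electronic closed-shell determinant and one
orbital per quantum proton (distinguishable-particle treatment, no
nuclear–nuclear exchange).  Two coupled Roothaan–Hall problems result, with
Fock operators

    F^e = h^e + J^e[D^e] - 1/2 K^e[D^e] - sum_p J[D^p]
    F^p = T/m_p + V_cl + sum_{p'!=p} J[D^{p'}] - J[D^e]

solved stepwise: a nuclear SCF with the electronic density frozen, then an
electronic SCF with the proton densities frozen, iterated until the total
energy is macro-converged (default 1e-7 Eh; micro-thresholds 1e-8 au on
energy, density and gradient simultaneously, DIIS after the first iteration
with ten stored Fock matrices).

Every Coulomb/exchange build can run through robust density fitting
(resolution of the identity with the Coulomb metric), in which four-index
integrals `(mu nu|lam sig)` are reduced to the 2-index metric `J_AB` and
3-index integrals `(mu nu|A)`:

    J_mu_nu ~= sum_A (mu nu|A) d_A,      J2 d = B,   B_A = sum D_mu_nu (mu nu|A)

and exchange is assembled from half-transformed 3-index integrals.  The
electron–proton Coulomb coupling is fitted too: the proton densities in the
electronic JK basis inside the electronic SCF, the electronic density in
proton-centred even-tempered ladders inside the nuclear SCF.  Local density
fitting (LDF) additionally localises the occupied electronic orbitals to
intrinsic bond orbitals and restricts each orbital's exchange contribution
to per-orbital AO/fitting domains.  A composite correction

    E = E_X + (E_NEO-HF - E_HF)

adds the resulting NQE to any electronic single-point energy `E_X`.

An exact ("integral-direct") mode with full four-index tensors provides the
in-tree reference that all fitted modes are measured against.  The integral
engine (McMurchie–Davidson, s–g functions, arbitrary particle mass and
charge) is part of the package and is validated against independent
quadrature oracles in the test suite.

## Worked example

Water with both protons quantum, split-valence-quality electronic basis,
density-fitted mode:

```r
library(neoscf)
sys <- generate_fixture("water", quantum = "all-H")
cfg <- neo_config(mode = "df", e_basis = "sv-synth", jkfit = "tz-synth-jkfit")
res <- run_neo(sys, cfg)
print(res)
#> NEO-RHF result (df mode)
#>   E_total      =   -75.880768392316 Eh
#>   electronic   =   -73.679640805728
#>   nuclear      =     8.784315724781 (sum over 2 protons)
#>   proton-proton=     0.344050717204
#>   coupling     =   -11.329494028573
#>   classical    =     0.000000000000
#>   macro cycles = 11, converged = TRUE, 3.5 s

nqe_delta(sys, cfg)$delta * 627.509474
#> [1] 50.34   # kcal/mol of proton zero-point-like energy (two protons)
```

`E_total` is the multicomponent total energy: the electronic term is the
internal RHF energy of the electrons, `nuclear` the protons' kinetic plus
classical-frame energy, `coupling` the (attractive) electron–proton Coulomb
energy counted once, and `proton-proton` the Coulomb repulsion between the
two quantum protons.  The NQE of ~25 kcal/mol per proton is the well-known
Hartree–Fock-level overestimate of proton zero-point energy; differences
between geometries (barriers, isotope shifts) are the meaningful output.

Proton densities export as Gaussian cube files
(`export_cube(res, proton = 2, "proton.cube")`), geometries read from XYZ
files (`read_xyz("file.xyz", charge = 1, quantum = "all-H")`), and a thin
command-line wrapper lives at `inst/cli/neoscf.R`.

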