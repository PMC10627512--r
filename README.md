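# saxsrb

Solution small-angle X-ray scattering (SAXS) analysis and restrained
rigid-body modelling for multi-chain protein complexes that partially
oligomerize in solution.

## What problem this package solves

A SAXS curve measured on a purified protein complex often disagrees with
the crystal structure for two entangled reasons: the domains move in
solution, and a fraction of the particles self-associate, so the measured
intensity mixes monomer and oligomer scattering. `saxsrb` was built for
this situation — its reference use case is a C2-symmetric heterohexameric
toxin–antitoxin kinase complex whose solution data show an apparent
maximum dimension far above the crystal diameter and a forward scattering
corresponding to roughly a dimer of hexamers.

The modelling chain, in the field's standard notation:

* **Guinier analysis**: ln *I* ≈ ln *I*₀ − *q*²*R*g²/3 over the
  self-consistent window *qR*g ≤ 1.3, giving *R*g and *I*₀.
* **Molar mass** from forward scattering on absolute scale:
  *M* = *I*₀*N*A/(*c* Δρm²), Δρm = 2.00×10¹⁰ cm g⁻¹.
* **Indirect Fourier transform** to the pair distance distribution
  *p*(*r*) with smoothness regularization, non-negativity and automatic
  *D*max/α selection; normalized Kratky transform
  (*qR*g)²*I*/*I*₀ vs *qR*g for compactness.
* **Debye forward model** on a coarse-grained structure (average excess
  scattering length per non-hydrogen atom, Gaussian smearing σ = 1 Å,
  optional hydration dummy-atom shell):
  *P*(*q*) = e^(−*q*²σ²) Σᵢⱼ *b*ᵢ*b*ⱼ sinc(*q dᵢⱼ*) / (Σ*b*)².
* **Partial oligomerization** via the two-parameter structure factor
  *S*(*q*) = 1 + (*N*−1) sin(*qD*)/(*qD*) in the decoupling
  approximation *I* ∝ *P* + ⟨*A*⟩²(*S*−1).
* **Restrained rigid-body refinement**: multi-start simulated annealing
  (best of 10 runs by reduced χ², deterministic under a seed) over
  per-body rigid transforms of the C2 asymmetric half — the 3+1+3 body
  scheme of the hexamer half ships as `hipbst_scheme()` — with harmonic
  distance restraints, a soft excluded-volume term, and simultaneous
  refinement of *N* and *D*.
* **Synthetic data**: bead-model generator and noise model reproducing
  the assumed data-generating process, for end-to-end recovery testing.
* **Motif classifier** for Ser/Thr-kinase Gly-rich-loop phosphosites
  (SΨS, (S/T)ΨT, (S/T)ΨP, SΨQ, ΨΨT; Ψ = Ile/Leu/Val).

## Worked example

Generate a partial-dimer scenario at the package's default study
conditions (heterohexamer-like bead model, oligomer truth N = 1.8,
D = 80 Å, 2% noise), analyse the curve model-free, then refine:

```r
library(saxsrb)

rs <- recovery_suite(scenario_spec(seed = 11,
                                   noise = noise_model(0.02, 1e-4, 42)))

guinier_fit(rs$curve)
#> Guinier fit: Rg = 63.77 A, I0 = 1.806 (50 pts, q in [0.0080, 0.0203], R^2 = 0.9729)

ift(rs$curve)
#> p(r): Dmax = 201.1 A, Rg = 63.33 A, I0 = 1.795, chi2_red = 1.005 (alpha = 2.92e+10)

fit <- refine_rigid_body(rs$half, rs$scheme, rs$curve,
                         fit_config(n_runs = 10, seed = 1,
                                    max_iter = 1500, cool = 0.985),
                         axis = rs$axis,
                         oligomer_start = oligomer_model(1.5, 100),
                         start_state = rs$start_state)
fit
#> saxs_fit: chi2_red = 1.069 (best of 10 runs), N = 1.812, D = 79.2 A
#>   restraint = 0.08773, excluded volume = 0.002053, scale = 0.9879
```

Reading the numbers: the apparent Rg (~64 Å) and Dmax (~200 Å) are far
above the single-hexamer values because the sample partially dimerizes —
exactly the signature the refinement resolves into a hexamer model plus a
structure factor with N ≈ 1.8 copies at D ≈ 80 Å inter-particle distance,
recovering the generator's truth. The reduced χ² near 1 says the model
fits to within the noise.

A thin command-line front end over the same functions is installed at
`inst/cli/saxsrb.R` (`refine`, `simulate`, `analyze`, `classify`
subcommands).

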