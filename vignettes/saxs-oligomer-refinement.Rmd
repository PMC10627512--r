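---
title: "Modelling partially oligomerizing protein complexes against SAXS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling partially oligomerizing protein complexes against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsrb)
```

## The problem

Solution small-angle X-ray scattering (SAXS) measures the orientation-averaged
intensity $I(q)$ of particles in solution as a function of the momentum
transfer $q = 4\pi\sin\theta/\lambda$. For a multi-chain protein complex the
measured curve often disagrees with the crystal structure for two reasons at
once: domains move in solution, and the complex partially self-associates, so
the scattering is a mixture of monomers and loose oligomers. `saxsrb`
implements a complete modelling chain for this situation, developed around a
C2-symmetric heterohexameric kinase/antitoxin complex whose solution
behaviour shows exactly this combination: an apparent maximum dimension far
above the crystal diameter, forward scattering corresponding to roughly a
dimer of hexamers, and domain motions that differ between phosphorylation
states.

The package has five analysis layers:

1. **Model-free curve analysis** — Guinier fit, molar mass from forward
   scattering, indirect Fourier transform (IFT) to $p(r)$, normalized Kratky
   transform.
2. **Forward model** — Debye-equation form factor on a coarse-grained
   structure with an average excess scattering length per non-hydrogen atom
   and an optional hydration dummy-atom shell.
3. **Oligomerization** — a two-parameter structure factor in the decoupling
   approximation.
4. **Refinement** — restrained, C2-symmetric rigid-body refinement with
   simultaneous refinement of the oligomer parameters, best-of-$n$ selection
   by reduced $\chi^2$.
5. **Synthetic data** — a generator that produces bead models and noisy
   curves with the statistical structure the analysis assumes, so the whole
   chain is testable without any experimental download.

A small sixth module classifies Ser/Thr-kinase Gly-rich-loop phosphosite
motifs (`SΨS`, `(S/T)ΨT`, `(S/T)ΨP`, `SΨQ`, `ΨΨT`, with Ψ ∈ {Ile, Leu,
Val}), mirroring how these kinases group phylogenetically by the
configuration of their two candidate autophosphorylation sites.

## Model-free analysis

**Guinier.** At low $q$, $\ln I \approx \ln I_0 - q^2 R_g^2/3$. `guinier_fit()`
performs a weighted linear regression of $\ln I$ on $q^2$ over the largest
low-$q$ window satisfying $qR_g \le 1.3$, iterated until the window implied
by the fitted $R_g$ reproduces itself. The 1.3 limit is the standard
convention for globular particles; it is a parameter (`qrg_max`). For a
perfect sphere the $q^4$ term of the expansion biases the fitted $R_g$
upward by about 1.6% at this window — within the 2% accuracy the package
claims for sphere fixtures, but worth remembering when comparing against
geometric oracles.

**Molar mass.** On absolute scale (cm$^{-1}$), $M = I_0 N_A / (c\,
\Delta\rho_m^2)$ with the standard protein contrast $\Delta\rho_m = 2.00
\times 10^{10}\,\mathrm{cm\,g^{-1}}$ as default. This is exact arithmetic;
`molar_mass_from_i0(0.06642, 1e-3)` gives $1.00\times10^5$ g/mol.

**IFT.** `ift()` represents $p(r)$ as a histogram on $[0, D_{max}]$ and
minimizes the error-weighted $\chi^2$ of the back-transform
$I(q) = 4\pi \sum_j p(r_j)\,\mathrm{sinc}(q r_j)\,\Delta r$ plus a
second-difference smoothness penalty $\alpha$, with $p \ge 0$ (optional) and
$p(0) = p(D_{max}) = 0$ enforced through zero-padded differences. The
solver is a non-negative least squares on the stacked system. Two automatic
choices are deterministic and documented:

* `alpha = "auto"`: L-curve corner (maximum discrete curvature) over a
  log-spaced grid anchored at the scale of the design matrix;
* `dmax = "auto"`: scan $2R_g$–$4.5R_g$ and keep the *smallest* candidate
  whose reduced $\chi^2$ is within 5% of the minimum (parsimonious
  support). Alphas at which the active-set solver fails to converge are
  skipped; if the final system is singular the error message suggests
  increasing `alpha`.

This is a transparent deterministic scheme, not a Bayesian evidence
calculation; equivalence with any specific published IFT implementation is
at the property level (recovering known $p(r)$ and $D_{max}$ on synthetic
curves), not numerical identity.

**Kratky.** `normalized_kratky()` returns $x = qR_g$, $y = x^2 I/I_0$; a
globular particle peaks at $(\sqrt3, 3/e)$, a random coil rises to a
plateau. The transform is exact and pointwise.

## Forward model

`read_structure()` coarse-grains a PDB file to one scattering center per
non-hydrogen atom, all with the same average excess scattering length
$b = 1$ (relative units). Because the experimental intensity scale is always
refined, only relative contrasts matter; absolute units enter solely through
the molar-mass formula. The form factor is the Debye double sum

$$P(q) = e^{-q^2\sigma^2}\frac{\sum_{ij} b_i b_j\,
\mathrm{sinc}(q d_{ij})}{(\sum_i b_i)^2},$$

with $\sigma = 1.0$ Å smearing each point center over a Gaussian width, and
$\mathrm{sinc}(0) = 1$. Two implementations are exposed: the exact
$O(n^2)$ sum (`method = "direct"`, the oracle) and a pair-distance
histogram accelerator (`method = "histogram"`, default bin width 0.5 Å)
that stores per-bin mean distances and second moments and applies a
curvature correction; it agrees with the direct sum to better than
$10^{-5}$ relative over the default $q$ range, comfortably inside the
$10^{-3}$ contract its tests assert.

The hydration layer is a shell of dummy centers placed by a ray-cast
Fibonacci lattice over the convex offset envelope at 3 Å from the protein
surface, one dummy per `grid_spacing`² (3.5 Å nominal pitch) of shell
area. The dummy contrast `dummy_b` defaults to 0, which leaves the
intensity bit-identical to the unhydrated model — a deliberate oracle
default; positive values add the usual excess-density shell. The
construction follows the convex envelope, so deep surface pockets are
bridged rather than traced; for the globular fixtures this package targets
the effect is negligible, and the dummy count matches the analytic
$4\pi(R+3)^2$/pitch² estimate within a few percent.

## Oligomerization and the decoupling approximation

Partial self-association is modelled with the two-parameter structure
factor

$$S(q) = 1 + (N-1)\frac{\sin(qD)}{qD},$$

where $N \ge 1$ is the mean number of particles per oligomer and $D$ the
inter-particle distance. $S(0) = N$: the forward scattering reports the
oligomer mass directly, which is what connects the "roughly a dimer"
reading of $I(0)$ to $N \approx 1.7$–$1.8$. The total intensity uses the
decoupling approximation, valid when orientation and position are
uncorrelated:

$$I(q) \propto P(q) + \langle A(q)\rangle^2\,[S(q) - 1],
\qquad
\langle A(q)\rangle = e^{-q^2\sigma^2/2}\frac{\sum_i b_i\,
\mathrm{sinc}(q d_{i,\mathrm{CM}})}{\sum_i b_i},$$

with $d_{i,\mathrm{CM}}$ measured from the scattering center of mass.
$\langle A\rangle^2 \le P$ at every $q$ (Jensen/Cauchy–Schwarz), and the
$N = 1$ limit collapses exactly to $P(q)$ — both are tested invariants.

## Restrained rigid-body refinement

`refine_rigid_body()` searches over per-body rigid transforms of the
asymmetric half of a C2-symmetric model; the symmetry mate is regenerated
at every evaluation, so every candidate is exactly symmetric by
construction. The packaged `hipbst_scheme()` is the 3+1+3 partition used
for the heterohexamer half: three bodies for the HipB-like chain (residues
1–31, 32–43, 44–107), one for HipS, three for the HipT-like kinase (2–59,
60–169, 170–331), plus six named inter-domain contact restraints
(Glu A107–Val D101, Pro B55–Gly C154, Trp B65–Gly C60, Gly D100–Asp F188,
Leu D6–Arg F291, Val C147–Gly B94) and automatically generated
chain-continuity restraints at each body boundary. Restraint anchors
resolve to the Cα center of the named residue; target distances are
measured from the reference structure at setup, so the unperturbed model
has zero penalty.

The objective is

$$\chi^2_{red}(\text{analytic scale}) \;+\; w_r \sum_k (d_k -
d_k^{ref})^2 \;+\; w_{ev} \sum_{\text{inter-body } d<c} (c-d)^2,$$

with $w_r = 10$, $w_{ev} = 0.1$, clash cutoff $c = 4$ Å — weights chosen
so the three terms are the same order of magnitude on the packaged
fixtures. The number of free parameters in $\chi^2_{red}$ is `1 (scale) +
6 per body + 2 (N, D)`, configurable because this counting is a
convention. The optimizer is multi-start simulated annealing with
hierarchical Gaussian rigid moves — a single body, a whole chain, or the
whole half, because domain clusters move coherently while keeping their
mutual contacts ($\sigma_{trans} = 2$ Å, $\sigma_{rot} = 5°$, geometric
cooling, proposal sizes shrinking with $\sqrt{T}$) — and $N$ and $D$
proposed as reflected lognormal steps within $[1, 4]$ and $[20, 300]$ Å. Each run is
seeded (`seed + run - 1`), the whole procedure is bit-reproducible, and
the representative model is the run with the lowest reduced $\chi^2$ out
of `n_runs = 10` — best-of-10 selection is asserted, not assumed. After
the annealing runs, the best run is polished by a derivative-free local
search (Nelder–Mead on the body transforms and oligomer parameters),
which typically removes the last few percent of $\chi^2$; the polish is
part of the deterministic procedure.

When hydration is enabled during refinement the shell is regenerated every
25 accepted moves (a cost control) and exactly for the final model.

## What the synthetic generator does and does not emulate

`make_bead_complex()` builds bead models at one bead per residue (3.8 Å
Cα-like scale, 135 Å³ of volume per residue) with unit scattering length.
The hexamer-like topology mimics the S–T–B | B–T–S chain arrangement of
the heterohexamer: each rigid-body range is its own compact globule
(domains in real structures are spatially compact), domains are packed by
a deterministic repulsion relaxation so the truth state is clash-free
under the 4 Å excluded-volume cutoff, and restraint anchor residues are
placed at the domain surface facing their restraint partner — contact
restraints in real work come from interface analysis, so anchors sit at
contacts. The default study conditions are the ones the analysis is
designed around: oligomer truth $N = 1.8$, $D = 80$ Å, 2% multiplicative
Gaussian noise with a $10^{-4} I(0)$ error floor, 200 log-spaced $q$
points over 0.008–0.35 Å⁻¹ (a typical lab-source range), and a refinement
start in which one body (HipS by default) is displaced by up to 8 Å and
10°.

What passing these tests shows: the estimator recovers the generating
parameters and geometry under the assumed noise model. What it does not
show: robustness to buffer-subtraction errors, beam smearing, detector
artefacts, inter-particle interference beyond the two-parameter $S(q)$,
or conformational ensembles — none of which the generator simulates.
Fixture sizes are capped at a few thousand centers so the brute-force
Debye oracle runs in seconds; the vignette-scale refinements use the
~1100-bead hexamer and 10 runs of 1500 annealing iterations, the
package's chosen fixture scale.

## Numerical choices and degenerate inputs

* `sinc` at $qd = 0$ is defined as its limit 1.
* The histogram Debye accelerator uses per-bin mean distances plus a
  curvature correction, so its error is second order in the bin width.
* The Guinier fit refuses windows containing non-positive intensities and
  reports failure when no self-consistent window exists.
* Curves without an error column get $\sigma = 0.01 I$ with a warning.
* `max_diameter()` and all geometry predicates exclude hydration dummies
  by default.
* A sphere-fixture subtlety: near the first zero of the analytic sphere
  form factor ($qR = 4.493$) the *relative* error of any discrete model
  diverges because the reference passes through zero; closed-form
  comparisons therefore stop one grid point short of the zero.
* The C2 axis of a deposited structure is not annotated in coordinate
  files; `apply_c2()` takes an explicit axis, the synthetic scenarios
  carry theirs, and `fit_c2_axis()` estimates it for a symmetric
  structure from one pair of equivalent chains (Kabsch superposition;
  the axis passes through the midpoint of the two chain centroids).

## Known limitations

* Atomic element-specific form factors $f(q)$ are deliberately out of
  scope: with the overall scale refined, the average-atom approximation is
  adequate at $q \le 0.35$ Å⁻¹ for protein-only particles.
* The two-parameter $S(q)$ describes weak, isotropic pairing; it is not a
  hard-sphere or screened-Coulomb liquid-state model.
* The IFT is a regularized least-squares scheme; it reports no posterior
  uncertainty on $p(r)$.
* Rigid-body refinement explores body transforms only — no loop
  flexibility, no ensemble weights.
* With ~2% noise and 200 points, body positions are identifiable to a few
  Å at best; the tests assert 3 Å on the perturbed body under the default
  scenario, and that is close to the information limit of the data.
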