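---
title: "Electrostatic machine-learning embedding: models, training and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic machine-learning embedding: models, training and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emler)
```

## The embedding model

`emler` implements an electrostatic machine-learning embedding (EMLE)
scheme for hybrid ML/MM simulations, in which a reactive subsystem treated
by a machine-learned (or analytic) gas-phase potential is coupled to an
environment of fixed point charges. The total energy is decomposed into
four terms,

$$E_{\mathrm{ML/MM}} = E_{\mathrm{gas}}(R_{\mathrm{ML}})
 + E_{\mathrm{static}}(R_{\mathrm{ML}}, R_{\mathrm{MM}})
 + E_{\mathrm{induced}}(R_{\mathrm{ML}}, R_{\mathrm{MM}})
 + E_{\mathrm{MM}}(R_{\mathrm{ML}}, R_{\mathrm{MM}}),$$

where the gas term is the in-vacuo energy of the ML region, the static
term is the Coulomb interaction of the *unperturbed* ML charge density
with the MM point charges, the induced term is the energy gained by
polarizing the ML region in the MM field, and the MM term collects the
ML–MM van-der-Waals interactions (12-6 Lennard-Jones with
Lorentz–Berthelot combining; MM-internal nonbonded energy is excluded,
being constant for a frozen environment). The decomposition identity
`e_total = e_gas + e_static + e_induced + e_mm` is enforced by the
`energy_decomposition()` constructor on every object the package emits.

Internally all electrostatics are evaluated in Hartree atomic units;
every file and function interface uses angstrom, kcal/mol and elementary
charges. The conversion constants are fixed
(1 bohr = 0.52917721092 Å, 1 hartree = 627.509474 kcal/mol).

### Static component: Slater densities and electronegativity equalization

The ML-region density is a sum of atomic contributions in the
minimal-basis-stockholder picture: a point core of charge $q_i + N_i$
plus a spherical Slater valence cloud of population $N_i$ and width
$s_i$,
$\rho_i(r) = N_i e^{-r/s_i} / (8\pi s_i^3)$. Its electrostatic
potential,

$$V_i(d) = \frac{q_i + N_i}{d}
 - \frac{N_i}{d}\Big[1 - e^{-d/s_i}\big(1 + \tfrac{d}{2s_i}\big)\Big],$$

decays to the point-charge potential $q_i/d$ at long range and carries a
positive charge-penetration correction at short range. Valence
populations are fixed per element (H 1, C 4, N 5, O 6, S 6); this
core/valence split reproduces the correct asymptotics while keeping one
scalar width per atom.

Per-atom widths and volumes are predicted directly by sparse
Gaussian-process regression (GPR) on local-environment descriptors, with
a softplus-style floor keeping them positive. Charges are *not*
predicted directly: the GPR predicts per-atom electronegativities
$\chi_i$, and the charges minimize
$\sum_i (\chi_i q_i + \tfrac12 \eta_i q_i^2)
 + \sum_{i<j} q_i q_j / d_{ij}$
subject to $\sum_i q_i = Q$, solved as an $(N+1)$-dimensional symmetric
linear system with a Lagrange multiplier. This guarantees exact total
charge conservation at every geometry and makes the charges
conformation-dependent by construction. The hardness rule is
$\eta_i = 1/(2 s_i)$, tying the self-repulsion to the predicted valence
width so that no separate hardness model is needed; the rule is a
documented, swappable choice. Off-diagonal couplings in the trained
model use a Gaussian-smeared kernel
$\mathrm{erf}\!\big(d/\sqrt{2(s_i^2+s_j^2)}\big)/d$ rather than
two-center Slater integrals: it has the right $1/d$ asymptotics, stays
finite at close contact (the bare kernel suffers a polarization
catastrophe when atoms collide during dynamics), and the training
inversion (below) uses the same kernel, keeping the construction
self-consistent. `eeq_charges()` itself defaults to the bare kernel.

Training inverts this construction: given reference charges, widths and
geometries, the equalization conditions are solved for the
electronegativity targets (gauge: zero Lagrange multiplier), which are
then regressed per element. Equalization with the learned
electronegativities therefore reproduces the reference charges exactly
in the noise-free limit.

### Induced component: Thole induced dipoles

Each ML atom is an isotropic polarizable center. Atomic polarizabilities
are proportional to the density-derived atomic volumes,
$\alpha_i = k_Z v_i$, with one learnable ratio per chemical element
(`fixed` mode), optionally multiplied by an environment-dependent
correction $k_\alpha(G_i)$ predicted by a sparse GPR with prior mean 1
(`flexible` mode). The induced dipoles solve the Thole relay equations
$A\mu = E$ with damped dipole–dipole interaction tensors (exponential
damping on the reduced distance $u = d/(\alpha_i\alpha_j)^{1/6}$,
damping constant $a = 0.39$ by default — a widely used value; the exact
damping kernel of other implementations is not claimed). The induction
energy $E_{\mathrm{induced}} = -\tfrac12 \sum_i \mu_i \cdot E_i$ is
non-positive by linear response, and the solver refuses
non-positive-definite relay matrices, naming the closest atom pair. The
dense Cholesky solve is the reference path (systems here have at most a
few hundred atoms); a damped Jacobi iteration is available as a
cross-check. The MM environment enters only as the electric field acting
on the ML atoms: MM charges are never back-polarized.

Molecular polarizability tensors are block sums of the inverse relay
matrix; the isotropic polarizability is a third of the trace.

### Embedding ablations

Three variants are exposed through `embedding_variant()`:

* `emle` — all four terms;
* `mechanical` — the induced term removed (conformation-dependent
  charges, no polarization);
* `mm_fixed` — additionally the static term replaced by plain Coulomb
  interactions with a named fixed charge set (reactant-derived `q_R` or
  product-derived `q_P`).

These ablations quantify, respectively, the role of polarization and of
electronic rearrangement in an embedded reaction.

## Training the polarizability models

`fit_kz()` fits the per-element $\alpha/v$ ratios by least squares on
molecular polarizability tensors over a set of conformers (quasi-Newton
on log-ratios; deterministic).

`fit_flexible_alpha()` fits the flexible correction by penalized least
squares — tensor misfit plus $\lambda \sum (k_\alpha - 1)^2$. The unity
bias matters: without it the correction overfits and destabilizes
subsequent dynamics. The implementation is two-stage: (1) for every
conformer, a damped Gauss–Newton inversion recovers the per-atom
correction factors minimizing the penalized tensor misfit (six tensor
components against five atoms is locally well-posed); (2) the recovered
factors are regressed on the atomic descriptors by a sparse GPR with
prior mean 1. A single joint fit of the GPR weights against all tensors
was evaluated and rejected: on nearly axially symmetric conformers the
tensor has fewer than five informative components per geometry, and the
joint fit can lower the tensor misfit along near-degenerate directions
that scramble the per-atom assignment. The pointwise inversion pins the
assignment geometry by geometry, and the regression stage (noise floor
`1e-4`) averages residual inversion noise away. In the infinite-$\lambda$
limit the correction is exactly unity, reproducing the fixed model.

## Descriptors

All property models share one descriptor: element-resolved Gaussian
radial sums
$G_{i,(Z,k)} = \sum_{j \ne i,\, Z_j = Z}
 e^{-(d_{ij}-\mu_k)^2/2w^2} f_c(d_{ij})$
with a smooth cosine cutoff. Defaults: cutoff 5.0 Å, 16 radial centers,
width 0.5 Å. The descriptor sees only ML atoms — the environment is
deliberately invisible, so trained models transfer across environments.
No angular channels are included: every property predicted here is a
scalar on an effectively radial synthetic surface, and angular channels
are a documented extension point rather than a need. The effective
radius of the "local environment" is not prescribed by the embedding
model itself; the cutoff is configurable.

## Sparse GPR

The property models are subset-of-regressors sparse GPs with an RBF
kernel. Inducing points are chosen by farthest-point sampling starting
from the largest-norm sample, which makes the selection fully
deterministic and independent of sample ordering. The weights solve the
penalized projected system in augmented least-squares form (QR) rather
than through the normal equations, whose squared condition number loses
half the working precision on quasi-one-dimensional conformer manifolds.
Hyperparameters are fixed by configuration, not optimized: the package
favours bit-reproducible training over marginal-likelihood tuning, which
is an extension point.

## Dynamics, umbrella sampling and WHAM

`run_langevin()` is a BAOAB Langevin integrator (deterministic given a
seed; velocity Verlet in the zero-temperature, zero-friction limit).
Restraints follow the MD-engine convention $K(\Delta\xi)^2$ *without*
the one-half factor — published force constants for umbrella windows and
one-sided guards are engine-convention values — switchable per restraint
via `half_convention`. Supported restraints: harmonic on a reaction
coordinate, one-sided harmonic on a distance, and isotropic position
anchors.

Force paths: the fast path differentiates the energy with the predicted
density parameters and polarizabilities frozen (analytic, used for
sampling); the finite-difference path (central differences, step
1e-3 bohr on the full energy including parameter response) defines
correctness. Because the parameter response can dominate along a
reaction coordinate with strong charge rearrangement, the sampling force
field optionally restores it along a chosen RC
(`param_response_rc`): the embedding energy is re-evaluated with
parameters predicted at RC-displaced geometries and the resulting
$dE/d\xi$ is projected onto the RC gradient. This is exact when the
parameters depend on geometry only through the RC — true by construction
for the synthetic ground truth, and a good approximation for models
trained on its data. Without this term the sampled free-energy surfaces
of the `emle` and `mechanical` variants lose most of their
charge-rearrangement physics, which is why it is on in every sampling
workflow shipped with the package.

`run_umbrella()` can start every window from a fresh structure or, with
`continuation = TRUE`, from the previous window's final configuration;
replica chains are independent and alternate traversal direction, so with
two or more replicas every window is approached from both sides of the
profile. For a barrier region the window force constant must also be
chosen so the bias curvature ($2K$ in the engine convention) exceeds the
curvature of the free-energy maximum — otherwise the combined
bias-plus-free-energy surface is bistable, windows snap to one branch
regardless of how they are approached, and adjacent histograms develop
gaps that (correctly) abort WHAM. The shipped reactive workloads
therefore use a stiff, dense grid (0.05 Å spacing,
600 kcal/mol/Å²) with serial continuation.

`wham()` is a binned self-consistent weighted-histogram solver
(default bin width spacing/5, convergence `1e-6` kcal/mol on the window
free energies, minimum-shifted PMF). It refuses non-overlapping
adjacent histograms, naming the gap. `pmf_uncertainty()` implements two
estimators: one PMF per replica, and the 5-fragment method in which each
window's time series is split into contiguous fragments and one PMF is
computed per fragment index. The fragment split is over time within
windows; splitting over window subsets would generically break histogram
overlap and is not offered. Basin ranges for barrier and reaction free
energies are always explicit — no automatic basin detection.

## The synthetic ground truth

Real reference data for this kind of scheme are gas-phase quantum
calculations: per-atom density-partitioned charges, widths and volumes,
molecular polarizability tensors, and embedded single-point energies.
`ground_truth_model()` replaces them with an exactly known generator
over a five-atom model atom-transfer reaction
(O1–C2 bond breaking, C2–C3 bond forming; RC
$\xi = d_{\mathrm{O1C2}} - d_{\mathrm{C2C3}}$, total charge $-1$):

* the gas-phase surface is analytic — two Morse-bonded diabatic states
  coupled by a logistic switch in $\xi$, plus a Gaussian barrier-control
  term, a harmonic O1⋯C3 frame, a collinearity penalty, spectator C–H
  bonds and short-range exchange-like repulsion between the remaining
  nonbonded pairs (so no two atoms can collapse onto each other during
  sampling). The constructor calibrates the barrier (default
  20 kcal/mol) and reaction asymmetry (default −3 kcal/mol) of the
  relaxed 1D profile to the requested values by deterministic
  constrained scans;
* per-atom properties follow
  $\mathrm{base} + \mathrm{amplitude}\cdot\sigma(\xi/w)$ with a logistic
  $\sigma$ ($w = 0.25$ Å): 0.6 e moves onto the leaving oxygen across
  the reaction (an oxyanion-like product), widths and volumes shift
  accordingly;
* the true $k_\alpha$ field is a Gaussian bump in $\xi$ on the reactive
  pair (peak value 2 near the transition state), so the reactive pair's
  polarizability roughly doubles through the TS;
* conformers are stratified on an even RC grid with small coordinate
  jitter (0.02 Å), then Newton-corrected back onto their RC targets so
  coverage guarantees hold.

The deliberately large charge rearrangement and polarizability peak put
the system in the regime where fixed-charge embedding fails outright,
mechanical embedding recovers part of the physics, and the full scheme
recovers the rest — so the qualitative claim becomes a strict, testable
error ordering. The "enzyme-like" environment
(`gt_catalytic_environment()`) is a neutral random droplet plus one
+0.7 e charge 3 Å from the leaving oxygen, standing in for an
active-site residue that stabilizes the developing oxyanion; harmonic
position anchors on O1 and C3 (`gt_pocket_restraints()`, 20 kcal/mol/Å²)
stand in for the binding pocket and are identical across embedding
variants.

What the generator does *not* emulate: real electronic structure
(properties here are smooth functions of one internal coordinate, so
trained models can recover them to fractions of a percent — real
partitioned densities are noisier and higher-dimensional), solvent
exchange and diffusion, bonded MM terms, periodic electrostatics, and
conformational diversity beyond the reaction path. Passing the recovery
and ordering tests therefore demonstrates the correctness and internal
consistency of the machinery, not chemical accuracy on real systems.

## Validation choices and problem sizes

The test and validation workloads use sizes chosen to make every check
statistically decisive at desk scale: 60 training and 15 held-out
conformers for property recovery; 15 umbrella windows at 0.1 Å spacing
(K = 40 kcal/mol/Å²) for the 1D benchmarks and 43 windows at 0.05 Å
(K = 600) for the reactive system; 500–4000 production steps per window
at dt = 0.5–1 fs; a 1D double well
(barrier 3 kcal/mol) for WHAM validation against a per-bin Boltzmann
quadrature oracle; and a 20000-step flat-bottom window for the
equipartition check. The embedding-variant comparison drives the
variants with the ground-truth backends rather than trained models, so
the measured error ordering isolates the embedding ablation itself from
(small) training error; the full trained-model pipeline is validated
separately by comparing its PMF against the ground-truth PMF.

## Known limitations

* Atomic monopoles only: no static atomic dipoles or quadrupoles, and no
  ML correction to the Lennard-Jones short-range terms.
* The flexible correction is trained on polarizability tensors only, not
  on induction energies.
* Non-periodic electrostatics over explicit point charges; no Ewald/PME,
  no constraint algorithms.
* The fast force path freezes predicted parameters; full parameter
  response is available only along a designated RC (sampling) or via the
  finite-difference mode (testing).
* The RDF uses a droplet normalization (reference density from the full
  sampled sphere), appropriate for finite systems but not directly
  comparable with periodic-solvent RDF conventions.
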