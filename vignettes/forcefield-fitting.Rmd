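---
title: "Force-field fitting with smirfit: models, objectives and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field fitting with smirfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smirfit)
```

# Scope

`smirfit` is a desk-scale re-creation of the production pipeline used to
build modern SMIRKS-typed ("SMIRNOFF-style") small-molecule force fields:
direct chemical perception for parameter assignment, a gas-phase molecular
mechanics engine, regularized least-squares refitting of valence and
Lennard-Jones parameters, the training-data curation filters such pipelines
apply, and the geometric/energetic benchmark statistics used to judge the
result. Everything runs on synthetic molecules and synthetic reference data
with a known ground truth, so every stage of the machinery can be validated
end to end by parameter recovery rather than by comparison to external
datasets.

# The potential model

The engine evaluates the standard AMBER-family functional form:

* bonds: $\tfrac{k}{2}(r - r_0)^2$, $k$ in kcal/mol/Å², $r_0$ in Å;
* angles: $\tfrac{k}{2}(\theta - \theta_0)^2$, $k$ in kcal/mol/rad²,
  $\theta_0$ stored in degrees in files;
* proper and improper torsions: $\sum_n K_n (1 + \cos(n\phi - \gamma_n))$;
* van der Waals: 12-6 Lennard-Jones from per-type $(R_{min}/2, \epsilon)$
  with Lorentz–Berthelot combination;
* electrostatics: Coulomb over fixed input partial charges.

1-2 and 1-3 pairs are excluded; 1-4 pairs are scaled by 0.5 (vdW) and
1/1.2 (electrostatics) by default. There are no cutoffs and no periodic
boundary conditions — every target in scope is gas phase. The `k/2`
harmonic convention matches the SMIRNOFF ecosystem; AMBER parameter files
use `k (x - x_0)^2`, so force constants from that lineage must be doubled
before use here.

Analytic gradients are implemented for every term (compiled kernel, with a
pure-R reference implementation retained and cross-checked in the test
suite) and verified against central finite differences at relative 1e-6.

## Parameter assignment

Parameters are keyed by SMIRKS patterns held in *ordered* lists. For each
bonded tuple of a molecule (atom, bond, angle, proper torsion, trivalent
improper center), every pattern in the list is matched and the **last**
matching parameter wins, so generic patterns are listed first and refined
chemistries override them. Symmetric matches are collapsed through a
canonical tuple key (bonds ordered, angles ordered by their outer atoms,
torsions oriented by the inner bond, impropers keyed by center plus sorted
neighbors), so each chemical tuple receives exactly one parameter per
class. Impropers follow the one-term-per-center convention (no trefoil
averaging); they are never optimized here, matching the production
protocol.

The SMARTS dialect supported by the built-in matcher covers the needs of
the shipped chemistry: atomic number (`#n`), wildcard (`*`), degree
(`X<n>`), attached hydrogens (`H<n>`), formal charge, negation, the
`&`/`,`/`;` connectives, bond symbols `-`, `=`, `#`, `~`, and parenthesised
branches. Ring-closure digits, aromaticity and recursive SMARTS are not
supported; the toy chemistry is deliberately acyclic and aliphatic. The
matcher is validated against an independent cheminformatics engine on
frozen match tables in the test suite.

# Fitting targets

## Optimized-geometry targets

An opt-geo target stores a reference minimized geometry. Its loss is the
mean over internal coordinates (bond lengths, angles, improper deviations
— proper torsions deliberately excluded, since they are fit through
profiles) of the squared scaled deviation between the reference and the
geometry minimized under the current parameters:
$(x^{ref}_i - x^{MM}_i)^2 / d_i^2$ with divisors 0.05 Å for bonds, 8° for
angles and 20° for impropers. The MM geometry is re-minimized from the
reference at every objective evaluation. Improper deviations are folded to
(−90°, 90°] so that planarity reads zero on either dihedral branch.

## Torsion-profile targets

A torsion-profile target stores a dihedral, a grid (production convention:
24 points at 15° covering [−180°, 180°)), per-point reference energies
referenced to the grid minimum, and the per-point reference structures.
Evaluation re-minimizes each stored frame with the four torsion atoms
Cartesian-frozen and all other atoms under harmonic positional restraints
of 1 kcal/mol/Å² about the reference frame, removes restraint energy,
re-references the profile to its own minimum, and scores
$w(E^{ref}_i)\,(\Delta E^{MM}_i - \Delta E^{ref}_i)^2 / d_E^2$ averaged
over the grid, $d_E = 1$ kcal/mol.

The energy-dependent weight prioritizes the thermally relevant region near
the minima: $w = 1$ below 1 kcal/mol, $w = 1/\sqrt{1 + (E-1)^2}$ between 1
and 5 kcal/mol, $w = 0$ at and above 5 kcal/mol. Both regime boundaries are
configurable.

During standalone scans (as opposed to target evaluation) the dihedral is
driven by an exact rigid rotation about the central bond followed by
freezing the four torsion atoms, which leaves zero residual angle error; a
stiff-harmonic-restraint mode is available as an option, but for realistic
barrier heights a restraint of ~1000 kcal/mol/rad² leaves residuals of
order $nK/k_{restraint}$ radians, which can exceed 0.1°, so exact driving
is the default. In-ring scans support an energy cutoff (0.05 hartree ≈
31.4 kcal/mol) above which grid points are dropped.

# The total objectives and the optimizer

The valence objective is $\sum_i w_i L_i + w_{reg}\sum_p
(\Delta\theta_p/\sigma_p)^2$ with target weights 0.1 (opt-geo) and 1
(torsion-profile) and the Gaussian-prior regularization scales $\sigma_p$:
100 kcal/mol/Å² (bond k), 0.1 Å (bond length), 100 kcal/mol/rad² (angle
k), 20° (equilibrium angle), 1 kcal/mol (torsion barrier), 0.1 kcal/mol
(vdW $\epsilon$), 1 Å ($R_{min}/2$). Parameters are optimized in
prior-scaled coordinates $(\theta - \theta_{start})/\sigma_p$, which makes
the convergence thresholds dimensionless and the problem well scaled.

Eligibility: only parameters applied to at least 5 molecules in the target
set are freed; equilibrium angles of linear angle parameters stay at 180°;
torsion periodicities and phases are fixed; impropers are never freed.
Box constraints keep force constants and $\epsilon$ nonnegative and
$R_{min}/2$ positive.

The Lennard-Jones objective pools pure and mixture densities into one
block and enthalpies of mixing into another, each averaged over its number
of measurements with divisors $d_\rho = 0.05$ g/mL and
$d_{\Delta H_{mix}} = 1.6$ kJ/mol, plus the prior penalty. Property values
and their parameter gradients come from a pluggable backend; the package
ships an analytic surrogate (below) and the contract admits a real
condensed-phase estimator.

The outer loop mirrors the production protocol: per iteration, evaluate
the objective and gradient and take a bounded quasi-Newton step, then test
convergence by the two-of-three rule (objective ≤ 0.1, gradient norm
≤ 0.1, step ≤ 0.01 in scaled coordinates). The LJ loop defaults to 15
iterations. Two implementation notes:

* The inner solver for property fits is L-BFGS-B. The valence objective,
  however, itself runs L-BFGS-B geometry minimizations for every target,
  and R's L-BFGS-B C routine is not reentrant; the valence outer loop
  therefore uses an R-level projected BFGS with Armijo backtracking whose
  Hessian approximation persists across outer iterations.
* Valence gradients are central finite differences with per-kind steps
  (1e-3 Å, 5e-2°, 0.5 kcal/mol/Å² for force constants, 1e-2 kcal/mol for
  torsion barriers). The force-constant steps are deliberately much larger
  than machine-level: the objective is computed through iterative
  minimization with a gradient-RMS tolerance of about 1e-5–1e-6, and
  smaller steps make the finite difference noise-dominated. Warm-start
  geometries for the per-target minimizations are committed only at
  accepted iterates, keeping the objective a deterministic function of the
  parameters during line searches and differencing.

The default minimizer tolerance is a gradient RMS of 1e-5 kcal/mol/Å; for
the stiffest toy system the achievable floor in double precision is about
3e-6, so tighter defaults would flag spurious non-convergence.

# Curation rules

The package implements the training-data filters of the production
pipeline:

* conformer capping at 10 per molecule by greedy max-min heavy-atom RMSD
  selection, seeded at the lowest-energy conformer;
* removal of targets whose distance-perceived connectivity (1.2 × the sum
  of covalent radii) changes between initial and final geometries;
* exclusion of torsion targets with intramolecular hydrogen bonds by a
  single-structure Baker–Hubbard criterion (N/O donors and acceptors,
  H···A ≤ 2.5 Å, D–H···A ≥ 120°; thresholds configurable);
* torsion-scan selection preferring candidates that exercise a single
  torsion parameter across the central bond, escalating the allowed
  overlap count one unit at a time;
* physical-property curation: element whitelist (H, C, N, O, Cl, Br),
  ambient window 99.9–101.4 kPa and 288.15–318.15 K (boundaries
  inclusive), a mole-fraction floor of 0.05 (inclusive, since the stated
  rule is a *minimum* concentration), retention of at most three binary
  points nearest x₁ ∈ {0.25, 0.5, 0.75}, and removal of functional groups
  with fewer than 5 surviving measurements per data type. The group rule
  is applied last; applying it before the concentration selection is the
  other defensible reading, and the choice is a single code location.
* vdW-type eligibility for LJ refits: at least 5 density *and* 5 enthalpy
  points touching the type.

All filters are idempotent and report exact input/retained/removed counts.

# Benchmark statistics

Geometric and energetic metrics follow the conventions of force-field
benchmarking studies: Kabsch optimal-superposition RMSD (validated against
the closed-form quaternion solution), torsion fingerprint deviation
following the Schulz-Gasch method as realized in its reference
implementation (local-symmetry reference quartets, minimal circular
deviation normalized by 180°, centrality weights $e^{-\beta d^2}$
calibrated so the weight at half the maximal bond distance is 0.1; TFD is
flagged undefined — never silently 0 — for molecules without nonterminal
rotatable bonds, and ring systems are out of scope here), and relative
conformer-energy errors ΔΔE referenced to the reference-minimum conformer,
which is excluded from summaries so they are not skewed toward zero.

Free-energy tables are scored by RMSE and mean signed error with
percentile-bootstrap 95% confidence intervals (default 2000 resamples,
seed mandatory), by the mean shift in unsigned error between a new and a
reference force field over paired systems (negative = improvement), by a
Gaussian deconvolution attributing shift variance to force-field change
versus simulation noise, $\max(0, s^2 - \sigma^2_{noise})/s^2$, and by the
transfer free energy composition
$\Delta G_{trans}(aq \to nonaq) = \Delta G_{solv}(nonaq) -
\Delta G_{solv}(aq)$, asserted through its additivity identity. Parameter
enrichment among TFD outliers uses the normalized form
$[n(p \wedge TFD>t)/n(TFD>t)] \,/\, [n(p)/n]$ — the literal fraction is
bounded by 1 and cannot express the over-representation values of interest
— with the literal form available behind a flag.

# The synthetic world

Toy molecules are built from explicit internal-coordinate templates
(alkanes of any length, methanol, ethanol, dimethyl ether, ethylene
glycol, ethylamine, acetamide, methanesulfonamide, acetonitrile), so no
conformer embedder and no randomness is involved; partial charges follow
a fixed element/environment scheme and are exactly neutralized. The
ground-truth force field covers every interaction class with
generic-to-specific SMIRKS hierarchies so last-match-wins assignment is
genuinely exercised. Acetonitrile contributes a linear angle (equilibrium
180°, force constant only) and a zero-barrier torsion across its sp
carbon, exercising both freezing conventions.

Synthetic "QM" data are produced by the package's own engine under the
ground truth: opt-geo references are minimized geometries plus optional
Gaussian coordinate noise; torsion profiles are restrained scans plus
optional Gaussian energy noise, re-referenced to their minimum. With zero
noise the valence data term at the ground truth vanishes by construction.

Physical properties come from an analytic surrogate standing in for
condensed-phase simulation. Per substance, an effective molar volume
$V = \sum_a c_v (R_{min}/2)_a^3 (1 - 0.7\,\epsilon_a/(\epsilon_a+0.05))$
(mL/mol) makes density $M/V$ decrease with growing radii and increase
with growing well depths; mixtures mix volumes ideally, and the enthalpy
of mixing combines a regular-solution term
$V_m \phi_1 \phi_2 (\delta_1-\delta_2)^2$ with solubility parameter
$\delta = \sqrt{c_e E_{coh}/V}$ and a type-resolved cross-interaction term
$c_x x_1 x_2 \sum_t f_{t,1} f_{t,2} \epsilon_t$. The cross term exists so
that the well depths of individual types are identifiable from mixture
data rather than only through their per-substance sums; without it (and
without sufficient substance diversity) the LJ fit is structurally
underdetermined. The default constants give densities of roughly 1–1.9
g/mL and enthalpies of mixing up to about 0.9 kJ/mol. The surrogate is
deterministic, has exact gradients (complex-step differentiation), and
deliberately omits temperature dependence — the curation windows are
exercised through the design metadata instead.

Free-energy benchmark tables draw experimental values from a normal
distribution and add configurable biases and Gaussian noise for the
"reference" and "new" predictions; the analytic expected mean shift
(difference of folded-normal means) is returned for validation.

## What the synthetic world does and does not show

Passing the recovery experiments demonstrates that the assignment,
engine, objectives, optimizer, curation and statistics are internally
correct and consistent — not that the functional form or the surrogate
describes real liquids. Real QM references carry anharmonicity and basis
error; real property data carry temperature dependence and experimental
scatter; real chemistry includes rings, aromatics and charged species that
the toy templates avoid by design.

# Parameter-recovery experiments

`recover_valence_parameters()` generates noiseless targets for seven
H/C/N/O molecules (7 opt-geo targets and 7 torsion profiles on an
8-point, 45° grid — a desk-scale reduction of the production 15° grid),
perturbs all eligible identifiable valence attributes by +10%, and refits
without regularization. Regularization is excluded deliberately: the
prior is centered on the *perturbed* start, so any nonzero weight biases
the fit away from the truth and the experiment would measure the prior
rather than the machinery. Typical results: equilibrium bond lengths and
angles recovered to well under 0.1%, angle force constants to about 1%,
torsion barriers to under 0.1%, in about 30 iterations.

Bond force constants are excluded from this experiment, and the package's
test suite asserts why: with vibrational-frequency targets absent (the
production pipeline removed them), equilibrium geometries and restrained
torsion profiles carry almost no bond-stiffness information — a 10% bond-k
error changes the noiseless data term by about 2×10⁻⁷, versus about 10⁻⁴
for angle force constants — because bond strains in minimized small
molecules are of order 10⁻³ Å against a 0.05 Å divisor. In production
fits the Gaussian prior, not the data, holds bond force constants near
their starting values; the same is true here.

`recover_lj_parameters()` generates a noiseless surrogate dataset over
all toy substances, curates it, determines data-eligible vdW types
(sulfur types drop out with the element whitelist, exactly as low-coverage
chemistries are left unrefit in production), perturbs the refittable
eligible types by +10% and refits with the prior disabled for the same
reason as above. The hydroxyl-hydrogen type is frozen in the ground truth:
it co-occurs 1:1 with its host oxygen in any conceivable liquid, so bulk
properties can only ever constrain the pair jointly — the classic reason
production force fields keep the hydroxyl hydrogen's well vestigial.
Recovery is to about 0.2% in $\epsilon$ and 0.02% in $R_{min}/2$.

Problem sizes throughout (seven molecules, 8-point fit grids, toy
chemistry) are the package's choice of a desk scale at which every
experiment runs on a single CPU in minutes.

# Known limitations

* Acyclic, aliphatic, neutral chemistry only; no aromaticity model.
* TFD ring-torsion treatment not implemented (no rings in scope).
* The torsion-scan driver cannot rigidly drive in-ring torsions (use the
  restraint mode if ever needed).
* The surrogate's density is temperature-independent.
* Bond force constants are identifiable only through the prior, as
  discussed above.
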