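---
title: "Methods: physics-based descriptors and empirical scoring in plscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physics-based descriptors and empirical scoring in plscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plscore)
```

# Scope and model

`plscore` estimates protein–ligand binding free energy as an affine
combination of six physics-based interaction descriptors, and evaluates
scoring functions for affinity prediction and virtual screening. The
package covers the *re-scoring* stage only: it consumes prepared structures
(explicit hydrogens, assigned protonation states) and takes no position on
docking, protonation, or structure curation, which belong to upstream
pipelines.

The linear scoring functions shipped with the package
(`published_model()`) are fixed coefficient sets: `general-random` and
`general-all` for diverse targets, `protease` for protease active sites,
and `ippi` / `ippi-onesolv` for small-molecule inhibitors of
protein–protein interfaces. They differ in how solvation and entropy are
weighted — the interface-inhibitor sets put much more weight on the
torsional-entropy count and on surface burial, reflecting the flat,
hydrophobic character of those sites. Nonlinear models (ε-SVR and random
forest) are *retrainable* from descriptor tables but not shipped: their
published fitted states are not available as reusable parameters, so any
nonlinear model in this package is one you train yourself on your own data.

# The descriptors

## Electrostatics

The screened Coulomb term sums over all intermolecular atom pairs

$$E_{coul} = \sum_{ij} \frac{332.0716\,q_i q_j}{\varepsilon(R_{ij})\,(R_{ij} + \delta_{elec})},
\qquad \delta_{elec} = 0.05\ \text{Å},$$

with partial charges in elementary units and energies in kcal/mol. The
denominator convention deserves a note: the source expression is typeset
ambiguously between $\varepsilon \cdot (R+\delta)$ with a
distance-dependent $\varepsilon(R)$, and $\varepsilon$ evaluated *at*
$R+\delta$. We evaluate the dielectric at $R$ and buffer only the distance
factor; for $\delta = 0.05$ Å the difference is far below every other
uncertainty in the model.

Two sigmoidal distance-dependent dielectrics are provided
(`dielectric_model()`): the Hingerty function, fixed between 1 (contact)
and 78 (bulk water), and the Ramstein–Lavery function

$$\varepsilon(r) = D - \tfrac{D - D_i}{2}\left[(rs)^2 + 2rs + 2\right]e^{-rs}$$

with slope $s = 0.16\ \text{Å}^{-1}$, plateau $D = 78$ and a configurable
short-range limit $D_i$ (1 or 4; the default 4 models the depressed
dielectric inside binding sites). Both are monotone non-decreasing;
$r = 0$ returns the analytic limit. The Ramstein tail approaches 78 as
$r^2 e^{-rs}$, i.e. to within $10^{-3}$ only beyond ~100 Å — a property
test documents this because a naive "equals 78 at long range" assertion
fails at moderate distances.

## Van der Waals

The buffered 14-7 form with buffering constants $\delta_{vdW}$ and
$\gamma = 0.12$:

$$E_{vdW} = \sum_{ij} \varepsilon_{ij}
\left(\frac{(1+\delta)R^*_{ij}}{R_{ij}+\delta R^*_{ij}}\right)^{7}
\left(\frac{(1+\gamma)R^{*7}_{ij}}{R^7_{ij}+\gamma R^{*7}_{ij}} - 2\right).$$

$\delta = 0.07$ is the classical parameterization; the default here is the
softened $\delta = 0.67$, which damps the short-range repulsion and is the
appropriate choice for structures that have not been energy-minimized
(crystal poses, docking poses with small clashes).

A subtle point we verified analytically and pinned in tests: the pair
energy at $R = R^*$ equals $-\varepsilon_{ij}$ *exactly* for any $\delta$
(both bracketed factors reduce to 1 and −1), but $R^*$ is the exact
minimizer only when $\delta = \gamma$. The derivative at $R^*$ is
proportional to $1/(1+\delta) - 1/(1+\gamma)$, so with $\gamma = 0.12$ the
true minimum sits at $0.99618\,R^*$ (depth $1.00056\,\varepsilon$) for
$\delta = 0.07$ and at $1.03627\,R^*$ (depth $1.03403\,\varepsilon$) for
$\delta = 0.67$. Likewise the statement "the softened potential is less
repulsive below $R^*$" holds only below ≈ $0.89\,R^*$, where the two
curves cross. Our property tests assert the true behavior (constants
frozen from an independent one-dimensional optimization), not the
idealized one.

Pair parameters combine by geometric mean for the well depth and
arithmetic mean for $R^*$ — the combination rules of the built-in backend,
not of any particular force field (see *Parameterization backend*).

## Lipophilic contacts

Each eligible intermolecular pair contributes a piecewise-linear weight:
1 for $d \le d_{vdW} + 0.5$ Å, falling linearly to 0 at $d_{vdW} + 3.5$ Å,
where $d_{vdW}$ is the sum of the two contact radii. Two eligibility
variants exist: *carbons* (both atoms carbon, regardless of charge) and
the default *charge window* (both atoms heavy with partial charge strictly
inside (−0.4, +0.4) e); hydrogens are never eligible. The middle branch is
implemented as $1 - (d - d_{vdW} - 0.5)/3$, which is the only reading
continuous at both breakpoints (a sign typo in the extracted source text
would make the function jump from 1 to 2/3 at the first breakpoint);
continuity at both knots is asserted by test.

## Solvation

Surface areas come from a deterministic Shrake–Rupley implementation:
each atom's sphere (contact radius + probe, default probe 1.4 Å) is
sampled on a fixed golden-spiral lattice (default 960 points/atom) and a
point is accessible if outside every other expanded sphere. The published
work used a different surface engine (MSMS) with unstated settings; all
downstream uses of SAS here are thresholded ratios or a linear map, which
tolerates this substitution, but absolute per-atom areas should not be
compared across engines. Quadrature convergence (doubling the lattice
changes totals by <0.5%), rigid-motion invariance, and agreement with an
independent random-direction quadrature are property-tested. Hydrogens are
included in SAS by default (the source is silent); a heavy-atom-only mode
is available and is what the `oneSolv` descriptor uses by definition.

**Nonpolar**: $E_{np\_solv} = G_{np}(\mathrm{SAS}_{complex}) -
G_{np}(\mathrm{SAS}_{receptor}) - G_{np}(\mathrm{SAS}_{ligand})$ with
$G_{np}(S) = 0.0092\,S + 0.82$ (kcal/mol, Å²). Two separated molecules
give exactly $-0.82$ (the intercepts cancel against the areas); a fixture
with an analytically computed 100 Å² burial gives $-1.74$. These closed
forms are acceptance-tested.

**Polar**: a count of charged atoms — heavy, non-carbon, $|q| > 0.8$ e,
on either side — that (a) become buried on binding and (b) are not within
$d_{vdW} + 1.0$ Å of any other charged atom in the complex. "Buried" is
not quantified in the source; our rule is bound-state SAS ≤ 10% of
free-state SAS (ratio-based, hence size-independent), configurable via
`polar_burial_ratio`. The partner test is sign-agnostic and spans both
molecules with covalent neighbors excluded, following the source text
literally; an opposite-sign-only mode is provided.

**oneSolv**: identical functional form to the nonpolar term but computed
over heavy atoms only; used by the interface-inhibitor model in place of
the two separate solvation terms, because the two-term fit on that class
yields a polar coefficient with an unphysical favorable sign.

## Torsional entropy

Rotatable bonds are acyclic single bonds between two heavy atoms, each of
which has at least one further heavy neighbor; amide C–N bonds are
excluded by default. This deterministic rule is a package choice (the
source does not state its convention), so the count is reproducible and
documented rather than toolkit-dependent.

For each rotatable bond $(i, j)$ the two flanking sides are
$\{i\} \cup \mathrm{neighbors}(i)\setminus\{j\}$ and symmetrically for
$j$, with hydrogens attached to side atoms included by default. Each
side's fractional SAS loss is computed between the free ligand and the
complex; the bond is *frozen* when both fractions are ≥ 0.5, and
`E_entropy` is the frozen count. A side whose free-state area is already
below 0.5 Å² is defined as fully lost (fraction 1) — this degenerate case
matters for deeply self-occluded ligand cores. The three behavioral cases
(both sides ≥ 50% → frozen; one side < 50% → not frozen; rigid ligand →
0) are exercised by constructed fixtures whose per-side fractions sit far
from the 0.5 boundary (≈1.0 vs ≈0.26 in the discriminating case), so the
tests do not hinge on quadrature noise.

# Parameterization backend

No MMFF94S implementation exists in this R environment, so parameter
assignment is a pluggable contract with a built-in minimal backend:

* **partial charges** — bond-charge increments proportional to the Pauling
  electronegativity difference across each bond (scale 0.1 e per unit),
  added to the file formal charges. Increments are antisymmetric, so the
  charge sum equals the net formal charge *exactly*, and graph-equivalent
  atoms get identical charges — the two invariants the descriptors rely
  on.
* **vdW parameters** — a per-element (ε, R\*) table with geometric/
  arithmetic combination.
* **contact radii** — the Bondi set, configurable (`radii_table`), since
  the source never states which radii feed its $d_{vdW}$ sums.

This backend is calibrated for *plausibility, not fidelity*: descriptor
values computed with it are internally consistent and satisfy every
formula-level test, but they are not MMFF94S values, and predictions on
real complexes will differ from an MMFF94S-parameterized pipeline.
Substituting a real force-field engine means filling the same per-atom
columns (`partial_charge`, `eps`, `rmin`, `radius`) by any external means;
everything downstream is agnostic.

# Regression and validation stack

`fit_mlr()` is ordinary least squares. `fit_svr()` solves the
ε-insensitive SVR dual with a sequential-minimal-optimization solver
(compiled; working-set selection by maximal KKT violation) over a
precomputed kernel matrix — rbf or Pearson VII ("puk") kernels; features
are z-scored by default for SVR. The solver is cross-checked in the test
suite against an independent quadratic-programming solve of the same dual
on small problems: the *fitted function* and dual objective must agree,
which is the correct comparison because the dual coefficients themselves
are not unique for smooth kernels. `fit_rf()` is bagged CART regression
(random feature subset of size `num_features` per split, prediction =
mean over trees, per-tree predictions exposed).

`kfold_cv()` draws a seeded random partition into near-equal folds and
averages per-fold Pearson R and RMSE. `tune_model()` grid-searches
hyperparameters with the tie-break: highest mean R, then lowest RMSE,
then grid order (simplest first). The default grids are C ∈ {0.1, 1, 10,
100}, ε ∈ {0.001, 0.01, 0.1}, rbf γ ∈ {0.01, 0.1, 1}, puk σ, ω ∈ {0.5, 1,
3}; forest size ∈ {100, 500, 1000} with 1–6 features per split — spanning
the ranges a practitioner would scan, since the winning published values
are not available. `ablation_selection()` implements the published
protocol: start from the electrostatics + vdW basic function, add each
candidate class one variant at a time, keep each class's CV winner.

# Synthetic data: what it does and does not establish

The fixture generators define the package's test world:

* `make_toy_complex()` builds geometric, not chemical, complexes: carbon
  rotor chains, single-atom probes, charged atom pairs, with pockets that
  are capsule shells (full burial), slabs (partial one-sided burial) or
  per-atom occluder cages (surgical burial of a chosen atom subset; small
  occluder radii, candidates near unenclosed atoms removed). Annotated
  ground truths (nearest contact distance, rotor count, intended frozen
  count) are verified against the descriptor engine in CI.
* `make_feature_table()` draws descriptor vectors uniformly in ranges
  typical of drug-like complexes (Coulomb −40..5, vdW −60..−5 kcal/mol,
  0..300 lipophilic contacts, 0..10 rotors, 0..5 buried charges, −10..−1
  kcal/mol nonpolar) and generates targets from a planted linear model
  plus Gaussian noise (σ = 0.5 kcal/mol for the noisy recovery tests —
  about the scatter of high-quality affinity data; σ = 0 for exactness
  tests; n = 500 for the recovery criteria).
* `make_screening_scores()` draws active scores from N(−separation, 1)
  and inactives from N(0, 1).

A green suite therefore establishes that every formula is implemented as
printed, that the regression/validation machinery recovers planted truth,
and that the metrics obey their boundary algebra. It does *not* establish
predictive accuracy on real protein–ligand data: that depends on the
force-field backend and on curated structure sets that are outside this
package's world.

# Numerical choices and edge cases

* No nonbonded cutoff by default (`cutoff = NULL`); a cutoff is available
  for speed but documented as non-canonical.
* Enrichment factors count the top fraction *fractionally* (a compound
  straddling the cutoff contributes pro rata), which makes the theoretical
  maximum exactly $\min(1/f,\ N/n_{active})$ — the convention that
  reproduces all seven published "(max = …)" values; an integer-cutoff
  mode exists. Ranking ties: average-rank for AUC, stable input order for
  EF/BEDROC.
* Scores are "lower is better" throughout (predicted ΔG); a
  `higher_is_better` flag inverts on input.
* Affinity conversion uses ΔG = RT ln K with T defaulting to 298.15 K
  (the source states no temperature) and Kd, Ki and IC50 treated
  identically, the PDBbind convention.
* SMO stops at duality gap 10⁻³ (configurable); non-convergence inside the
  iteration cap is an error, never a silent result.
* The SDF writer emits `M  CHG` lines; the PDB reader falls back to
  distance-based bond perception (covalent radii + 0.45 Å) when CONECT
  records are absent.

# Known limitations

* The built-in parameter table covers C, H, N, O, S, P and halogens;
  metals and exotic elements raise a parameterization error naming the
  atom.
* Intramolecular (ligand strain) energies are out of scope by design; the
  descriptors are purely intermolecular.
* The frozen-rotor count inherits any error in rotatable-bond perception;
  our rule is deliberately simple and may disagree with toolkit
  conventions on exotic linkages.
* Published headline accuracies on external benchmark sets are not
  reproducible from this package alone (they require the original curated
  structure sets and docking poses); the acceptance targets are restricted
  to quantities computable from printed values.
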