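# plscore

Physics-based empirical scoring of protein–ligand complexes in R.

`plscore` is for computational chemists and method developers who need a
transparent, fully inspectable re-scoring stack: six physics-based
interaction descriptors computed from a receptor + ligand structure pair,
published multiple-linear-regression (MLR) scoring functions that map those
descriptors to a binding free energy, retrainable nonlinear models
(ε-insensitive SVR and random forest), and the standard virtual-screening
evaluation metrics (Pearson *R*, RMSE, ROC AUC, EF, BEDROC).

## The model

The predicted binding free energy of a complex is an affine combination of
interaction descriptors,

    ΔG_pred = Σ_t  w_t · E_t  +  c0        [kcal/mol]

with the descriptor set:

| term | meaning | form |
|---|---|---|
| `E_coul` | screened electrostatics | Σ_ij 332.0716 q_i q_j / (ε(R_ij)·(R_ij + δ_elec)), δ_elec = 0.05 Å; ε(r) a sigmoidal distance-dependent dielectric (Hingerty, or Ramstein–Lavery with short-range limit D_i ∈ {1, 4} and plateau D = 78) |
| `E_vdW` | buffered 14-7 van der Waals | Σ_ij ε_ij ((1+δ)R\*/(R+δR\*))⁷ ((1+γ)R\*⁷/(R⁷+γR\*⁷) − 2), γ = 0.12, δ = 0.07 (original) or 0.67 (softened) |
| `E_lipo` | lipophilic contacts | piecewise-linear pair count: 1 up to d_vdW + 0.5 Å, linear to 0 at d_vdW + 3.5 Å; eligible atoms are all carbons, or any heavy atom with partial charge in (−0.4, +0.4) e |
| `E_entropy` | ligand torsional entropy | number of rotatable bonds whose two flanking atom groups each lose ≥ 50% of their solvent-accessible surface (SAS) upon binding ("frozen" rotors) |
| `E_polar_solv` | polar desolvation penalty | count of charged atoms (non-H, non-C, \|q\| > 0.8 e) that become buried on binding and have no charged partner within d_vdW + 1.0 Å |
| `E_np_solv` | nonpolar solvation | G_np(SAS_complex) − G_np(SAS_receptor) − G_np(SAS_ligand), with G_np(S) = 0.0092·S + 0.82 kcal/mol |

The package ships five published coefficient sets (`published_model()`):
`general-random`, `general-all` (diverse complexes), `protease`, `ippi` and
`ippi-onesolv` (protein–protein-interaction inhibitors; the `-onesolv`
layout replaces both solvation terms with a single heavy-atom ΔSAS term,
`oneSolv`). Default descriptor configuration is the published pairing of
the Ramstein–Lavery dielectric with D_i = 4 and the softened vdW
(δ = 0.67).

SAS is computed with a deterministic Shrake–Rupley golden-spiral
quadrature (probe 1.4 Å, 960 points/atom); partial charges, vdW parameters
and Bondi contact radii come from a built-in element table behind a
pluggable backend contract (see the methods vignette for what this does
and does not emulate).

## Worked example

Score a synthetic rotor-chain ligand enclosed in a tight pocket shell and
evaluate a synthetic screening run:

```r
library(plscore)

tc <- make_toy_complex(toy_complex_spec("rotor_chain", "shell",
                                        n_rotors = 3, gap = 1.0))
d <- compute_descriptors(tc$complex)
d
#> <descriptor_vector>
#>       E_coul        E_vdW       E_lipo    E_entropy E_polar_solv    E_np_solv
#>     0.000000   -54.880651   733.274668     3.000000     0.000000    -4.114863

predict_linear(d, published_model("general-random"))
#> [1] -15.67898
```

The chain is apolar (`E_coul = 0`, no buried charges), in tight contact
(`E_vdW` deep, many lipophilic contacts), all three rotatable bonds freeze
(`E_entropy = 3`), and ~360 Å² of surface is buried (`E_np_solv = −4.11`
kcal/mol); the general model maps this to −15.7 kcal/mol.

```r
st <- make_screening_scores(n_active = 50, n_inactive = 2500,
                            separation = 2, seed = 7)
screening_metrics(st, ef_fractions = 0.01, bedroc_alphas = c(20, 100))
#> $auc       0.8889
#> $ef1       25
#> $ef1_max   51
#> $bedroc20  0.5584
#> $bedroc100 0.5106
```

With a 2-σ score separation the library is well ranked (AUC 0.89) and a
quarter of the theoretical maximum 1% enrichment (25 of 51) is achieved.

Real structures enter through `read_structure()` (PDB / SDF V2000 / MOL2,
explicit hydrogens required) followed by `assign_parameters()` and
`pl_complex()`. A command-line front end covering descriptor computation,
scoring, training and screening evaluation is installed at
`inst/scripts/plscore` (see `?plscore_main`).

## Retraining

`fit_mlr()`, `fit_svr()` (SMO ε-SVR with rbf/puk kernels) and `fit_rf()`
(bagged CART with `numTrees` / `numFeatures`) train on descriptor tables
(columns = term names, plus `dG_exp` in kcal/mol); `kfold_cv()` is the
tenfold cross-validation used for selection, `tune_model()` grid-searches
hyperparameters, and `ablation_selection()` implements the
one-term-at-a-time descriptor selection protocol starting from the
electrostatics + vdW basic function.

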