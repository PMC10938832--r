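---
title: "Temperature-dependent viscosity QSPR: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent viscosity QSPR: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical decisions taken
where more than one defensible convention exists.

## The modeling problem

Dynamic viscosity μ (cP) of a small organic liquid depends jointly on the
molecule and on temperature. Empirically the dependence follows the Vogel
form

$$\log_{10} \mu = A + \frac{B}{T - C},$$

with compound-specific parameters: an asymptotic offset $A$ (log₁₀ cP), a
fragility-like slope $B$ (K) and a divergence temperature $C$ (K) well
below the measured range. Modeling on the log₁₀ scale makes errors roughly
multiplicative and comparable across three decades of viscosity, and makes
$1/T$ the natural external feature to hand a regression model.

A QSPR model maps a molecular-descriptor vector plus inverse temperature
to $\log_{10}\mu$. The scientific question the evaluation protocol answers
is *generalization to unseen compounds*: all resampling is
compound-disjoint, because rows of one compound at different temperatures
are close to deterministic functions of each other and would otherwise
leak.

## Curation

Three filters run in a fixed order on raw records, then the log transform:

1. **Structure screen.** A record survives if its SMILES parses
   (OpenBabel via ChemmineR/ChemmineOB), is a single connected fragment,
   contains at least one carbon ("organic" operationalized as
   carbon-containing — water and fully inorganic species are excluded),
   and uses only {H, C, N, O, F, Si, P, S, Cl, Br, I}. Compound identity
   throughout the package is the OpenBabel canonical SMILES. One caveat:
   OpenBabel silently repairs some malformed strings, so "parseable" means
   "accepted by the toolkit", not "well-formed".
2. **Box-and-whisker screen.** Tukey fences
   $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are computed
   *once*, on the raw cP viscosities and Kelvin temperatures of the input
   set (linear-interpolation quantiles, `stats::quantile` type 7, a
   convention we fix because none is universal). A record outside either
   fence is removed. The screen is single-pass by design: fences are not
   recomputed after removals. Because experimental viscosity tables are
   right-skewed in cP, this filter genuinely trims the upper tail of
   legitimate data too — that is its documented, intended behavior on
   skewed inputs, and it is why re-curation of a curated dataset is a
   fixed point only when the surviving data is fence-compatible (compact,
   short-tailed); the suite verifies the fixed point on such data.
3. **Positive-deviation screen.** Bulk-liquid viscosity decreases with
   temperature, so within a compound (sorted by ascending T, ties broken
   by viscosity) a point whose viscosity exceeds the *last retained*
   point's by more than 0.02 cP (strictly; a 10⁻¹² guard absorbs binary
   floating-point representation error) is removed and scanning continues
   from the same anchor. Comparing against the last retained point rather
   than the raw neighbor preserves each curve's low-temperature anchor and
   converges in one pass. Typical positive deviations arise when sources
   disagree, so the removed point is the higher-temperature one of the
   violating pair.

## Featurization and preprocessing

Structure features are computed once per unique compound and broadcast:

* **2D block** (33 descriptors): OpenBabel bulk properties (MW, logP,
  TPSA, molar refractivity, H-bond donor/acceptor counts) plus graph
  quantities from the heavy-atom bond block — element counts, ring and
  rotatable-bond counts, branching, connectivity indices χ₀ and χ₁,
  Wiener index, graph diameter.
* **Fingerprint block** (1000 bits, radius 2): a hashed circular
  fingerprint implemented in the package (no installed R package provides
  circular fingerprints; OpenBabel's FP2 is path-based). Atom invariants
  (element, heavy degree, implicit-H count) are iteratively hashed with
  sorted (bond order, neighbor invariant) lists; every identifier from
  every radius sets one of 1000 bits. Radius 2 and binary bits are the
  common defaults for property modeling.
* **Composition block** (55 features): composition-weighted mean, min,
  max, range and standard deviation of tabulated elemental properties
  (mass, electronegativity, covalent and van der Waals radius,
  polarizability, ionization energy, valence electrons, period) over the
  molecular formula, plus atomic fractions.
* **External block**: inverse temperature always; optional MD or
  surrogate descriptors joined by (compound, temperature).

Preprocessing is fit on the training rows of each split only and applied
frozen everywhere else. The scan is keep-first greedy in column order: a
feature is dropped when its Pearson |r| with any earlier *kept* feature
reaches 0.90 (a 10⁻¹² tolerance absorbs floating-point error in the
cross-product correlations); zero-variance features are dropped next
(constant columns have undefined correlations and are skipped by the
greedy scan); survivors are standardized with training means and standard
deviations. Inverse temperature is standardized like every other feature.
Applying the transform twice standardizes twice — it is deliberately not
idempotent, so it must be applied exactly once per matrix.

On grammar-generated synthetic libraries the correlation filter is much
more aggressive than on diverse experimental chemistry (homologous series
make many descriptors collinear); a few hundred columns typically survive
from ~1100.

## Resampling, models, scoring

`out_of_sample_split()` shuffles compounds by seed and accumulates whole
compounds into the training set until it first reaches 80% of rows
(slight overshoot allowed). `grouped_kfold()` partitions training
compounds into five validation sets balanced by row count (largest-first
greedy onto the lightest fold), so fold sizes stay comparable when
compounds have unequal temperature coverage.

Eight algorithm families sit behind one registry: nnet (MLP), e1071
(RBF-kernel SVR), ranger (random forest), glmnet (LASSO), mixOmics (PLS),
and xgboost behind the three boosting flavors — depthwise unregularized
trees for classic gradient boosting, histogram + leaf-wise (lossguide)
growth for the light-gradient-boosting style, and the regularized default
for extreme gradient boosting. All fits are single-threaded and seeded
for replay.

Hyperparameters are tuned with single (un-bagged) fits per grid point on
the grouped folds — bagging every grid point would multiply cost twentyfold
for no ranking benefit — maximizing mean left-out R², ties broken by lower
mean RMSE, then first-in-grid. The shipped grids are small (2–3 values of
the dominant knob per family); users pass wider grids through `grids=`.
Cross-validation metrics are computed on the *pooled* left-out
predictions, not averaged per fold: pooling weighs every compound equally
and is the convention the parity-plot view of CV suggests.

The final model per (family, seed) is a 20-estimator bagged ensemble on
with-replacement resamples of the full training split; prediction = mean
over estimators; the 90% interval is the 5th/95th percentile
(linear-interpolation convention) of the 20 estimator predictions.
`Score_M = R²_test (1 − |R²_CV − R²_test|)` ranks families; negative R²
values on hard splits enter the formula unchanged.

The learning-curve experiment holds a fixed compound-disjoint 20% test
set per seed and draws nested compound-wise training subsets (smaller
subsets contained in larger ones, which removes subset-sampling noise
from the size axis). Curve fits are single estimators: the quantity of
interest is data efficiency, and the 20-seed spread provides the error
bars.

## Shapley attribution

Both estimators target interventional Shapley values: a coalition's value
is the mean model output with out-of-coalition features replaced by
background rows. The exact enumerator (≤ 15 features) is the oracle; the
permutation-sampling estimator batches one model call per (instance,
permutation) and is seeded. Attribution runs per bagged estimator on test
instances, with the test set itself as background; Mean|SHAP| averages
magnitudes over instances × estimators, the uncertainty is the standard
deviation across the 20 per-estimator means, and the sign is the sign of
the Pearson correlation between Shapley values and feature values (the r
value is reported so users can judge weak correlations; constant features
get an explicit "undefined"). Features correlated with a top feature at
|r| ≥ 0.90 are listed as its group, since the greedy preprocessing keeps
only one representative of each collinear cluster.

## MD descriptors

Computed from extended-XYZ frames (orthorhombic boxes; Å/ps/u/kcal·mol⁻¹
internally) with a JSON topology (masses, molecule membership, vdW radii
defaulting to a bundled Bondi-type table):

* density = Σm / V with 1 u = 1.66054×10⁻²⁴ g;
* radius of gyration: per molecule, mass-weighted about the center of
  mass after minimum-image unwrapping relative to the molecule's first
  atom (valid while molecular extent < half the box); frame value = mean
  over molecules;
* RMS displacement: per-atom minimum-image increments accumulated along
  the trajectory (no superposition — this is a mobility measure, not a
  structural RMSD);
* free volume: fraction of grid points farther than (vdW + probe) radius
  from every atom under minimum image, ×100; probe radius defaults to 0;
  the estimator converges to the Monte-Carlo point-sampling value as the
  grid spacing shrinks;
* cohesive energy density = −⟨E_inter⟩/⟨V⟩ converted at 6948.03 MPa per
  kcal·mol⁻¹·Å⁻³; solubility parameter = √CED, with electrostatic and
  van-der-Waals components from the corresponding energy shares
  (non-cohesive shares clamp to zero with a warning);
* heat of vaporization = −⟨E_inter⟩/n_molecules + RT
  (R = 1.98720×10⁻³ kcal·mol⁻¹·K⁻¹).

These are the standard textbook definitions, stated here because several
conventions (probe radius, RMSD reference, component decomposition) exist;
ours are fixed as above. `ensemble_descriptors()` averages per-frame
values over the trailing half of the trajectory (the production-run
convention of analyzing the equilibrated second half); the window's RMS
displacement is the mean displacement of the window's frames from the
window's first frame.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` draws per-compound Vogel parameters whose means shift
with two structure summaries:

* $A = -1.45 - 0.003\,n_\text{heavy} + 0.05\,n_\text{HBD} + 0.02\,z$
* $B = 40 + 3.5\,n_\text{heavy}^{1.5} + 45\,n_\text{HBD} + 3\,z$ (K)
* $C = 85 + 2.5\,n_\text{heavy} + 2\,z$ (K), capped at 190 K

with standard-normal $z$ drawn deterministically per (canonical SMILES,
seed). The superlinear size term reflects how chain length raises
viscosity faster than linearly in oligomers, and makes the
structure–property link genuinely nonlinear — on this data tree ensembles
beat linear models, the qualitative ordering real viscosity benchmarks
show. The small residual scales encode the premise that structure
determines the curve up to lab-level reproducibility (a few percent in
viscosity); coefficients put common esters near their experimental
viscosities (ethyl acetate ≈ 0.3–0.5 cP near room temperature) and keep
$C$ far below the coldest sampled temperature. These constants are this
package's modeling choices, not estimates of any particular dataset.

Default sampling: 200 compounds × 5 temperatures; compound windows of
120 K inside 230–400 K with window placement skewed toward lower
temperatures; temperatures stratified with jitter confined to the middle
of each stratum so adjacent points keep enough spacing that measurement
noise (log₁₀-scale sd 0.02) cannot fake a positive viscosity–temperature
deviation; viscosities clipped to 0.10–26.52 cP. The resulting pooled
log-viscosity distribution is right-skewed, as experimental tables are.
Two alternative sampling designs exist for fixtures: `"inverse"` spacing
(uniform in $1/(T-C)$, i.e. even in log-viscosity along the curve) and the
isoviscous `viscosity_band` mode, where every compound is measured across
a common log-viscosity band — the analogue of a rheometer's dynamic range
— which yields a bounded, near-uniform pooled distribution that is
compatible with Tukey fences. The curation test fixture combines the
isoviscous mode with the `homologous_midsize` preset (all grammar
structures with exactly 14 heavy atoms and no H-bond donors) and low
noise (sd 0.005), so that each curation filter fires exactly on its
injected violations: element violations from a fixed list of disallowed
or multi-fragment structures, range violations extreme in exactly one
variable and mid-distribution in the other, and positive-deviation
violations (+0.05 to +0.5 cP, comfortably above the 0.02 cP threshold)
anchored on each compound's highest-temperature record.

What the generator does *not* emulate: real chemical diversity (the
fragment grammar spans esters, ethers, carbonates, ketones, alcohols and
alkanes only, so descriptor collinearity is higher than in experimental
libraries), stereochemistry, inter-laboratory systematic offsets,
heteroscedastic measurement error, and any correlation between
measurement availability and viscosity. Passing tests therefore show the
pipeline's machinery is correct under its stated assumptions — not that
any particular accuracy carries over to experimental data.

## Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to make the
statistics stable while keeping a full run in minutes on one CPU: the
benchmark at 200 compounds × 5 temperatures over 5 seeds with the three
families that span the linear/tree contrast; learning curves over 20
splits at training sizes 100/300/690; attribution with 30 test instances,
20 background rows and 20 permutations per estimator; splitting
invariants at 300 compounds. Every stochastic step derives its seed
deterministically from a master seed (32-bit safe), so benchmarks replay
byte-identically from their manifests for deterministic families; the MLP
family is seeded and iteration-capped for the same reason.

## Known limitations

* The box-and-whisker screen on raw cP values removes legitimate
  high-viscosity tails of skewed datasets; users wanting a gentler screen
  can raise `range_k`.
* "Parseable" defers to OpenBabel, which repairs some malformed SMILES
  rather than rejecting them.
* The 2D and composition blocks are compact (33 + 55 features) compared
  with large descriptor libraries; the block structure is configurable
  and extensible, and counts are not asserted anywhere.
* PLS requires mixOmics (Suggests); without it the other seven families
  still run.
* Free-volume accuracy is grid-limited; halve `grid_spacing` before
  comparing absolute values across systems.
* The eight-family benchmark at full feature width is the slow path
  (~minutes); the spot checks in examples use family subsets.
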