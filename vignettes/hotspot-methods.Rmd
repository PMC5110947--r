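---
title: "Identifying hot-spot residues from fast GNM modes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying hot-spot residues from fast GNM modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnmhotspots)
```

## The scientific problem

Hot spots are the minority of interface residues that dominate the free
energy of protein–protein binding (conventionally, contributions above
~2 kcal/mol). Because experiments that map them — alanine-scanning
mutagenesis — are expensive, there is long-standing interest in predicting
them computationally, ideally from the *unbound* structure alone, on the
premise that hot spots are pre-organized in the intrinsic dynamics of the
monomer. `gnmhotspots` implements that idea in its most direct form: the
high-frequency normal modes of a Gaussian network model are used, raw, as
the feature space of a probabilistic classifier.

## Gaussian network model

Each chain is coarse-grained to its Cα atoms. Two residues interact
through a uniform harmonic spring iff their separation is at most the
cutoff $R_C$; the quadratic network potential then makes residue
fluctuations Gaussian and isotropic, and everything observable follows
from the Kirchhoff matrix $\Gamma$ (off-diagonal $-1$ for contacts,
diagonal = contact degree). With eigendecomposition
$\Gamma = U \Lambda U^\top$:

* cross-correlations over a mode subset $S$:
  $C_{ij} \propto \sum_{k \in S} \lambda_k^{-1} u_{ki} u_{kj}$;
* mean square fluctuation (MSF) weighted by $S$:
  $\langle \Delta R_i^2 \rangle_S =
  c\,\sum_{k \in S} \lambda_k^{-1} u_{ki}^2 / \sum_{k \in S} \lambda_k^{-1}$,
  with $c = 3 k_B T / \gamma$;
* mean square distance fluctuation (MSDF):
  $\langle \Delta R_{ij}^2\rangle = C_{ii} + C_{jj} - 2 C_{ij}$.

Modes are indexed from the fast end: hm1 is the eigenvector of the largest
eigenvalue. Fast modes are geometrically localized on the most tightly
packed network positions, which is why both the threshold baselines and
the classifier build on them.

Assumptions worth keeping in mind: a single uniform force constant, an
isotropic model (no directionality, unlike an anisotropic network model),
contacts from a hard distance cutoff, and Cα-only coarse graining.

### Numerical choices

* **Boundary rule.** A pair at exactly $R_C$ counts as a contact
  ($d \le R_C$). The inclusive rule is the common convention and the
  choice has measure-zero effect on real coordinates; it is applied
  consistently everywhere.
* **Eigenvector sign.** Eigenvector sign is arbitrary, but the GNB
  features are signed, so reproducibility requires a convention: the
  component of largest absolute value is made positive (ties: lowest
  index).
* **Degeneracy.** Near-equal eigenvalues (gap $< 10^{-8}\lambda_{max}$)
  make mode identity ill-defined; ties keep the sorted order of the
  decomposition and the spectrum object carries a `degenerate` flag.
* **Null space.** Eigenvalues below $10^{-10}\lambda_{max}$ are treated as
  zero; their count equals the number of connected components of the
  contact graph (checked against an independent graph traversal in the
  tests). Requesting a null mode in any fluctuation quantity is an error,
  not a silent infinity.
* **Scale.** $c = 3k_BT/\gamma$ defaults to 1: it divides out of
  normalized MSF, and a uniform scaling of features is absorbed into the
  fitted Gaussian parameters, so classification is invariant to it.
  Matrix sizes here (N ≤ a few hundred) need no sparse or cell-list
  machinery; dense `eigen(symmetric = TRUE)` is exact and fast.

## Feature coding

Two schemes encode residue $i$ from the mode matrix:

* `single_mode`: components of the $i$-th fastest mode only;
* `top_m`: the $m$ fastest modes stacked.

A sliding window of odd size `sw` adds the same components at sequence
offsets $-\frac{sw-1}{2} \dots +\frac{sw-1}{2}$, in **mode-major** order
(all window positions of hm1, then hm2, …). Offsets beyond the termini
are zero-filled by default so every residue has the same dimension — the
alternative (`boundary = "drop"`) discards incomplete windows and is
exposed as an option. Window offsets count positions in the retained Cα
trace, not residue numbers, so numbering gaps in real PDB files do not
skew windows.

## Gaussian Naive Bayes

The classifier is deliberately minimal: class priors are training
frequencies; each feature has a per-class Gaussian with the class mean
and *population* variance; features are conditionally independent given
the class. Scoring compares the posterior numerators
$P(y)\prod_j P(x_j \mid y)$ in the log domain (hundreds of density factors
underflow otherwise; the tests verify log- and linear-domain agreement
where the latter is representable). Ties — which occur, e.g., for an
all-padding feature row — go to the negative class: a residue is called a
hot spot only on a strict win.

Two tunables matter:

* `var_smoothing` (default $10^{-9}$): each variance gets an additive
  floor of `var_smoothing` × (largest pooled feature variance), so
  constant features (all-zero padded columns in one class) stay finite.
* Priors are *learned*, not uniform — on ~4% positive data the prior term
  is a large part of the decision, and forcing uniform priors would
  change the operating point substantially.

Posteriors (`predict(type = "prob")`) are normalized by log-sum-exp and
cross-checked in the test suite against an independent reference
implementation to $10^{-6}$.

## Baselines

The two classical MSF-threshold predictors label residue $i$ a hot spot
when its normalized fast-mode MSF strictly exceeds a threshold: a constant
0.005, or $6/N$ for chain length $N$. Since single-mode normalized MSF
averages to $1/N$, the $6/N$ rule asks for six times the average
fluctuation and is the stricter rule whenever $N < 1200$ — its prediction
set is then provably a subset of the constant rule's, which the tests
check on simulated chains. Both baselines run at the conventional 7.0 Å
cutoff by default.

The MSDF scorer aggregates each row of the fast-mode MSDF matrix (max by
default; mean over the other residues as an alternative) into a
per-residue ranking score. The historical selection rule that turned such
scores into labels is not fully specified in the literature this package
draws on, so the scorer deliberately returns a ranking and leaves the
labelling quantile to the user rather than inventing a cutoff.

## Evaluation protocol

Cross-validation is at **chain level**: chains are shuffled with a
recorded seed and dealt round-robin into $n$ folds (default 10), so fold
sizes differ by at most one and no residue of a chain appears on both
sides of a split. Confusion counts are pooled over folds
(micro-averaging) into a single sen/spe/pre/acc/F1 report per experiment
cell — the only averaging consistent with reporting one count-derived set
of indices per cell. F1 is defined as 0 when sensitivity or precision is
0, and any zero-denominator index is reported as 0 with a flag so grid
ranking never propagates NaN. The fold plan is one fixed seeded partition
per run, reused for every grid cell; the seed is a required, recorded
input because a random partition is otherwise unrecoverable.

On heavily imbalanced data, accuracy and specificity are nearly
uninformative (an all-negative predictor gets ~96% accuracy at 4%
prevalence); F1 is the ranking metric throughout.

## Synthetic data: what it emulates, and what it does not

The generator produces self-avoiding random walks with exact 3.8 Å
virtual bonds, a 4.0 Å excluded-volume radius, and confinement to a
sphere of radius $3.2\,N^{1/3}$ Å. The confinement constant was chosen
once so that the mean 7 Å contact degree of generated chains falls in the
protein-like range 4–14 (empirically ≈9–10, matching globular protein
density); chain lengths are drawn uniformly from 80–200 to mimic small
unbound chains, 30 chains per dataset at roughly the residue count of the
curated experimental sets this emulates. A blocked walk backtracks and,
if persistently stuck, restarts from the seeded stream, so generation is
deterministic given (seed, index) and fixture files are byte-identical
across runs.

Labels are planted from the model's own signal: residues above the 0.96
quantile of the normalized MSF over the 3 fastest modes at a planted
cutoff of 7.0 Å are positives (≈4%, the prevalence of curated hot-spot
datasets), then every label flips independently with probability
η = 0.1. Planting from MSF rather than raw mode components gives *both*
the GNB pipeline and the MSF-threshold baselines recoverable signal, so
comparative experiments have the structure of the published method
comparisons. The quantile is per chain, matching the per-chain planting
interface.

What passing recovery tests shows: the pipeline detects a
fluctuation-encoded minority class through 10% label noise and
cross-validation, and the grid search localizes the generating cutoff.
What it does not show: performance on real hot spots, whose relation to
fast-mode fluctuations is far weaker and confounded by chemistry the
model never sees (side chains, interface geometry, conservation).
Published F1 values on real datasets are an order of magnitude lower than
the synthetic recovery F1, and reproducing them requires the original
structures and labels, which this package reads (`read_ca_chain()`,
`read_labels()`, `hotspot_data()`) but does not bundle.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run: spectral invariants on 20
chains of 50–110 residues; the planted-signal experiment on the default
30-chain dataset (~4300 residues) with a 200-shuffle permutation null;
and cutoff recovery over 20 replicate datasets on an 11-point cutoff grid
(6.5–7.5 Å) with the planted scheme. These sizes give stable statistics
(the observed F1 exceeds the null's 95th percentile by a factor of ~7)
while keeping a full run in the low minutes on one core; the full
21-cutoff × 11-window × 20-mode grid of the original experimental design
remains available through `grid_search()` and the CLI for users with real
datasets.

## Known limitations

* Isotropic GNM only; no anisotropic network model, no B-factor
  calibration of the force constant.
* The MSDF baseline stops at a ranking score (see above).
* GNB assumes conditionally independent Gaussian features; window
  features of neighbouring residues are in fact correlated, which GNB
  ignores by construction (as do the published models it reimplements).
* PDB reading covers standard ATOM records (altloc by highest occupancy,
  first model by default, insertion codes honoured); mmCIF is out of
  scope.
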