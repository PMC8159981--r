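---
title: "Neural-gas analysis of depth-stratified microbial communities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-gas analysis of depth-stratified microbial communities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picogas)
```

This vignette is the package's account of its methods: the quantization
model and its schedules, the model-selection procedure and why it is built
the way it is, the preprocessing rules, the synthetic-data generator that
defines the test conditions, and the numerical and design choices a
maintainer would want spelled out.

## The quantization model

Samples are points in a feature space: nine standardized picoplankton
variables for the PIC analysis, or standardized genus-level relative
abundances for the BCC analysis. A codebook of $K$ units
$w_1,\dots,w_K$ is trained online. For each presented sample $x$, units are
ranked by Euclidean distance — $r_i(x)$ is the number of units strictly
closer to $x$ than $w_i$, with ties awarded to the lower unit index — and
every unit moves toward $x$:

$$ w_i \leftarrow w_i + \varepsilon(t)\, e^{-r_i(x)/\lambda(t)}\,(x - w_i). $$

Both schedules decay exponentially over the run,
$v(t) = v_0 (v_f/v_0)^{t/t_\max}$, where $t$ counts single presentations
and $t_\max = \text{epochs} \times n$. Defaults: $\varepsilon$ from 0.5 to
0.005, $\lambda$ from 2.5 to 0.01, 500 epochs, one shuffled pass over all
samples per epoch. "Epoch" is read as a full pass over the data; the
alternative reading (500 single presentations) would barely anneal a
22-sample dataset. The rank-based update has no topology bookkeeping: the
quantizer is used purely to place units in the populated part of feature
space, which is what lets a single extreme sample claim its own unit.

The quantization error is
$\mathrm{SSIntra}(X, W) = \sum_x \min_i \lVert x - w_i \rVert^2$, recorded
per epoch and at the end. Training is bit-reproducible from the seed: the
seed fixes the codebook initialization (default: $K$ distinct data rows)
and every epoch's presentation order.

Assumptions worth stating: features are standardized before training
(`zscore_normalize`, sample sd with denominator $n-1$), so each variable
contributes comparably and unit positions are interpretable as signed
anomaly profiles; Euclidean distance on standardized genus proportions is a
pragmatic choice, not a compositional-geometry one (log-ratio transforms
are deliberately out of scope).

## Choosing the number of units

The unit count is chosen from the dispersion of final SSIntra across
restarts (`ng_select_k`). Two details matter, and both were settled by
parameter-recovery experiments on planted clusters rather than by
convention:

**Restarts must be under-annealed to carry information.** With the full
schedule ($\lambda$ from 2.5, 500 epochs) the quantizer converges to the
same solution from almost any initialization, so the restart-to-restart
coefficient of variation of SSIntra sits at numerical noise
($\sim 10^{-7}$) for several $K$ at once, and "minimum CV" picks among
them arbitrarily. Selection restarts therefore use a reduced neighbourhood
range ($\lambda$ from 0.5) and shorter runs (100 epochs) — each restart is
still fully converged (the step size still ends at 0.005), but different
restarts now land in different local optima wherever several exist. The
restart ensemble probes the optimum landscape instead of collapsing onto
one point of it.

**The decision rule is a stability rule.** For each $K$ the *basin share*
is the fraction of restarts whose final SSIntra matches the best one within
1% relative tolerance. At the true cluster number a single dominant basin
captures nearly every restart; with one unit too many, which cluster gets
split varies across restarts; with one too few, which clusters merge
varies. The chosen $K$ is the largest one with share $\ge 0.9$ (fallback:
maximal share, ties to the smaller $K$). Plain minimum-CV remains available
(`rule = "min_cv"`), and the full table (mean, sd, CV, share per $K$) is
always returned so any other rule can be applied by the user. The
acceptance suite verifies that on 22-point datasets with four planted
Gaussian clusters at separation 5 within-cluster sd in 9 dimensions, the
procedure picks $K=4$ and the trained assignment matches the planted
labels (ARI $\ge 0.9$) in at least 9 of 10 generator seeds.

Known limitations, stated plainly:

* Reliability degrades as the cluster count approaches what the sample
  size supports (five clusters in 22 samples is already noticeably harder
  than four) and when separation drops much below 5 sd.
* In high-dimensional spaces with a singleton cluster (the 40-genus BCC
  block with one deep sample), under-annealed restarts rarely migrate a
  unit across the large empty gap onto the singleton, so the share at the
  true $K$ is depressed and selection falls back to fewer units — visible
  in the stage-3 table of the analysis scripts. The best-of-restarts
  *training* (below) still finds the singleton solution, because a few
  restarts do start with a unit on it and those win on SSIntra.

**Final training** (`ng_train_best`) uses the same under-annealed restarts
and keeps the lowest-SSIntra model. Best-of-restarts with the *full*
schedule would be pointless — every restart returns the same model — and
that model systematically refuses singleton clusters: the annealing drags
all units toward the data bulk, and serving a lone extreme sample never
pays during the high-$\lambda$ phase. Diverse restarts plus an SSIntra
argmin is the standard vector-quantization remedy.

## Preprocessing rules

* **Taxonomic filter**: keep ASVs whose domain is "Bacteria"
  (case-insensitive) and that carry no "Chloroplast" / "Mitochondria" /
  "Mitochondrion" label at *any* rank — classifications place chloroplasts
  at order and mitochondria at family level, so only scanning the genus
  column would miss them. Samples emptied by the filter are kept, with a
  warning.
* **Prevalence filter**: keep ASV $j$ iff it has $\ge$ `min_count`
  (default 3) reads in $\ge \lceil \texttt{min\_fraction} \cdot n \rceil$
  samples (default 20%). This is the conventional keep-side reading of the
  removal phrase "seen less than three times in at least 20% of samples";
  the ceiling implements "at least" for fractional thresholds. The filter
  is applied after the taxonomic filter; only that order is canonical.
* **Agglomeration** sums counts over ASVs sharing the label at the target
  rank; ASVs lacking the label are pooled under their finest available
  ancestor label suffixed `_unclassified`, so read totals are conserved
  exactly and unassigned reads stay visible rather than vanishing.
* **Limitation classification**: P-limited iff SRP $< 0.1\ \mu$mol/L and
  TIN/SRP $> 22$ and SiO$_4$/SRP $> 22$; N-limited iff TIN $< 1\ \mu$mol/L.
  N/P is computed from the inorganic pools (TIN/SRP), since the criteria
  reference inorganic stoichiometry. SRP $= 0$ yields $+\infty$ ratios and
  the inequalities apply as written. The extended N-limitation variant
  (TIN $< 1$, TIN/SRP $< 10$, Si/TIN $> 1$) is reported as a separate
  column (`n_limited_ext`) and never folded into `n_limited`.

## Diversity

Shannon $H' = -\sum p_i \ln p_i$ (nats by default; base exposed) and
Pielou $J' = H'/\ln S_{obs}$ are computed on the untransformed, unrarefied
— but filtered — count table; which table was used is recorded on the
result. $J'$ is undefined for single-taxon samples and reported as `NA`
with a warning. Rarefaction uses the exact hypergeometric expectation
$E[S_n] = \sum_i \left(1 - \binom{N-N_i}{n}\middle/\binom{N}{n}\right)$
(via `vegan`, i.e. log-Gamma arithmetic), deterministic by construction; a
Monte-Carlo subsampler is kept for cross-checking and agrees within three
standard errors in the tests. Spearman correlations use average ranks and
the t-approximation for p-values; no multiplicity correction is applied
because none is part of the analysis being reproduced.

## Cluster characterization

Per-unit summaries report mean and sample sd of each variable in its
original units; sds of singleton units are `NA`, and n-weighted unit means
recover the grand mean exactly (tested). Composition profiles are
unweighted means of member samples' proportion vectors; taxa below the
`other_threshold` per unit are pooled into "other", preserving the unit
sum of 1, and raising the threshold can only shrink the named-taxon set.

The salinity relationship is summarized by anomaly-direction concordance:
a sample "opposes" when the sign of its salinity anomaly differs from the
sign of the per-sample *median* of the comparator anomalies, both nonzero.
The median was chosen over "majority of pairwise oppositions" (available
via `method = "pairwise"`) because it is robust, reproduces the all-agree
and all-oppose limits, and needs no extra tie rule; exact zero anomalies
count as non-opposing so degenerate inputs stay deterministic.

## The synthetic-data generator

The generator defines the conditions under which everything is tested. Its
defaults emulate a late-summer, depth-stratified survey of six open-sea
stations: 22 samples at the stations' fixed depth grids (0–100 m), four
community types tied deterministically to depth bins (breaks at 25, 60 and
90 m, giving occupancies 11/6/4/1 — the deepest bin is a single sample),
sequencing depths lognormal with mean 93,317 reads and CV 0.247, ~5% of
reads in contaminant ASVs (eukaryotic, chloroplast, mitochondrial), and 30
rare ASVs planted to fail the prevalence rule by construction (their reads
are moved from each sample's top ASV, so row sums stay exact).

Genus compositions are Dirichlet-multinomial: each genus has a preferred
depth bin and a lognormal abundance weight; cluster base compositions decay
away from the preferred bin; within-cluster variation comes from a
Dirichlet draw at concentration 200; each genus is split over 1–5 ASVs
with fixed weights, so agglomeration is a nontrivial, testable step.
Environmental profiles are monotone parametric depth curves plus noise
(temperature 22.6 °C at the surface to ~13 °C at depth, nutrients
increasing with depth, a Gaussian chlorophyll-fluorescence peak at 70 m);
TIN is the exact sum of its components, so the metadata invariants hold by
construction. Picoplankton vectors are per-bin means plus Gaussian noise;
the bin means are calibrated to the observed ranges of the emulated system
and the within-bin sds to the low end of the observed per-cluster spreads,
so the planted bins sit at least 5 within-cluster sd apart in normalized
space — the separation scale at which quantization recovery is a fair ask.
The deep bin is an extreme endpoint (collapsed stocks, HNA dominance)
rather than an average over moderately deep casts: with a singleton
cluster, a sum-of-squares quantizer only dedicates a unit to it when it is
genuinely far out, which also matches how such surveys describe their
deepest sample.

Salinity carries the planted association: with $b$ the standardized mean
anomaly of the abundance-type variables (tp, syn, prochl, pe, hnf, aap,
bp), salinity is $38.8 + 0.05\,(\rho b + \sqrt{1-\rho^2}\,\epsilon)$ with
$\rho = -0.9$. The realized correlation is verified on a 500-sample design.
The within-sample covariance of the picoplankton block is otherwise
diagonal — a modeling choice, since only this covariance structure matters
to the analysis.

One statistical point shapes how the concordance property is tested: the
opposition fraction is a ratio estimator over samples, and at $n=22$ its
seed-to-seed standard deviation is large relative to the distance between
its expectation and the 0.8 threshold, so single-survey fractions scatter
widely around the mean regardless of implementation correctness. The
property test therefore runs on a densely sampled water column (3 stations
× 40 depths, $n=120$; same generator, same $\rho$), where the fraction
concentrates; the 22-sample default design is used everywhere else, and
stage 4 of the analysis prints its (noisier) single-survey fraction.

What the generator does *not* emulate — and hence what green tests do not
show about real data: sequence-level error and chimera structure (the
artifact consumes a finished ASV table), phylogenetic correlation among
taxa, compositional covariance beyond the planted cluster structure, any
coupling between alpha-diversity and the chlorophyll maximum (the observed
diversity–chlorophyll correlations in the synthetic survey are incidental),
and real hydrographic covariance between temperature, salinity and
nutrients beyond monotone depth trends.

`generate_planted_clusters` (used by the recovery experiments) draws
isotropic unit-variance Gaussian clusters with iid-normal centers rescaled
so the *minimum* pairwise distance equals the requested separation. Points
landing nearer another planted center than their own are redrawn, so the
planted labels coincide with the nearest-center partition — without this,
at separation 5 in 9 dimensions a noticeable fraction of 22-point draws
contains a label-inconsistent point that no clustering method could
recover. Its output is already standardized by construction and is fed to
the quantizer directly; z-scoring it would shrink precisely the
informative dimensions (they carry the between-cluster variance) and lower
the effective separation below the stated value. A regular-simplex center
geometry (all pairs exactly at the stated separation) was evaluated and
rejected: in 9 dimensions equidistant clusters at 5 sd overlap enough that
even training at the true $K$ becomes unstable.

## Numerical choices and degenerate inputs

* Ties (distance ranks, assignments) always resolve to the lower unit
  index; determinism everywhere is bit-level given the seed.
* Constant features z-score to all-zero columns with a warning and are
  flagged on the result.
* `ng_select_k` defines CV $=0$ when the mean SSIntra over restarts is 0
  (perfect quantization); the basin-share tolerance is 1% relative.
* A single data point trains to all units on that point; $K >$ n falls
  back to bounding-box initialization.
* Zero-total samples abort `to_relative` with the sample named; an SRP of
  0 produces infinite stoichiometric ratios rather than an error.
* The `exp(-rank/lambda)` factor underflows harmlessly for
  $\lambda \to 0$, which is exactly the winner-take-all limit used to
  cross-check training against an online k-means oracle.

## Problem sizes used by the tests

The suite runs at the survey's own scale: 22 samples throughout the
pipeline tests; 1,000 random toy tables (≤ 20 × 50) for the filter
oracles; 1,000 random records for the limitation rules; 10 generator seeds
for each recovery/concordance property; 10,000 Monte-Carlo draws for the
rarefaction cross-check; 500 samples for the planted-correlation check;
120 samples for the concordance property. The full suite and the
acceptance script each finish in a few minutes on one CPU.
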