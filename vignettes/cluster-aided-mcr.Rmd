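---
title: "Cluster-aided MCR-ALS: identifying reliable components without choosing k"
author: "camcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-aided MCR-ALS: identifying reliable components without choosing k}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camcr)
```

## The problem

Multivariate curve resolution by alternating least squares (MCR-ALS) models a
non-negative data matrix `D` (samples x spectral bins, here binned 1D NMR
spectra) as a bilinear product

    D = C %*% t(S) + E,

where the columns of `C` are concentration profiles across samples, the
columns of `S` are spectral profiles across bins, both constrained
non-negative, and `E` is residual noise. Like all component models, MCR-ALS
requires the number of components `k` to be chosen in advance, and the many
conventional estimators of `k` (Kaiser criterion, scree, parallel analysis,
CNG, multiple regression, cross-validation, cumulative contribution — all
implemented in `estimateComponents()`) routinely disagree on real
metabolomics data.

Cluster-aided MCR-ALS sidesteps the choice. The factorization is repeated
for every `k` from 1 up to a maximum (the number of samples, since the PCA
scores used for initialization provide at most that many columns), and all
concentration profiles from all runs are pooled. A component that reflects a
real constituent of the mixtures re-emerges, nearly unchanged, in run after
run; a noise component appears once or twice. Reliability is therefore
measured by reproducibility: the pooled profiles are clustered, and a
cluster that (a) is statistically supported, (b) is larger than anything
that arises in randomized data, and (c) is internally coherent, is accepted
as a *reliable cluster* representing one underlying component.

## The pipeline

1. **Preprocessing** (`binSpectrum()`, `excludeRegions()`,
   `normalizeTotal()`). Raw (ppm, intensity) spectra are summed into
   half-open bins of fixed width (0.04 ppm for urine-style data giving 250
   variables over 0-10 ppm, 0.02 ppm for fecal-style data giving 500); bins
   whose centers fall in excluded regions (the DSS internal standard near 0
   ppm; water/urea at 4.5-6.25 ppm for urine) are removed, and each spectrum
   is then divided by its own total over the retained bins. Binning by sum
   (not mean) preserves total-intensity semantics; exclusion uses bin
   centers because published region endpoints (e.g. 0.277 ppm) need not be
   bin boundaries; bin labels denote centers.

2. **The sweep** (`runSweep()`). One ALS fit per `k`, each initialized from
   the first `k` PCA score columns of the column-centered data (each
   column's sign fixed so it projects positively on the samples' total
   intensities — oriented away from the data, a score column can be
   annihilated by the first constrained half-step) and an all-ones
   spectral matrix. The pool holds `kmax*(kmax+1)/2` components before
   zero-component removal — 210 at `kmax = 20`, 4005 at `kmax = 89`. The
   ALS alternates exact non-negative least squares half-steps (per-bin,
   then per-sample), so the residual sum of squares never increases; the
   solver is a warm-started Bro-De Jong active-set NNLS on the normal
   equations, with iteration stopping when the relative residual change
   falls below `tol = 1e-8` or at `maxIter = 200` alternations. Because the
   product `C %*% t(S)` rather than either factor alone is identifiable,
   all downstream comparisons of profiles use correlations.

3. **AU clustering** (`auCluster()`, `pickClusters()`). The pooled
   concentration profiles are clustered with the correlation distance
   `1 - r` and average linkage (UPGMA). Cluster uncertainty is assessed by
   multiscale bootstrap: for each scale `r` in 0.5, 0.6, ..., 1.4 (ten
   scales), `nboot` bootstrap datasets are drawn by resampling
   `round(n * r)` of the `n` sample-columns with replacement — the sample is
   the observation unit of a concentration profile — and each internal
   node's bootstrap probability BP is the fraction of bootstrap trees
   containing its exact leaf set. The approximately unbiased p-value of a
   node comes from the scale dependence of BP: with
   `z_r = qnorm(1 - BP_r)`, a weighted least-squares fit of
   `z_r ~ v*sqrt(r) + c/sqrt(r)` (weights from the delta-method binomial
   variance of BP) yields `AU = 1 - pnorm(v - c)`. Nodes with `AU > 0.95`
   are selected; among nested selections only the maximal cluster is kept,
   so selections are disjoint.

4. **Reliability filtering** (`sizeThreshold()`, `selectReliable()`). The
   same clustering, selection, and refinement are applied to randomized
   pools in which each record's concentration values are independently
   permuted across sample positions; the largest cluster a replicate can
   *accept* — selected, refined, internally coherent — is recorded, the
   maximum over replicates (default 10; 5 for the scaled standard-mixture
   runs; ideally 1000+) becomes the threshold, and real clusters count
   only if strictly larger. Calibrating the threshold on the same
   statistic the analysis accepts matters at small sample counts: the raw
   selected size of a shuffled pool is dominated by large AU-extrapolation
   artifacts with near-zero internal correlation, clusters the pipeline
   could never accept, and a threshold read off those would exceed every
   genuine cluster.
   Clusters whose minimum internal pairwise correlation is at most 0.6 are
   recursively refined (`refineCluster()`): by default the members' own
   correlation-distance UPGMA dendrogram is divided at its top split and
   both halves are refined, a deterministic recursion; sub-clusters at or
   below the size threshold are dropped, so each accepted cluster ends
   internally coherent, disjoint, and above-threshold. An alternative
   refinement (`method = "au"`) re-runs the full bootstrap selection on
   the members; at small `nboot` its accept/discard decisions for
   borderline cores are themselves resampling noise, which is why the
   deterministic recursion is the default.

5. **Summaries** (`summarizeClusters()`, `detectionScore()`). Each member
   contributes its rank-one matrix `concentration %o% spectrum`; the
   element-wise mean, SD and CV across the member stack describe the
   cluster, the row and column of the mean matrix through its global
   maximum serve as the typical spectral and concentration profiles, the
   sum of squared deviations (SSD) of the typical concentration profile
   ranks clusters by information content, and in evaluation mode a compound
   counts as detected when some cluster's typical concentration profile
   correlates with its known series above 0.8.

## Numerical choices

* **NNLS subproblems** are solved exactly (active set), not by projected
  gradients: exactness is what guarantees the monotone-residual invariant
  that the tests assert. Warm starts reuse the previous iteration's active
  set; the KKT conditions are re-verified on exit, so warm starting changes
  the path, never the solution.
* **Degenerate AU fits.** Scales where BP is exactly 0 or 1 carry no
  information about the scale dependence and are excluded from the
  (v, c) fit. The fit is attempted only when it has positive residual
  degrees of freedom — at least three interior scales. With fewer, the node
  is classified by its mean BP (AU = 1 when the node is present in
  essentially every bootstrap tree, 0 when absent). Without this guard an
  exact two-point fit can extrapolate a node that almost never forms
  (BP near 0 at every scale) to AU = 1, which both inflates the
  randomized-data size threshold and swallows genuine clusters into
  spurious near-root parents.
* **The dendrogram root is never a candidate**: the full pool is contained
  in every bootstrap tree by construction, so its BP is 1 at every scale
  and maximal-cluster selection would otherwise always return the entire
  pool.
* **Bootstrap replicates that flatten a profile** (a record constant within
  a resample, correlation undefined) assign that record the maximal
  distance 2 for that replicate. Records constant in the *observed* pool
  carry no pattern at all and are excluded before clustering.
* **Ties.** UPGMA tie-breaking follows `stats::hclust`, which is
  deterministic for a given input; typical-profile ties resolve to the
  first cell in row-major order; estimator ties resolve to the smallest
  candidate.
* **Zero components** are dropped when the largest absolute entry of the
  concentration or spectral column is at most `1e-12 * max(D)`.

## The synthetic generator

`standardMixturePreset()` emulates a designed standard-mixture experiment
on the 250-bin 0-10 ppm grid: fifteen named compounds with Lorentzian peak
signatures (half-width at half-maximum 0.015-0.02 ppm, centers on the bin
grid) at chemical shifts typical of urine/feces metabolites, plus a fixed
set of 25 low-intensity trace signals. Seven major compounds (alanine,
lactate, butyrate, formate, citrate, creatinine, hippurate) carry mutually
distinct concentration patterns; each has a multi-peak signature or at
least one resonance in an uncrowded region, with comparable total spectral
energy, as real standard-mixture compounds do. Three compounds (glucose,
trehalose, ethanol) share one concentration pattern up to 5% multiplicative
jitter (pairwise r >= 0.9) and crowd the 3.2-3.9 ppm sugar region: the
concentration-confounded case in which the clustering can, at best, assign
one cluster to several compounds. Five minor compounds at roughly a fifth
of the major intensities (including taurine, whose doublet is spectrally
confounded with glucose) and the trace signals give the data the gradually
decaying variance spectrum of real spectra. This tail matters: against a
hard-rank matrix, factorizations with more components than compounds gain
nothing by absorbing residual noise and instead split major profiles along
samples, destroying the reproducibility the method relies on; with a
realistic signal tail the extra components absorb minor variation and the
major profiles re-emerge essentially unchanged across the sweep.

Concentration series are log-normal (sdlog = 0.8), with each compound
deliberately absent from a fifth of the samples — the contrast of a
designed dilution series. The absences are what make the non-negative
factorization essentially unique: with an everywhere-positive design an
exact continuum of rotated solutions exists (component A's spectrum can
absorb a fraction of B's while B's concentration sheds a multiple of A's,
all constraints intact), and which compounds come out pure is then a
lottery of the optimization path. Heavier-tailed or zero-inflated designs
were rejected on the null side: shuffled profiles then cluster by their
dominant positions or common supports, inflating the randomized size
threshold. Distinctness is enforced by redrawing a series until its
correlation with all earlier distinct series is below 0.3 (well under the
0.7 used to define "distinct" in evaluation). Noise is i.i.d. Gaussian,
truncated at zero, with standard deviation defaulting to 1% of the mean
noise-free intensity.

What the generator does *not* emulate: peak-position drift between samples
(bin-boundary effects), baseline and phase artifacts, multiplicative
(intensity-dependent) noise, and peak-shape variation. Passing tests on
this generator therefore demonstrate the pipeline's statistical machinery —
reproducibility pooling, AU selection, null thresholding, refinement — not
robustness to those instrumental effects.

## Problem sizes used in the tests

The test-suite runs are scaled so the whole suite stays lightweight: sweeps
use 20 samples with `kmax = 20` (and one 89-sample count-law check run at a
reduced ALS iteration budget, since the pooled count is a purely
combinatorial property), AU clustering uses `nboot = 200` with the full ten
scales, and the size threshold uses 5 shuffle replicates — the same
configuration as the scaled standard-mixture evaluation. The defaults
(`nboot = 1000`, 10 shuffles, `kmax` = number of samples) reproduce the
full-scale procedure.

At this scale the randomized-data size threshold is substantial relative
to the cluster sizes the preset's compounds can attain: with only 20
samples the bootstrap correlation estimates are noisy and the AU
extrapolation is anticonservative, so shuffled pools support moderately
sized chance clusters. This is the regime the threshold exists for;
reliable clusters of well-resolved compounds clear it, but the margin
shrinks for compounds whose spectra are heavily confounded, and a
factorization that never resolves a compound (a rotational local optimum
of the ALS — possible for any particular dataset) leaves that compound
undetected, exactly as with real standard mixtures.

## Design choices that were genuinely open

* **Shuffle semantics.** The null permutes each record's concentration
  values independently across sample positions. This destroys exactly the
  inter-profile correlation the clustering feeds on while preserving each
  profile's marginal distribution. A global shuffle of the whole matrix was
  evaluated and discarded: it homogenizes all records toward the pooled
  marginal and produced *larger* chance clusters, i.e. a strictly less
  faithful null.
* **SSD operand.** The sum of squared deviations that ranks clusters is
  computed over the typical concentration profile — the object the
  clustering itself works with and the one compared across clusters in
  reports. The mean-matrix variant is a one-line change kept out of the
  default surface.
* **CV at zero mean** is defined as 0 (cells without signal), so reports
  carry no NaN.
* **Sample standard deviation** (n - 1) is used in cluster statistics; with
  cluster sizes above any reasonable threshold the difference from the
  population variant is immaterial.
* **Scree stays visual.** `screeTable()` exports the spectrum; the panel
  function reports the acceleration (second-difference) point as a numeric
  stand-in, clearly labelled, because a fully automated scree decision
  would misrepresent the method.
* **Parallel-analysis reference** is the mean of the random eigenvalues
  (the classic variant); a quantile option is exposed.
* **Concurrency.** Sweep runs and bootstrap replicates are logically
  independent; the implementation executes them sequentially with
  per-replicate seeds derived from the master seed, so any future parallel
  execution cannot change results.

## Limitations

* AU p-values are asymptotic in the number of samples; at 20 samples they
  are anticonservative, which the randomized-data threshold compensates
  but does not eliminate.
* Concentration-confounded compounds are fundamentally unresolvable from
  concentration patterns alone; the method reports one cluster for the
  trio, as expected.
* The refinement recursion can trim borderline members of genuine
  clusters, and a coherent core that ends at or below the size threshold
  after trimming is lost; the divisive recursion makes these decisions
  deterministic but not infallible.
* Binning absorbs only small chemical-shift drift; signals that straddle a
  bin boundary in different samples can split into separate clusters.
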