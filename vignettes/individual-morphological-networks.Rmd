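---
title: "Individual morphological covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcn)
```

## The model

A morphological covariance network summarises, for one subject, how similar
the gray-matter composition of every pair of brain regions is. Unlike
population-level structural covariance (one network per group, built from
across-subject correlations of regional summaries), the individual variant
uses the full *distribution* of voxel gray-matter volume (GMV) values
inside each region, so each subject gets their own network:

1. **Nodes.** The 90 cortical and subcortical regions of the AAL cerebrum
   parcellation (packaged as `aal90_regions()`); any integer-labelled
   parcellation works.
2. **Regional distributions.** For region $r$, the voxel values
   $x_{r1}, \dots, x_{rn_r}$ are turned into a probability density
   $\hat f_r$ by Gaussian kernel density estimation,
   $\hat f_r(y) = \tfrac{1}{n_r h_r}\sum_i \phi\!\big((y - x_{ri})/h_r\big)$,
   with Silverman's rule-of-thumb bandwidth $h_r$ by default.
3. **Edges.** For each pair $(r, s)$ the symmetrised Kullback--Leibler
   divergence is computed by discrete summation on a shared grid,
   $D_{rs} = \mathrm{KL}(\hat f_r \| \hat f_s) +
   \mathrm{KL}(\hat f_s \| \hat f_r)$, and mapped to the edge weight
   $w_{rs} = e^{-D_{rs}} \in (0, 1]$. Identical distributions give 1;
   the weight decays monotonically as the distributions separate.
4. **Binarization.** The weighted $90 \times 90$ matrix is thresholded at a
   *sparsity* $s$: the $K = \lfloor s \cdot R(R-1)/2 \rfloor$ strongest
   off-diagonal weights become edges. Because no single sparsity is
   canonical, the analysis runs over $s = 0.05, 0.07, \dots, 0.39$
   (18 levels) with trapezoidal area-under-curve summaries across the grid.

Graph topology is then characterised per network: clustering coefficient
$C_p$, characteristic path length $L_p$, global and local efficiency
$E_g, E_{loc}$, degree assortativity, modularity, nodal degree and nodal
betweenness, plus small-world indices
$\gamma = C_p / \bar C_p^{null}$, $\lambda = L_p / \bar L_p^{null}$,
$\sigma = \gamma / \lambda$ normalised against degree-preserving
(Maslov--Sneppen double-edge-swap) null networks.

Group inference uses a partial-F ANCOVA engine (group factor adjusted for
covariates) applied voxelwise to GMV maps and to scalar network measures,
Benjamini--Hochberg FDR and cluster-extent thresholding for voxelwise maps,
pairwise pooled-variance *t*-tests with Bonferroni correction post hoc, and
Pearson correlations with BH-FDR for clinical associations.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| KDE bandwidth | Silverman per region (`bw_adjust = 1`) | standard rule; exposed as a multiplier |
| Evaluation grid | 128 points, pooled range $\pm$ 3 bandwidths | shared support is required for a finite KL; padding captures kernel tails |
| Density floor | $10^{-10}$, then renormalise | prevents infinite KL where one density vanishes; negligible bias |
| Sparsity grid | 0.05--0.39 step 0.02 | spans sparse-but-connected to dense regimes |
| Smoothing | 8-mm FWHM Gaussian, zero-padded | conventional VBM choice; kernel is unit-mass so interior signal is conserved |
| Analysis mask | GMV > 0.1 in $\ge$ 90% of subjects | excludes background/edge voxels; configurable |
| Cluster rule | 18-connectivity, size strictly > 30 | common neuroimaging convention; 6/26 available |
| Null model | 100 rewired graphs, 10 swap attempts/edge | stable $\bar C_p^{null}, \bar L_p^{null}$ at acceptable cost |
| Modularity | greedy agglomeration + 10 seeded refinement restarts | deterministic given the internal seeds |

## Numerical and degenerate-input choices

* **Disconnected graphs.** $L_p$ averages over connected pairs only (the
  disconnected-pair count is reported); $E_g$ uses $1/\infty = 0$. An
  edgeless graph reports $C_p = E_g = 0$ and a flagged missing $L_p$.
* **Ties at binarization.** Equal weights are broken by ascending
  (row, column) order, so networks are bit-reproducible across platforms.
* **Degenerate regions.** A region whose voxels are all identical has no
  bandwidth; by default this errors, naming the region. An opt-in
  deterministic jitter spreads such samples over a $10^{-6}$ interval.
* **Negative voxels.** GMV maps are clipped at 0 on load with a warning
  count: densities are non-negative by definition, but interpolation during
  spatial normalisation can produce small negative values.
* **Atlas regridding.** Label volumes are resampled by nearest neighbour
  through both affines; labels are never interpolated continuously.
* **Covariates undefined for controls.** A three-group model with clinical
  covariates (PANSS, illness duration) that exist only for patients is not
  estimable as stated: the default policy drops such covariates from the
  three-group model (with a message) and keeps them for patient-only
  contrasts; mean-imputation and strict-error modes are available.
* **Summary-statistic tests.** Group comparisons reconstructed from printed
  means/SDs/sizes use the pooled-variance (Student) *t*; the Welch variant
  is available but does not reproduce summary tables computed under the
  pooled convention. Statistics reconstructed from rounded summaries are
  accurate only to about one unit in the inputs' last printed digit.

## The synthetic cohort generator

Because clinical MRI cohorts cannot ship with a package, `imcn` includes a
fully deterministic generator emulating a three-group design (healthy
controls, non-violent and violent patients; 22/23/18 subjects) so every
stage is testable end to end:

* **Images** (`generate_gm_cohort()`): a 90-region Voronoi-style
  parcellation of an ellipsoidal "brain" on a $32^3$ grid of 4-mm voxels
  (about 12,000 mask voxels, roughly 140 voxels per region — a
  desk-scale stand-in for a full-resolution brain). Voxels in region $r$
  are drawn from $\mathcal N(\mu_r f_i g, 0.1^2)$ truncated at 0, with
  baseline means $\mu_r \sim U(0.4, 0.7)$, a per-subject global scale
  $f_i \sim \mathcal N(1, 0.02^2)$, and a planted atrophy gradient
  $g = 1, 0.9, 0.8$ (HC, NSZ, VSZ) in one designated region — a 10%
  reduction per group step, a strong but realistic regional effect.
* **Networks** (`generate_network_cohort()`): one Watts--Strogatz graph
  per subject (90 nodes, lattice degree 8) with group rewiring
  probabilities 0.05 / 0.15 / 0.30 plus per-subject jitter (SD 0.02).
  Rewiring shortens paths, so $E_g$ rises and $L_p$ falls along the group
  gradient while the edge count stays fixed.
* **Clinical scores** (`generate_clinical_scores()`): PANSS and MOAS are
  linear functions of a signed composite of each subject's realized planted
  measures plus noise (composite correlation $\rho = 0.85$), with signs
  fixed so GMV and nodal degree couple negatively and global efficiency
  positively (MOAS), and the linear map chosen so the expected patient
  group means match the emulated demographic table. In the MOAS composite
  the nodal-degree weight is 2 (GMV and efficiency weight 1): degree has no
  between-group gradient under degree-preserving Watts--Strogatz rewiring,
  and the heavier weight balances every planted coupling at a pooled
  correlation near 0.5--0.6 over the 41 patients, which a power analysis
  shows is needed for reliable FDR-significant recovery at that sample
  size. Illness duration is drawn from per-group gamma distributions
  matching the emulated means/SDs. Controls' clinical fields stay missing.

The two generators are deliberately separate: networks built from the
image cohort control topology only indirectly, so topology-gradient claims
are tested on the network generator and regional/correlation claims on the
image generator, each against its own recorded ground truth.

**What passing these tests shows — and what it does not.** The synthetic
cohorts have homogeneous Gaussian within-region distributions, a single
planted effect, no spatial autocorrelation beyond smoothing, no scanner or
segmentation artifacts, and no realistic anatomy. Recovery of the planted
effects therefore validates the *machinery* (extraction, KDE/KL edges,
thresholding, graph measures, inference, correction) — not the sensitivity
or specificity of the method on real clinical data.

## Design decisions taken where the construction was open

* **Similarity transform.** The divergence-to-similarity map is
  $e^{-D}$: symmetric, bounded in $(0,1]$, and the de-facto standard for
  this network construction.
* **Per-sparsity vs AUC inference.** Group comparison of network measures
  defaults to the per-metric AUC over the sparsity grid (single test per
  metric, no per-level multiplicity); per-sparsity records remain
  available.
* **Nodal degree comparisons** default to the global mean degree, with
  per-node vectors exposed for nodal analyses.
* **Betweenness** is reported as raw pair counts; a normalised option
  divides by $(R-1)(R-2)/2$.
* **FDR families.** All (measure, score) pairs of one correlation run are
  corrected together; flagged (constant/short) pairs are excluded from the
  family rather than absorbed into it.
* **Calibration checks** in the test-suite use 1,000-replicate null
  simulations for the ANCOVA type-I error and 1,000 mixed
  (half-real/half-null) families for BH: under a fully null family the
  expected false-discovery proportion equals the nominal level exactly, so
  only a mixed family tests *control* rather than a coin flip.

## Problem sizes used in the shipped checks

Unit tests run on toy grids ($\le 16^3$) and graphs ($\le 90$ nodes). The
end-to-end checks use the full default cohort (63 subjects, $32^3$ grid,
90 regions), 20 generator seeds per recovery claim, 10 seeds with 20 null
graphs each for small-world behaviour, and 1,000 replicates for the
calibration rates — sizes at which every claim is decided in seconds to a
few minutes on one CPU.

## Known limitations

* KDE on a 128-point grid biases the KL divergence slightly for extremely
  peaked distributions; increase `n_grid` if regions have near-degenerate
  value spreads.
* $\sigma$ from rewired nulls is unstable for very sparse graphs whose
  null clustering is near zero; such values are flagged rather than
  extrapolated.
* The voxelwise engine fits one design across voxels and does not support
  voxel-specific missingness.
* Weighted-network variants, rich-club and network-based statistics are
  out of scope.
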