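# imcn — Individual Morphological Covariance Networks from Structural MRI

`imcn` builds and analyses **single-subject morphological covariance
networks** from modulated gray-matter volume (GMV) maps, for researchers
studying structural brain organisation in case–control designs (the
motivating setting is a three-group schizophrenia study: healthy controls,
non-violent and violent patients).

Population-level structural covariance yields one network per *group*;
the individual construction yields one network per *subject*:

- **Nodes** are the 90 AAL cerebrum regions (any integer parcellation
  works; the AAL-90 name table ships with the package).
- For each region, the distribution of voxel GMV values is estimated by
  Gaussian **kernel density estimation** (Silverman bandwidth).
- Each pair of regions is connected with weight `exp(-D)`, where
  `D = KL(p‖q) + KL(q‖p)` is the **symmetrised Kullback–Leibler
  divergence** of the two regional densities on a shared grid —
  a similarity in (0, 1], equal to 1 for identical distributions.
- The 90×90 matrix is binarized over a **sparsity range**
  (0.05–0.39, step 0.02) and each binary graph is characterised with
  graph-theory measures — clustering coefficient (Cp), characteristic path
  length (Lp), global/local efficiency (Eg, Eloc), assortativity,
  modularity, nodal degree and betweenness — plus **small-world indices**
  γ, λ, σ normalised against degree-preserving rewired null networks.

Around the network core the package provides voxel-based morphometry group
statistics (voxelwise ANCOVA, Benjamini–Hochberg FDR, cluster-extent
filtering, post-hoc pooled *t*-tests), summary-statistic demographic tests,
clinical correlation analyses with FDR, a deterministic synthetic
three-group cohort generator with recorded ground truth, and a file-based
pipeline runner (`run_pipeline()`, with a thin CLI wrapper in
`inst/scripts/imcn-pipeline.R`).

## Worked example

Build one subject's network from a synthetic cohort and run the group
pipeline:

```r
library(imcn)

spec   <- cohort_spec(seed = 7)            # 22 HC / 23 NSZ / 18 VSZ
cohort <- generate_gm_cohort(spec)         # GM maps + atlas + ground truth

samples <- extract_regional_samples(cohort$maps[[1]], cohort$atlas)
sim     <- build_similarity_matrix(samples)
sim
#> <similarity_matrix> subject 'sub001', 90x90

net <- binarize_at_sparsity(sim, 0.23)
net
#> <binary_network> 90 nodes, 921 edges (sparsity 0.230)

gm <- global_metrics(net)                  # Cp 0.762, Lp 3.001, Eg 0.482
sw <- small_worldness(net, n_null = 20, seed = 1)
#> gamma = 3.14, lambda = 1.68, sigma = 1.87   (small-world organisation)
```

The 921 edges are `floor(0.23 * 90*89/2)` — the 23% strongest
similarities. σ ≈ 1.9 with γ ≫ 1 and λ ≈ 1.7 says the network clusters
far more than its degree-matched random nulls at a modest path-length
cost: small-world organisation.

Voxelwise group inference recovers the cohort's planted atrophy region:

```r
maps <- lapply(cohort$maps, smooth_gm_map, fwhm_mm = 8)
sm   <- voxelwise_anova(maps, cohort$design, covariates = c("PANSS", "duration"))
cl   <- cluster_filter(fdr_threshold(sm, 0.05), 30, statmap = sm)
cl
#> <cluster_set> 1 cluster(s)
#>   cluster_id size peak_stat peak_x_mm peak_y_mm peak_z_mm
#> 1          1  262  126.6688        38        -6        18

posthoc_cluster_tests(cluster_mean_gmv(maps, cl, 1), cohort$design)
#>   comparison  statistic        p_adj direction
#> 1  HC vs NSZ -13.431752 1.650951e-16        -1
#> 2  HC vs VSZ -18.539888 3.719317e-20        -1
#> 3 NSZ vs VSZ  -6.704215 1.641868e-07        -1
```

One cluster (262 voxels, all p's Bonferroni-corrected) survives FDR +
cluster-extent thresholding; it overlaps the planted region, and the
negative directions show the planted GMV gradient HC > NSZ > VSZ.

Summary-statistic demographic tests reproduce a printed group table from
means/SDs/sizes alone:

```r
pooled_t_from_summary(16.1, 28.88, 23, 59.89, 65.25, 18)$statistic
#> [1] 2.885
```

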