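# Synthetic three-group cohort generation with recorded ground truth:
# parcellated gray-matter images with a planted atrophy gradient, network
# cohorts with a planted topology gradient, and clinical scores coupled to
# the planted effects.

#' Default clinical coupling pattern
#'
#' Signed weights linking generated clinical scores to subject-level
#' measures: PANSS couples negatively to planted-region GMV and nodal
#' degree; MOAS couples negatively to GMV and nodal degree and positively
#' to global efficiency. The degree weight in the MOAS composite is doubled
#' because nodal degree, unlike GMV and efficiency, carries no
#' between-group gradient in the network generator; the heavier weight
#' balances the per-measure signal so every planted coupling has a pooled
#' correlation of comparable magnitude (about 0.5-0.6) over the patient
#' groups.
#'
#' @return Named list of named numeric weight vectors, one per score.
#' @export
default_coupling <- function() {
  list(PANSS = c(gmv = -1, degree = -1),
       MOAS = c(gmv = -1, degree = -2, Eg = 1))
}

#' Specification of a synthetic three-group cohort
#'
#' Defines the study conditions the generator emulates: group sizes
#' 22/23/18 (HC/NSZ/VSZ), a 90-region parcellation on a 32^3 grid with 4-mm
#' voxels, a planted gray-matter atrophy region whose mean decreases by
#' \code{atrophy_effect} per group step (HC -> NSZ -> VSZ), Watts-Strogatz
#' network topology with a group-increasing rewiring probability, and
#' clinical scores coupled to the planted effects.
#'
#' @param n_per_group Named counts for HC, NSZ, VSZ.
#' @param grid_shape Image grid in voxels.
#' @param voxel_size_mm Isotropic voxel edge length.
#' @param n_regions Number of parcellation regions.
#' @param planted_region_id Region carrying the atrophy gradient.
#' @param atrophy_effect Fractional GM reduction per group step (0.10 means
#'   NSZ -10\%, VSZ -20\% in the planted region).
#' @param gm_mean_range Range of baseline regional mean GM values.
#' @param noise_sd Voxel-level Gaussian noise SD.
#' @param subject_scale_sd SD of the per-subject global scaling factor.
#' @param ws_degree Even Watts-Strogatz lattice degree.
#' @param ws_rewire_p Named per-group rewiring probabilities.
#' @param rewire_jitter_sd Per-subject jitter SD on the rewiring probability.
#' @param clinical_rho Correlation between the clinical scores and the
#'   planted composite (the rest is noise).
#' @param coupling Clinical coupling pattern, see
#'   \code{\link{default_coupling}}.
#' @param seed Integer master seed; all randomness derives from it.
#' @return Object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = c(HC = 22, NSZ = 23, VSZ = 18),
                        grid_shape = c(32, 32, 32),
                        voxel_size_mm = 4,
                        n_regions = 90,
                        planted_region_id = 42,
                        atrophy_effect = 0.10,
                        gm_mean_range = c(0.4, 0.7),
                        noise_sd = 0.10,
                        subject_scale_sd = 0.02,
                        ws_degree = 8,
                        ws_rewire_p = c(HC = 0.05, NSZ = 0.15, VSZ = 0.30),
                        rewire_jitter_sd = 0.02,
                        clinical_rho = 0.85,
                        coupling = default_coupling(),
                        seed = 1L) {
  # accept list-valued fields (e.g. from YAML configs)
  n_per_group <- unlist(n_per_group)
  grid_shape <- unlist(grid_shape)
  ws_rewire_p <- unlist(ws_rewire_p)
  gm_mean_range <- unlist(gm_mean_range)
  stopifnot(length(n_per_group) == 3L,
            all(c("HC", "NSZ", "VSZ") %in% names(n_per_group)),
            all(n_per_group >= 2),
            length(grid_shape) == 3L,
            ws_degree %% 2 == 0, ws_degree < n_regions,
            all(c("HC", "NSZ", "VSZ") %in% names(ws_rewire_p)),
            atrophy_effect >= 0, atrophy_effect < 0.5,
            planted_region_id >= 1, planted_region_id <= n_regions)
  structure(list(n_per_group = n_per_group[c("HC", "NSZ", "VSZ")],
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_regions = n_regions,
                 planted_region_id = planted_region_id,
                 atrophy_effect = atrophy_effect,
                 gm_mean_range = gm_mean_range, noise_sd = noise_sd,
                 subject_scale_sd = subject_scale_sd,
                 ws_degree = ws_degree,
                 ws_rewire_p = ws_rewire_p[c("HC", "NSZ", "VSZ")],
                 rewire_jitter_sd = rewire_jitter_sd,
                 clinical_rho = clinical_rho, coupling = coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Subject table (ids + groups) implied by a cohort spec.
spec_subjects <- function(spec) {
  groups <- rep(c("HC", "NSZ", "VSZ"), times = spec$n_per_group)
  data.frame(subject_id = sprintf("sub%03d", seq_along(groups)),
             group = groups, stringsAsFactors = FALSE)
}

#' Generate a synthetic brain parcellation
#'
#' An ellipsoidal "brain" mask inscribed in the grid is partitioned into
#' \code{n_regions} compact regions by k-means (Voronoi-style) clustering
#' of voxel coordinates around seeded random centers. Every region has at
#' least 20 voxels; the construction is deterministic given the seed. With
#' 90 regions the packaged AAL-90 name list is attached.
#'
#' @param grid_shape Grid in voxels.
#' @param n_regions Number of regions (at most voxel count / 20).
#' @param seed Integer seed.
#' @param voxel_size_mm Isotropic voxel size for the affine.
#' @return An \code{\link{atlas_parcellation}}.
#' @export
generate_atlas <- function(grid_shape = c(32, 32, 32), n_regions = 90,
                           seed = 1L, voxel_size_mm = 4) {
  dm <- as.integer(grid_shape)
  ctr <- (dm - 1) / 2
  rad <- 0.45 * dm
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  inside <- rowSums(sweep(sweep(idx, 2, ctr), 2, rad, "/")^2) <= 1
  n_vox <- sum(inside)
  if (n_regions > n_vox / 20)
    stopf("infeasible region count: %d regions for %d mask voxels",
          n_regions, n_vox)
  coords <- idx[inside, , drop = FALSE]
  lab_in <- NULL
  for (attempt in 1:10) {
    km <- with_seed(derive_seed(seed, attempt), {
      centers <- coords[sample.int(n_vox, n_regions), , drop = FALSE]
      suppressWarnings(kmeans(coords, centers = centers, iter.max = 50L,
                              algorithm = "Lloyd"))
    })
    if (min(tabulate(km$cluster, n_regions)) >= 20L) {
      lab_in <- km$cluster
      break
    }
  }
  if (is.null(lab_in)) stopf("could not build a parcellation with all regions >= 20 voxels")
  labels <- array(0L, dm)
  labels[inside] <- as.integer(lab_in)
  regions <- if (n_regions == 90L) aal90_regions() else
    data.frame(region_id = seq_len(n_regions),
               region_name = sprintf("R%03d", seq_len(n_regions)))
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -voxel_size_mm * ctr
  atlas_parcellation(labels, regions, aff)
}

#' Generate a synthetic gray-matter image cohort
#'
#' Each subject's voxels in region r are drawn from
#' \code{Normal(mu_r * f_i * g, noise_sd^2)} truncated at 0, where
#' \code{mu_r} are baseline regional means, \code{f_i} is a per-subject
#' global scaling factor, and \code{g} implements the planted atrophy
#' gradient: 1 everywhere for HC, and \code{1 - atrophy_effect} /
#' \code{1 - 2 * atrophy_effect} in the planted region for NSZ / VSZ.
#' All parameters are recorded in the returned ground truth.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List with \code{maps} (list of \code{\link{gm_map}}),
#'   \code{design} (\code{\link{group_design}}, clinical fields NA),
#'   \code{atlas}, and \code{truth} (class \code{ground_truth}).
#' @export
generate_gm_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- generate_atlas(spec$grid_shape, spec$n_regions,
                          seed = spec$seed,
                          voxel_size_mm = spec$voxel_size_mm)
  subj <- spec_subjects(spec)
  n <- nrow(subj)
  step <- c(HC = 0, NSZ = 1, VSZ = 2)[subj$group]
  g_mult <- 1 - step * spec$atrophy_effect
  lab <- as.vector(atlas$labels)
  inside <- which(lab != 0L)
  lab_in <- lab[inside]
  region_ids <- atlas$regions$region_id
  truncated <- 0L
  maps <- vector("list", n)
  mu <- with_seed(derive_seed(spec$seed, 1e6),
                  runif(spec$n_regions, spec$gm_mean_range[1],
                        spec$gm_mean_range[2]))
  f_subj <- with_seed(derive_seed(spec$seed, 2e6),
                      rnorm(n, 1, spec$subject_scale_sd))
  true_means <- matrix(NA_real_, n, spec$n_regions,
                       dimnames = list(subj$subject_id,
                                       sprintf("region_%d", region_ids)))
  realized_planted <- numeric(n)
  for (i in seq_len(n)) {
    means_i <- mu * f_subj[i]
    means_i[spec$planted_region_id] <-
      means_i[spec$planted_region_id] * g_mult[i]
    true_means[i, ] <- means_i
    vals_in <- with_seed(derive_seed(spec$seed, i), {
      rnorm(length(lab_in), mean = means_i[lab_in], sd = spec$noise_sd)
    })
    truncated <- truncated + sum(vals_in < 0)
    vals_in[vals_in < 0] <- 0
    a <- array(0, dim(atlas$labels))
    a[inside] <- vals_in
    maps[[i]] <- gm_map(a, atlas$affine, subject_id = subj$subject_id[i])
    realized_planted[i] <-
      mean(vals_in[lab_in == spec$planted_region_id])
  }
  design <- group_design(subj$subject_id, subj$group)
  truth <- structure(list(
    spec = spec, mu = mu, subject_scale = f_subj, group_step = step,
    planted_region_id = spec$planted_region_id,
    true_regional_means = true_means,
    measures = data.frame(subject_id = subj$subject_id,
                          gmv = realized_planted,
                          stringsAsFactors = FALSE),
    n_truncated_voxels = truncated,
    seed = spec$seed), class = "ground_truth")
  if (truncated > 0)
    message(sprintf("truncated %d negative voxels to 0", truncated))
  list(maps = maps, design = design, atlas = atlas, truth = truth)
}

#' Generate a synthetic network cohort
#'
#' One Watts-Strogatz small-world graph per subject
#' (\code{n_regions} nodes, even lattice degree \code{ws_degree}), with the
#' rewiring probability set by the subject's group
#' (default 0.05 / 0.15 / 0.30 for HC / NSZ / VSZ) plus per-subject jitter.
#' Higher rewiring shortens paths, so global efficiency increases and
#' characteristic path length decreases along the group gradient.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return List with \code{networks} (list of \code{\link{binary_network}}),
#'   \code{design}, and \code{truth} (per-subject realized rewiring
#'   probabilities and measures: Eg, Lp, and planted-node degree).
#' @export
generate_network_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subj <- spec_subjects(spec)
  n <- nrow(subj)
  p_group <- spec$ws_rewire_p[subj$group]
  R <- spec$n_regions
  density <- (R * spec$ws_degree / 2) / (R * (R - 1) / 2)
  networks <- vector("list", n)
  p_real <- numeric(n)
  eg <- lp <- degp <- numeric(n)
  for (i in seq_len(n)) {
    res <- with_seed(derive_seed(spec$seed, 5e6 + i), {
      p_i <- min(0.999, max(0.001,
                            p_group[i] + rnorm(1, 0, spec$rewire_jitter_sd)))
      g <- igraph::sample_smallworld(1, R, spec$ws_degree / 2, p_i,
                                     loops = FALSE, multiple = FALSE)
      list(p = p_i,
           adj = as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0)
    })
    p_real[i] <- res$p
    net <- binary_network(res$adj, density,
                          region_ids = seq_len(R),
                          subject_id = subj$subject_id[i])
    networks[[i]] <- net
    gm <- global_metrics(net, modularity_restarts = 0L)
    eg[i] <- gm$Eg
    lp[i] <- gm$Lp
    degp[i] <- sum(net$adjacency[spec$planted_region_id, ])
  }
  design <- group_design(subj$subject_id, subj$group)
  truth <- structure(list(
    spec = spec, rewire_p = p_real,
    measures = data.frame(subject_id = subj$subject_id, Eg = eg, Lp = lp,
                          degree = degp, stringsAsFactors = FALSE),
    seed = spec$seed), class = "ground_truth")
  list(networks = networks, design = design, truth = truth)
}

# Default clinical calibration targets (group mean, SD) for the patient
# groups, mirroring the emulated study population.
clinical_targets <- function() {
  list(PANSS = list(NSZ = c(86.3, 16.49), VSZ = c(112, 7.4)),
       MOAS = list(NSZ = c(14.96, 3.99), VSZ = c(29, 3.33)),
       duration = list(NSZ = c(16.1, 28.88), VSZ = c(59.89, 65.25)))
}

#' Generate clinical scores coupled to planted effects
#'
#' PANSS and MOAS are generated for the patient groups as linear functions
#' of a signed composite of the subject's planted measures (see
#' \code{\link{default_coupling}}) plus Gaussian noise; the linear map is
#' chosen so that the expected NSZ and VSZ group means match the
#' calibration targets. Disease duration is drawn from per-group gamma
#' distributions matching the target means and SDs. HC clinical fields are
#' left missing. Signs are set so that gray-matter volume and nodal degree
#' couple negatively to PANSS and MOAS while global efficiency couples
#' positively to MOAS.
#'
#' @param design A \code{\link{group_design}}.
#' @param truth A \code{ground_truth} (or a merged measures data frame with
#'   a \code{subject_id} column) supplying the per-subject measures named
#'   in the coupling.
#' @param coupling Coupling pattern; default \code{\link{default_coupling}}.
#' @param rho Correlation of scores with the composite.
#' @param seed Integer seed.
#' @param targets Calibration targets, see source for format.
#' @return The design with \code{duration}, \code{PANSS}, \code{MOAS}
#'   filled for patients.
#' @export
generate_clinical_scores <- function(design, truth,
                                     coupling = default_coupling(),
                                     rho = 0.85, seed = 1L,
                                     targets = clinical_targets()) {
  stopifnot(inherits(design, "group_design"))
  measures <- if (inherits(truth, "ground_truth")) truth$measures else truth
  stopifnot(is.data.frame(measures), "subject_id" %in% names(measures))
  for (sc in names(coupling)) {
    need <- names(coupling[[sc]])
    miss <- setdiff(need, names(measures))
    if (length(miss))
      stopf("coupling for %s needs measure(s) %s absent from the truth",
            sc, paste(miss, collapse = ", "))
  }
  pat <- design$group != "HC"
  m <- measures[match(design$subject_id[pat], measures$subject_id), ,
                drop = FALSE]
  grp <- design$group[pat]
  out <- design
  k <- 0L
  for (sc in names(coupling)) {
    k <- k + 1L
    w <- coupling[[sc]]
    comp <- rep(0, sum(pat))
    for (nm in names(w)) {
      x <- m[[nm]]
      if (sd(x) > 0) comp <- comp + w[[nm]] * (x - mean(x)) / sd(x)
    }
    latent <- if (sd(comp) > 0) {
      z <- comp / sd(comp)
      eps <- with_seed(derive_seed(seed, 10 + k), rnorm(length(z)))
      rho * z + sqrt(1 - rho^2) * eps
    } else rep(0, sum(pat))
    tg <- targets[[sc]]
    mN <- mean(latent[grp == "NSZ"])
    mV <- mean(latent[grp == "VSZ"])
    if (sd(latent) == 0) {
      score <- rep(mean(c(tg$NSZ[1], tg$VSZ[1])), sum(pat))
    } else if (abs(mV - mN) > 0.2 * sd(latent)) {
      b <- (tg$VSZ[1] - tg$NSZ[1]) / (mV - mN)
      a <- tg$NSZ[1] - b * mN
      score <- a + b * latent
    } else {
      b <- mean(c(tg$NSZ[2], tg$VSZ[2])) / sd(latent)
      a <- mean(c(tg$NSZ[1], tg$VSZ[1])) - b * mean(latent)
      score <- a + b * latent
    }
    out[[sc]][pat] <- score
  }
  tgd <- targets$duration
  dur <- with_seed(derive_seed(seed, 99), {
    d <- numeric(sum(pat))
    for (gname in c("NSZ", "VSZ")) {
      tg <- tgd[[gname]]
      shape <- (tg[1] / tg[2])^2
      rate <- tg[1] / tg[2]^2
      d[grp == gname] <- rgamma(sum(grp == gname), shape = shape,
                                rate = rate)
    }
    d
  })
  out$duration[pat] <- dur
  out
}
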