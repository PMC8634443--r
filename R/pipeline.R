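# File-based pipeline orchestration: every stage reads and writes plain
# files (NIfTI / TSV / JSON) so that stages are independently re-runnable
# and runs are auditable via a manifest.

#' Build a pipeline run configuration
#'
#' @param outdir Output directory (created if absent).
#' @param seed Master seed for all stochastic stages.
#' @param cohort Named list of \code{\link{cohort_spec}} overrides used by
#'   the simulate stage.
#' @param smoothing_fwhm_mm Gaussian smoothing applied before voxelwise
#'   statistics.
#' @param sparsity Named list \code{min}, \code{max}, \code{step}.
#' @param kde Named list \code{n_grid}, \code{bw_adjust}.
#' @param null_model Named list \code{n_null}, \code{n_swaps_per_edge}.
#' @param stats Named list \code{fdr_q}, \code{min_cluster_size},
#'   \code{covariates}.
#' @return Object of class \code{run_config} (a named list).
#' @export
run_config <- function(outdir, seed = 1L, cohort = list(),
                       smoothing_fwhm_mm = 8,
                       sparsity = list(min = 0.05, max = 0.39, step = 0.02),
                       kde = list(n_grid = 128, bw_adjust = 1),
                       null_model = list(n_null = 100, n_swaps_per_edge = 10),
                       stats = list(fdr_q = 0.05, min_cluster_size = 30,
                                    covariates = c("PANSS", "duration"))) {
  structure(list(outdir = outdir, seed = as.integer(seed), cohort = cohort,
                 smoothing_fwhm_mm = smoothing_fwhm_mm, sparsity = sparsity,
                 kde = kde, null_model = null_model, stats = stats),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config A \code{\link{run_config}}.
#' @return (write) The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  # named vectors become named lists so YAML keeps the names
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(config)), path)
  invisible(path)
}

cfg_spec <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  do.call(cohort_spec, args)
}

pipeline_paths <- function(outdir) {
  list(maps_dir = file.path(outdir, "maps"),
       atlas = file.path(outdir, "atlas.nii.gz"),
       regions = file.path(outdir, "regions.tsv"),
       subjects = file.path(outdir, "subjects.tsv"),
       region_means = file.path(outdir, "region_means.tsv"),
       networks_dir = file.path(outdir, "networks"),
       metrics = file.path(outdir, "metrics.tsv"),
       metrics_auc = file.path(outdir, "metrics_auc.tsv"),
       stats_prefix = file.path(outdir, "vbm"),
       clusters = file.path(outdir, "clusters.tsv"),
       posthoc = file.path(outdir, "posthoc.tsv"),
       group_stats = file.path(outdir, "network_group_stats.tsv"),
       correlations = file.path(outdir, "correlations.tsv"),
       manifest = file.path(outdir, "manifest.json"))
}

require_stage_outputs <- function(paths, stage) {
  missing <- !vapply(paths, file.exists, TRUE)
  if (any(missing))
    stopf("missing outputs of upstream stage '%s': %s", stage,
          paste(unlist(paths)[missing], collapse = ", "))
}

load_cohort_maps <- function(p) {
  subj <- read_tsv(p$subjects)
  maps <- lapply(subj$subject_id, function(id)
    suppressWarnings(load_gm_map(file.path(p$maps_dir,
                                           paste0(id, ".nii.gz")),
                                 subject_id = id)))
  list(subjects = subj, maps = maps)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order:
#' \code{simulate} (synthetic cohort to disk), \code{extract} (regional
#' samples and region means), \code{network} (per-subject similarity
#' matrices and thresholded edge lists), \code{metrics} (graph measures and
#' AUC over the sparsity grid), \code{stats} (voxelwise ANCOVA + FDR +
#' cluster filtering + post-hoc tests; group tests on network metric AUCs),
#' \code{correlate} (clinical correlations). Each stage reads its inputs
#' from files written by the upstream stage and errors naming the missing
#' stage otherwise. A JSON manifest with the configuration, seeds and
#' output checksums is written at the end.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Character vector of stages, or \code{"all"}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "extract", "network", "metrics", "stats",
                  "correlate")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]
  p <- pipeline_paths(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if ("simulate" %in% stages) {
    spec <- cfg_spec(config)
    gm <- generate_gm_cohort(spec)
    netc <- generate_network_cohort(spec)
    meas <- merge(gm$truth$measures, netc$truth$measures, by = "subject_id")
    design <- generate_clinical_scores(gm$design, meas,
                                       coupling = spec$coupling,
                                       rho = spec$clinical_rho,
                                       seed = derive_seed(spec$seed, 7))
    dir.create(p$maps_dir, showWarnings = FALSE)
    for (m in gm$maps)
      write_gm_map(m, file.path(p$maps_dir, paste0(m$subject_id, ".nii.gz")))
    write_atlas(gm$atlas, p$atlas, p$regions)
    write_group_design(design, p$subjects)
    dir.create(p$networks_dir, showWarnings = FALSE)
    write_edge_list(netc$networks,
                    file.path(p$networks_dir, "simulated_networks.tsv"))
    truth_path <- file.path(config$outdir, "ground_truth.json")
    jsonlite::write_json(list(
      planted_region_id = spec$planted_region_id,
      atrophy_effect = spec$atrophy_effect,
      ws_rewire_p = as.list(spec$ws_rewire_p),
      rewire_p_realized = netc$truth$rewire_p,
      measures = meas, seed = spec$seed),
      truth_path, auto_unbox = TRUE, digits = NA)
  }

  if ("extract" %in% stages) {
    require_stage_outputs(p[c("subjects", "atlas")], "simulate")
    co <- load_cohort_maps(p)
    atlas <- load_atlas(p$atlas, p$regions)
    samples <- lapply(co$maps, extract_regional_samples, atlas = atlas)
    write_tsv(region_mean_table(samples), p$region_means)
  }

  if ("network" %in% stages) {
    require_stage_outputs(p[c("subjects", "atlas")], "simulate")
    co <- load_cohort_maps(p)
    atlas <- load_atlas(p$atlas, p$regions)
    dir.create(p$networks_dir, showWarnings = FALSE)
    for (m in co$maps) {
      s <- extract_regional_samples(m, atlas)
      sim <- build_similarity_matrix(s, n_grid = config$kde$n_grid,
                                     bw_adjust = config$kde$bw_adjust)
      write_similarity_matrix(sim,
        file.path(p$networks_dir, paste0(m$subject_id, "_similarity.tsv")),
        regions = atlas$regions)
      nets <- sparsity_series(sim, config$sparsity$min, config$sparsity$max,
                              config$sparsity$step)
      write_edge_list(nets,
        file.path(p$networks_dir, paste0(m$subject_id, "_edges.tsv")))
    }
  }

  if ("metrics" %in% stages) {
    subj <- if (file.exists(p$subjects)) read_tsv(p$subjects) else
      stopf("missing outputs of upstream stage 'simulate': %s", p$subjects)
    sim_paths <- file.path(p$networks_dir,
                           paste0(subj$subject_id, "_similarity.tsv"))
    if (!all(file.exists(sim_paths)))
      stopf("missing outputs of upstream stage 'network': %s",
            paste(sim_paths[!file.exists(sim_paths)], collapse = ", "))
    rows <- list(); aucs <- list()
    for (i in seq_along(sim_paths)) {
      tab <- read_tsv(sim_paths[i])
      S <- as.matrix(tab[, -1])
      sim <- structure(list(subject_id = subj$subject_id[i], values = unname(S),
                            region_ids = seq_len(nrow(S))),
                       class = "similarity_matrix")
      nets <- sparsity_series(sim, config$sparsity$min, config$sparsity$max,
                              config$sparsity$step)
      recs <- lapply(seq_along(nets), function(k)
        metrics_record(nets[[k]], small_world = TRUE,
                       n_null = config$null_model$n_null,
                       n_swaps_per_edge = config$null_model$n_swaps_per_edge,
                       seed = derive_seed(config$seed, i * 1000 + k)))
      for (r in recs)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = r$subject_id, sparsity = r$sparsity,
          metric = c("Cp", "Lp", "Eg", "Eloc", "assortativity",
                     "modularity", "gamma", "lambda", "sigma",
                     "mean_degree"),
          value = c(r$Cp, r$Lp, r$Eg, r$Eloc, r$assortativity,
                    r$modularity, r$gamma, r$lambda, r$sigma,
                    mean(r$nodal_degree)))
      curves <- metric_curves(recs)
      aucs[[length(aucs) + 1L]] <- data.frame(
        subject_id = subj$subject_id[i],
        metric = vapply(curves, `[[`, "", "metric"),
        auc = vapply(curves, `[[`, numeric(1), "auc"))
    }
    write_tsv(do.call(rbind, rows), p$metrics)
    write_tsv(do.call(rbind, aucs), p$metrics_auc)
  }

  if ("stats" %in% stages) {
    require_stage_outputs(p["subjects"], "simulate")
    co <- load_cohort_maps(p)
    design <- read_group_design(p$subjects)
    maps <- lapply(co$maps, smooth_gm_map, fwhm_mm = config$smoothing_fwhm_mm)
    sm <- voxelwise_anova(maps, design, covariates = config$stats$covariates)
    write_stat_map(sm, p$stats_prefix)
    surv <- fdr_threshold(sm, config$stats$fdr_q)
    cl <- cluster_filter(surv, config$stats$min_cluster_size, statmap = sm)
    write_tsv(cl$table, p$clusters)
    ph <- NULL
    if (nrow(cl$table) > 0) {
      cm <- cluster_mean_gmv(maps, cl, cl$table$cluster_id[1])
      ph <- posthoc_cluster_tests(cm, design)
      ph$df <- vapply(ph$df, function(d) d[1], numeric(1))
    }
    write_tsv(ph %||% data.frame(), p$posthoc)
    if (file.exists(p$metrics_auc)) {
      auc <- read_tsv(p$metrics_auc)
      res <- lapply(split(auc, auc$metric), function(d) {
        d <- d[match(design$subject_id, d$subject_id), ]
        a <- ancova(d$auc, design, covariates = config$stats$covariates)
        data.frame(metric = d$metric[1], F = a$statistic,
                   p = a$p_raw)
      })
      write_tsv(do.call(rbind, res), p$group_stats)
    }
  }

  if ("correlate" %in% stages) {
    require_stage_outputs(p[c("subjects", "region_means")], "extract")
    design <- read_group_design(p$subjects)
    rm_tab <- read_tsv(p$region_means)
    pat <- design$group != "HC"
    scores <- data.frame(subject_id = design$subject_id,
                         PANSS = design$PANSS, MOAS = design$MOAS)[pat, ]
    measures <- rm_tab[rm_tab$subject_id %in% design$subject_id[pat], ]
    if (file.exists(p$metrics_auc)) {
      auc <- read_tsv(p$metrics_auc)
      for (met in c("Eg", "Lp")) {
        d <- auc[auc$metric == met, c("subject_id", "auc")]
        names(d)[2] <- paste0(met, "_auc")
        measures <- merge(measures, d, by = "subject_id")
      }
    }
    write_tsv(clinical_correlations(measures, scores), p$correlations)
  }

  cfg_path <- file.path(config$outdir, "config.yaml")
  write_run_config(config, cfg_path)
  outputs <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, p$manifest)
  checks <- tools::md5sum(outputs)
  manifest <- list(package_version = as.character(packageVersion("imcn")),
                   seed = config$seed, stages = stages,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = as.list(setNames(unname(checks),
                                              basename(outputs))))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
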