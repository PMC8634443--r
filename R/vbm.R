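# Voxel-based morphometry group inference: voxelwise ANCOVA, FDR and
# cluster-extent thresholding, peak reporting, post-hoc tests.

#' Analysis mask from a cohort of gray-matter maps
#'
#' Voxels whose gray-matter value exceeds \code{threshold} in at least
#' \code{prop} of subjects.
#'
#' @param maps List of \code{\link{gm_map}} on one grid.
#' @param threshold Gray-matter value cut-off (default 0.1).
#' @param prop Minimum proportion of subjects above the cut-off (default 0.9).
#' @return 3D logical array.
#' @export
build_analysis_mask <- function(maps, threshold = 0.1, prop = 0.9) {
  stopifnot(length(maps) >= 1L)
  dm <- dim(maps[[1]]$values)
  acc <- array(0, dm)
  for (m in maps) {
    stopifnot(identical(dim(m$values), dm))
    acc <- acc + (m$values > threshold)
  }
  acc / length(maps) >= prop
}

#' Voxelwise group ANOVA/ANCOVA over gray-matter maps
#'
#' Per in-mask voxel, fits \code{intercept + covariates + group} and tests
#' the group indicators with a partial F against the covariate-only model;
#' degrees of freedom are \code{(G - 1, N - G - C)}. Covariate missingness
#' follows the policy of \code{\link{ancova}} (\code{"drop"} by default,
#' suited to clinical covariates that are undefined for controls).
#'
#' @param maps List of \code{\link{gm_map}}, one per subject, same grid and
#'   order as \code{design}.
#' @param design A \code{\link{group_design}} (>= 2 groups, >= 3 subjects).
#' @param covariates Character vector of design column names.
#' @param mask Optional 3D logical analysis mask; default
#'   \code{\link{build_analysis_mask}} of the input maps.
#' @param na_action Covariate missingness policy.
#' @return Object of class \code{stat_map}: \code{stat} and \code{p} 3D
#'   arrays (NA outside the mask), \code{df}, \code{mask}, \code{affine}.
#' @export
voxelwise_anova <- function(maps, design, covariates = character(),
                            mask = NULL, na_action = "drop") {
  stopifnot(length(maps) == nrow(design), length(maps) >= 3L,
            nlevels(design$group) >= 2L)
  dm <- dim(maps[[1]]$values)
  if (is.null(mask)) mask <- build_analysis_mask(maps)
  stopifnot(identical(dim(mask), dm))
  if (!any(mask)) stopf("empty analysis mask")
  idx <- which(mask)
  Y <- vapply(maps, function(m) m$values[idx], numeric(length(idx)))
  rc <- resolve_covariates(design, covariates, na_action)
  res <- partial_f_engine(Y, design$group, rc$covariates)
  stat <- p <- array(NA_real_, dm)
  stat[idx] <- res$F
  p[idx] <- res$p
  structure(list(stat = stat, p = p, df = res$df, mask = mask,
                 affine = maps[[1]]$affine,
                 distribution = "F"),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s(%s), %d in-mask voxels\n", x$distribution,
              paste(x$df, collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' FDR threshold a statistical map
#'
#' Benjamini-Hochberg over all in-mask p-values; returns the 3D survival
#' mask of voxels significant at level \code{q}.
#'
#' @param statmap A \code{stat_map}.
#' @param q FDR level in (0, 1).
#' @return 3D logical array.
#' @export
fdr_threshold <- function(statmap, q = 0.05) {
  stopifnot(inherits(statmap, "stat_map"), q > 0, q < 1)
  idx <- which(statmap$mask)
  if (!length(idx)) stopf("empty mask")
  surv <- fdr_bh(statmap$p[idx], q)$reject
  out <- array(FALSE, dim(statmap$mask))
  out[idx[surv]] <- TRUE
  out
}

# Neighbour offsets for 6/18/26-connectivity (half set: lexicographically
# positive), used to enumerate undirected voxel adjacencies once.
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(off)) == 1,
                 "18" = rowSums(off^2) <= 2,
                 "26" = rep(TRUE, nrow(off)),
                 stopf("connectivity must be 6, 18 or 26"))
  off <- off[keep, , drop = FALSE]
  # half set: first nonzero component positive
  first_nonzero <- apply(off, 1, function(o) o[which(o != 0)[1]])
  off[first_nonzero > 0, , drop = FALSE]
}

#' Connected-component cluster filtering
#'
#' Labels connected components of a binary 3D map (18-connectivity by
#' default, the common SPM convention) and keeps components whose size is
#' strictly greater than \code{min_size}. When a \code{stat_map} is given,
#' each cluster is annotated with its peak statistic and the peak voxel's
#' world coordinate in mm.
#'
#' @param binary_map 3D logical array.
#' @param min_size Minimum size; clusters must exceed it strictly
#'   (\code{min_size = 30} keeps clusters of >= 31 voxels).
#' @param statmap Optional \code{stat_map} for peak annotation.
#' @param connectivity 6, 18 or 26.
#' @param affine Optional 4x4 affine for peak mm coordinates (taken from
#'   \code{statmap} when present).
#' @return Object of class \code{cluster_set}: \code{table} (data frame
#'   with \code{cluster_id}, \code{size}, peak columns) and \code{voxels}
#'   (list of linear voxel indices per cluster, disjoint).
#' @export
cluster_filter <- function(binary_map, min_size, statmap = NULL,
                           connectivity = 18, affine = NULL) {
  stopifnot(min_size >= 1)
  dm <- dim(binary_map)
  idx <- which(binary_map)
  if (is.null(affine) && !is.null(statmap)) affine <- statmap$affine
  empty <- structure(list(table = data.frame(
    cluster_id = integer(), size = integer(), peak_stat = numeric(),
    peak_x_mm = numeric(), peak_y_mm = numeric(), peak_z_mm = numeric()),
    voxels = list(), dim = dm), class = "cluster_set")
  if (!length(idx)) return(empty)
  node <- array(0L, dm)
  node[idx] <- seq_along(idx)
  coords <- which(binary_map, arr.ind = TRUE)
  offs <- connectivity_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
          nb[, 2] >= 1 & nb[, 2] <= dm[2] &
          nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    to <- node[nb[ok, , drop = FALSE]]
    from <- seq_along(idx)[ok]
    hit <- to > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(from[hit], to[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  keep <- which(sizes > min_size)
  if (!length(keep)) return(empty)
  # order clusters by decreasing size for stable ids
  keep <- keep[order(-sizes[keep])]
  vox <- lapply(keep, function(k) sort(idx[memb == k]))
  tab <- data.frame(cluster_id = seq_along(keep),
                    size = sizes[keep],
                    peak_stat = NA_real_, peak_x_mm = NA_real_,
                    peak_y_mm = NA_real_, peak_z_mm = NA_real_)
  if (!is.null(statmap)) {
    for (c_i in seq_along(vox)) {
      v <- vox[[c_i]]
      stats_v <- statmap$stat[v]
      pk <- v[which.max(stats_v)]
      tab$peak_stat[c_i] <- max(stats_v)
      ar <- arrayInd(pk, dm) - 1L
      mm <- (affine %||% diag(4)) %*% c(ar, 1)
      tab$peak_x_mm[c_i] <- mm[1]
      tab$peak_y_mm[c_i] <- mm[2]
      tab$peak_z_mm[c_i] <- mm[3]
    }
  }
  structure(list(table = tab, voxels = vox, dim = dm), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Per-subject mean gray-matter value within a cluster
#'
#' @param maps List of \code{\link{gm_map}}.
#' @param clusters A \code{\link{cluster_filter}} result.
#' @param cluster_id Which cluster.
#' @return Numeric vector, one mean per subject.
#' @export
cluster_mean_gmv <- function(maps, clusters, cluster_id = 1L) {
  stopifnot(inherits(clusters, "cluster_set"),
            cluster_id %in% clusters$table$cluster_id)
  v <- clusters$voxels[[which(clusters$table$cluster_id == cluster_id)]]
  vapply(maps, function(m) mean(m$values[v]), numeric(1))
}

#' Post-hoc group tests on cluster mean GMV
#'
#' Pairwise pooled-variance two-sample t-tests on the per-subject cluster
#' means, Bonferroni-corrected over the group pairs (no covariates, as is
#' conventional for post-hoc tests on extracted cluster means).
#'
#' @param cluster_means Numeric per-subject mean GMV in one cluster.
#' @param design A \code{\link{group_design}}.
#' @return Data frame of pairwise results (see
#'   \code{\link{posthoc_bonferroni}}).
#' @export
posthoc_cluster_tests <- function(cluster_means, design) {
  posthoc_bonferroni(cluster_means, design, var_equal = TRUE)
}

#' Write a stat map's components as NIfTI files
#'
#' @param statmap A \code{stat_map}.
#' @param prefix Output path prefix; writes \code{<prefix>_stat.nii.gz},
#'   \code{<prefix>_p.nii.gz} and \code{<prefix>_mask.nii.gz}.
#' @return Character vector of the written paths, invisibly.
#' @export
write_stat_map <- function(statmap, prefix) {
  paths <- paste0(prefix, c("_stat.nii.gz", "_p.nii.gz", "_mask.nii.gz"))
  arrs <- list(statmap$stat, statmap$p, statmap$mask * 1)
  for (i in 1:3) {
    a <- arrs[[i]]
    a[is.na(a)] <- 0
    img <- RNifti::asNifti(a, datatype = "double")
    img <- set_affine(img, statmap$affine)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}
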