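# Individual morphological covariance network construction: per-region KDE,
# symmetrised Kullback-Leibler similarity, sparsity-thresholded binarization.

#' Gaussian kernel density estimate on a uniform grid
#'
#' Bandwidth defaults to Silverman's rule of thumb. The estimated density is
#' floored at \code{floor_eps} and renormalised to integrate to 1
#' (trapezoidal rule), which keeps the subsequent Kullback-Leibler
#' divergence finite on any shared grid.
#'
#' @param samples Numeric vector of values (at least two distinct, unless
#'   \code{jitter = TRUE}).
#' @param n_grid Number of evaluation points (>= 32).
#' @param bandwidth Optional fixed bandwidth; overrides the rule.
#' @param bw_adjust Scalar multiplier on the rule-of-thumb bandwidth.
#' @param from,to Grid limits; default \code{range(samples)} padded by 3
#'   bandwidths.
#' @param floor_eps Density floor applied before renormalisation.
#' @param jitter If \code{TRUE}, degenerate all-identical samples are spread
#'   deterministically over a 1e-6-wide interval instead of raising an error.
#' @return Object of class \code{density_estimate}: list with \code{grid},
#'   \code{density}, \code{bandwidth}.
#' @export
estimate_density <- function(samples, n_grid = 128L, bandwidth = NULL,
                             bw_adjust = 1, from = NULL, to = NULL,
                             floor_eps = 1e-10, jitter = FALSE) {
  stopifnot(is.numeric(samples), length(samples) >= 2L)
  if (n_grid < 32L) stopf("n_grid must be >= 32")
  if (!all(is.finite(samples))) stopf("samples contain non-finite values")
  if (length(unique(samples)) < 2L) {
    if (!jitter)
      stopf(paste("all sample values identical; kernel bandwidth is",
                  "degenerate (set jitter = TRUE to spread them over a",
                  "1e-6 interval)"))
    samples <- samples +
      seq(-0.5, 0.5, length.out = length(samples)) * 1e-6
  }
  bw <- bandwidth %||% (bw.nrd0(samples) * bw_adjust)
  if (!is.finite(bw) || bw <= 0) stopf("degenerate bandwidth %g", bw)
  if (is.null(from)) from <- min(samples) - 3 * bw
  if (is.null(to)) to <- max(samples) + 3 * bw
  d <- density(samples, bw = bw, from = from, to = to, n = n_grid)
  y <- pmax(d$y, floor_eps)
  y <- y / trapz(d$x, y)
  structure(list(grid = d$x, density = y, bandwidth = bw),
            class = "density_estimate")
}

#' Symmetrised Kullback-Leibler divergence between two density estimates
#'
#' \code{KL(p||q) + KL(q||p)} by discrete summation over the shared grid
#' (density values times grid spacing). Non-negative up to numerical slack.
#'
#' @param p,q \code{density_estimate} objects on an identical grid.
#' @return Non-negative scalar divergence.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "density_estimate"), inherits(q, "density_estimate"))
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-12 * max(1, max(abs(p$grid))))
    stopf("density estimates are not on an identical grid")
  if (!all(is.finite(p$density)) || !all(is.finite(q$density)))
    stopf("non-finite density values")
  dx <- p$grid[2] - p$grid[1]
  lr <- log(p$density / q$density)
  sum(p$density * lr) * dx - sum(q$density * lr) * dx
}

#' Kullback-Leibler similarity
#'
#' Maps the symmetrised divergence \code{D} to \code{exp(-D)} in (0, 1]:
#' identical distributions give exactly 1, and similarity decays as the two
#' distributions are pulled apart. This is the edge weight of the
#' individual morphological covariance network.
#'
#' @inheritParams kl_divergence
#' @return Similarity in (0, 1].
#' @export
kl_similarity <- function(p, q) exp(-kl_divergence(p, q))

#' Build a subject's morphological covariance similarity matrix
#'
#' For every pair of regions, both regions' gray-matter value distributions
#' are re-estimated on one shared evaluation grid spanning the pooled sample
#' range padded by 3 bandwidths (the wider of the two rule-of-thumb
#' bandwidths), and the pair's edge weight is \code{exp(-D)} with \code{D}
#' the symmetrised Kullback-Leibler divergence. The construction is fully
#' deterministic given the samples and settings.
#'
#' @param samples A \code{regional_samples} object.
#' @param n_grid Evaluation grid size per pair.
#' @param bw_adjust Multiplier on each region's Silverman bandwidth.
#' @param pad_bandwidths Grid padding, in units of the pair's bandwidth.
#' @param floor_eps Density floor (see \code{\link{estimate_density}}).
#' @param jitter Passed to \code{\link{estimate_density}} for degenerate
#'   regions.
#' @return Object of class \code{similarity_matrix}: list with
#'   \code{subject_id}, \code{values} (RxR symmetric, unit diagonal) and
#'   \code{region_ids}.
#' @export
build_similarity_matrix <- function(samples, n_grid = 128L, bw_adjust = 1,
                                    pad_bandwidths = 3, floor_eps = 1e-10,
                                    jitter = FALSE) {
  stopifnot(inherits(samples, "regional_samples"))
  ids <- samples$region_ids
  R <- length(ids)
  xs <- samples$samples
  bws <- numeric(R)
  for (r in seq_len(R)) {
    x <- xs[[r]]
    if (length(unique(x)) < 2L && !jitter)
      stopf("region %s has all-identical values; enable jitter", ids[r])
    if (length(unique(x)) < 2L)
      x <- x + seq(-0.5, 0.5, length.out = length(x)) * 1e-6
    xs[[r]] <- x
    bws[r] <- bw.nrd0(x) * bw_adjust
    if (!is.finite(bws[r]) || bws[r] <= 0)
      stopf("degenerate bandwidth for region %s", ids[r])
  }
  rngs <- vapply(xs, range, numeric(2))
  S <- matrix(1, R, R)
  for (i in seq_len(R - 1L)) {
    for (j in (i + 1L):R) {
      b <- max(bws[i], bws[j]) * pad_bandwidths
      from <- min(rngs[1, i], rngs[1, j]) - b
      to <- max(rngs[2, i], rngs[2, j]) + b
      di <- estimate_density(xs[[i]], n_grid = n_grid, bandwidth = bws[i],
                             from = from, to = to, floor_eps = floor_eps)
      dj <- estimate_density(xs[[j]], n_grid = n_grid, bandwidth = bws[j],
                             from = from, to = to, floor_eps = floor_eps)
      S[i, j] <- S[j, i] <- kl_similarity(di, dj)
    }
  }
  structure(list(subject_id = samples$subject_id, values = S,
                 region_ids = ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> subject '%s', %dx%d\n", x$subject_id,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a binary network object
#'
#' @param adjacency Symmetric logical matrix with zero diagonal.
#' @param sparsity Proportion of possible edges retained.
#' @param region_ids Node identifiers.
#' @param subject_id Subject identifier.
#' @return Object of class \code{binary_network}.
#' @export
binary_network <- function(adjacency, sparsity, region_ids = NULL,
                           subject_id = NULL) {
  adjacency <- adjacency != 0
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!isTRUE(all(adjacency == t(adjacency))))
    stopf("adjacency must be symmetric")
  if (any(diag(adjacency))) stopf("self-loops are not allowed")
  structure(list(adjacency = adjacency, sparsity = sparsity,
                 region_ids = region_ids %||% seq_len(nrow(adjacency)),
                 subject_id = subject_id),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$sparsity))
  invisible(x)
}

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Keeps the \code{K = floor(sparsity * R(R-1)/2)} strongest off-diagonal
#' similarities as edges. Ties are broken deterministically by ascending
#' (row, column) lexicographic order.
#'
#' @param matrix A \code{similarity_matrix}.
#' @param sparsity Proportion of possible edges to keep, in (0, 1).
#' @return A \code{\link{binary_network}}.
#' @export
binarize_at_sparsity <- function(matrix, sparsity) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  if (!(sparsity > 0 && sparsity < 1))
    stopf("sparsity must be in (0, 1), got %g", sparsity)
  S <- matrix$values
  R <- nrow(S)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  w <- S[ut]
  K <- floor(sparsity * R * (R - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(K)]
  adj <- matrix(FALSE, R, R)
  adj[ut[keep, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  binary_network(adj, sparsity, matrix$region_ids, matrix$subject_id)
}

#' Binarize over a sparsity series
#'
#' The conventional analysis range is 0.05 to 0.39 in steps of 0.02
#' (18 levels).
#'
#' @param matrix A \code{similarity_matrix}.
#' @param s_min,s_max,s_step Arithmetic sparsity grid.
#' @return List of \code{\link{binary_network}} objects, one per level.
#' @export
sparsity_series <- function(matrix, s_min = 0.05, s_max = 0.39,
                            s_step = 0.02) {
  stopifnot(s_min > 0, s_max < 1, s_min <= s_max, s_step > 0)
  grid <- seq(s_min, s_max + s_step * 1e-9, by = s_step)
  if (!length(grid)) stopf("empty sparsity grid")
  lapply(grid, function(s) binarize_at_sparsity(matrix, s))
}

#' Write a similarity matrix as TSV
#'
#' 90x90 (or RxR) numeric table with region names as header row and first
#' column.
#'
#' @param matrix A \code{similarity_matrix}.
#' @param path Output TSV path.
#' @param regions Optional region table supplying names; ids used otherwise.
#' @return The path, invisibly.
#' @export
write_similarity_matrix <- function(matrix, path, regions = NULL) {
  nm <- if (!is.null(regions))
    regions$region_name[match(matrix$region_ids, regions$region_id)]
  else as.character(matrix$region_ids)
  df <- as.data.frame(matrix$values)
  names(df) <- nm
  df <- cbind(region = nm, df)
  write_tsv(df, path)
}

#' Write a binary network series as an edge-list TSV
#'
#' Long format: one row per (sparsity, edge), columns \code{sparsity},
#' \code{region_i}, \code{region_j}.
#'
#' @param networks List of \code{\link{binary_network}} objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(networks, path) {
  rows <- lapply(networks, function(net) {
    e <- which(upper.tri(net$adjacency) & net$adjacency, arr.ind = TRUE)
    if (!nrow(e)) return(NULL)
    data.frame(sparsity = net$sparsity,
               region_i = net$region_ids[e[, 1]],
               region_j = net$region_ids[e[, 2]])
  })
  write_tsv(do.call(rbind, rows), path)
}
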