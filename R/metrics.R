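# Graph-theory characterisation of binary networks: nodal and global
# measures, degree-preserving null models, small-world normalisation, and
# area-under-curve summaries over a sparsity series.

as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree and betweenness
#'
#' Betweenness follows the Brandes accumulation and is reported as raw
#' unordered-pair counts; the normalised variant divides by
#' \code{(R-1)(R-2)/2}.
#'
#' @param net A \code{\link{binary_network}}.
#' @param normalized If \code{TRUE}, betweenness is divided by the number of
#'   node pairs excluding the node itself.
#' @return List with numeric vectors \code{degree} and \code{betweenness}.
#' @export
nodal_metrics <- function(net, normalized = FALSE) {
  g <- as_igraph(net)
  deg <- as.numeric(rowSums(net$adjacency))
  btw <- as.numeric(igraph::betweenness(g, directed = FALSE))
  R <- nrow(net$adjacency)
  if (normalized && R > 2) btw <- btw / ((R - 1) * (R - 2) / 2)
  list(degree = deg, betweenness = btw)
}

# Best modularity over a deterministic greedy pass plus seeded
# multilevel-refinement restarts.
best_modularity <- function(g, restarts = 10L, base_seed = 20210101L) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  q <- igraph::modularity(igraph::cluster_fast_greedy(g))
  for (r in seq_len(restarts)) {
    qr <- with_seed(derive_seed(base_seed, r),
                    igraph::modularity(igraph::cluster_louvain(g)))
    if (qr > q) q <- qr
  }
  q
}

#' Global graph-theory measures
#'
#' \itemize{
#'   \item \code{Cp}: mean triangle-based local clustering; nodes with
#'     degree < 2 contribute 0.
#'   \item \code{Lp}: characteristic path length, averaged over connected
#'     ordered pairs only; the number of disconnected pairs is returned.
#'   \item \code{Eg}: global efficiency, mean of 1/d over all ordered pairs
#'     with 1/Inf = 0.
#'   \item \code{Eloc}: mean over nodes of the global efficiency of the
#'     node's neighbourhood subgraph.
#'   \item \code{assortativity}: Pearson correlation of degrees over edge
#'     endpoints.
#'   \item \code{modularity}: best partition quality found by greedy
#'     agglomeration plus seeded refinement restarts.
#' }
#' An edgeless graph yields \code{Cp = Eg = Eloc = 0} and \code{Lp = NA}
#' (flagged missing).
#'
#' @param net A \code{\link{binary_network}}.
#' @param modularity_restarts Number of seeded refinement restarts.
#' @return List with \code{Cp}, \code{Lp}, \code{Eg}, \code{Eloc},
#'   \code{assortativity}, \code{modularity}, \code{n_disconnected_pairs}.
#' @export
global_metrics <- function(net, modularity_restarts = 10L) {
  g <- as_igraph(net)
  R <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    return(list(Cp = 0, Lp = NA_real_, Eg = 0, Eloc = 0,
                assortativity = NA_real_, modularity = NA_real_,
                n_disconnected_pairs = R * (R - 1)))
  }
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  Cp <- mean(cc)
  d <- igraph::distances(g)
  du <- d[upper.tri(d)]
  finite <- is.finite(du)
  Lp <- if (any(finite)) mean(du[finite]) else NA_real_
  Eg <- mean(ifelse(finite, 1 / du, 0))
  Eloc <- mean(igraph::local_efficiency(g))
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  Q <- best_modularity(g, restarts = modularity_restarts)
  list(Cp = Cp, Lp = Lp, Eg = Eg, Eloc = Eloc,
       assortativity = assort, modularity = Q,
       n_disconnected_pairs = 2L * sum(!finite))
}

#' Degree-preserving randomisation (double edge swap)
#'
#' Maslov-Sneppen rewiring: repeated double-edge swaps that preserve every
#' node's degree while destroying higher-order structure; no self-loops or
#' multi-edges are created. Deterministic given \code{seed}.
#'
#' @param net A \code{\link{binary_network}} with at least 2 edges.
#' @param n_swaps_per_edge Attempted swaps per edge.
#' @param seed Integer seed.
#' @return A rewired \code{\link{binary_network}}.
#' @export
rewire_preserving_degree <- function(net, n_swaps_per_edge = 10L, seed = 1L) {
  g <- as_igraph(net)
  m <- igraph::ecount(g)
  if (m < 2) {
    warnf("graph has %d edge(s); no legal swap exists, returned unchanged", m)
    return(net)
  }
  gr <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps_per_edge * m)))
  adj <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE)) != 0
  binary_network(adj, net$sparsity, net$region_ids, net$subject_id)
}

#' Small-world normalisation against rewired null models
#'
#' \code{gamma = Cp / mean(Cp_null)}, \code{lambda = Lp / mean(Lp_null)} and
#' \code{sigma = gamma / lambda}, with null statistics averaged over
#' \code{n_null} degree-preserving rewired graphs. A small-world network
#' shows \code{gamma >> 1}, \code{lambda ~ 1} and \code{sigma > 1}.
#'
#' @param net A \code{\link{binary_network}} connected enough for \code{Lp}.
#' @param n_null Number of null graphs.
#' @param n_swaps_per_edge Swap attempts per edge for each null.
#' @param seed Integer seed; null i uses a seed derived from \code{seed + i}.
#' @return List with \code{gamma}, \code{lambda}, \code{sigma}.
#' @export
small_worldness <- function(net, n_null = 100L, n_swaps_per_edge = 10L,
                            seed = 1L) {
  gm <- global_metrics(net, modularity_restarts = 0L)
  if (!is.finite(gm$Lp)) stopf("Lp undefined for this graph")
  null_cp <- null_lp <- numeric(n_null)
  for (i in seq_len(n_null)) {
    nn <- rewire_preserving_degree(net, n_swaps_per_edge,
                                   seed = derive_seed(seed, i))
    nm <- global_metrics(nn, modularity_restarts = 0L)
    null_cp[i] <- nm$Cp
    null_lp[i] <- nm$Lp
  }
  mcp <- mean(null_cp)
  mlp <- mean(null_lp, na.rm = TRUE)
  if (!is.finite(mcp) || mcp == 0)
    return(list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_))
  gamma <- gm$Cp / mcp
  lambda <- gm$Lp / mlp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All measures for one network at one sparsity
#'
#' Convenience wrapper bundling \code{\link{global_metrics}},
#' \code{\link{nodal_metrics}} and (optionally)
#' \code{\link{small_worldness}} into one record.
#'
#' @param net A \code{\link{binary_network}}.
#' @param small_world Compute small-world normalisation?
#' @param n_null,n_swaps_per_edge,seed Null-model settings.
#' @return Object of class \code{graph_metrics_record}.
#' @export
metrics_record <- function(net, small_world = FALSE, n_null = 100L,
                           n_swaps_per_edge = 10L, seed = 1L) {
  gm <- global_metrics(net)
  nm <- nodal_metrics(net)
  sw <- if (small_world) small_worldness(net, n_null, n_swaps_per_edge, seed)
        else list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  structure(c(list(subject_id = net$subject_id, sparsity = net$sparsity),
              gm, list(nodal_degree = nm$degree,
                       nodal_betweenness = nm$betweenness),
              sw),
            class = "graph_metrics_record")
}

#' Metric curves and area under the curve over a sparsity series
#'
#' @param records List of \code{graph_metrics_record} sharing one sparsity
#'   grid (ascending).
#' @param metrics Character vector of global metric names to summarise.
#' @return List of \code{metric_curve} objects: \code{metric},
#'   \code{sparsity}, \code{values}, \code{auc} (trapezoidal).
#' @export
metric_curves <- function(records,
                          metrics = c("Cp", "Lp", "Eg", "Eloc",
                                      "assortativity", "modularity")) {
  stopifnot(length(records) >= 1L)
  grid <- vapply(records, `[[`, numeric(1), "sparsity")
  if (is.unsorted(grid, strictly = TRUE))
    stopf("records must be ordered by strictly increasing sparsity")
  lapply(metrics, function(m) {
    vals <- vapply(records, function(r) as.numeric(r[[m]]), numeric(1))
    structure(list(metric = m, sparsity = grid, values = vals,
                   auc = trapz(grid, vals)),
              class = "metric_curve")
  })
}
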