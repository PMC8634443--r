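# Shared fixtures and independent brute-force oracles.

# Small gm_map with known values.
toy_map <- function(values, voxel_mm = 2, subject_id = "toy") {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  gm_map(values, aff, subject_id = subject_id)
}

# Two-region toy atlas on a given grid: labels 1 and 2 at fixed voxels.
toy_atlas <- function(dm = c(4, 4, 4), voxel_mm = 2) {
  lab <- array(0L, dm)
  lab[1:5] <- 1L            # 5 voxels, flattened indices 1..5
  lab[10:16] <- 2L          # 7 voxels
  atlas_parcellation(lab, data.frame(region_id = 1:2,
                                     region_name = c("A", "B")),
                     diag(c(rep(voxel_mm, 3), 1)))
}

# Random Erdos-Renyi binary network.
random_net <- function(n, p, seed) {
  adj <- with_test_seed(seed, {
    m <- matrix(runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    m | t(m)
  })
  binary_network(adj, sum(adj) / (n * (n - 1)))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Floyd-Warshall all-pairs shortest paths (dense, independent of igraph).
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Brute-force betweenness: enumerate every shortest path between every
# pair by depth-first search on the shortest-path structure and accumulate
# fractional pair counts on interior nodes.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  btw <- numeric(n)
  enum_paths <- function(cur, target) {
    if (cur == target) return(list(target))
    nbrs <- which(adj[cur, ] & d[cur, target] == d[, target] + 1)
    out <- list()
    for (nb in nbrs)
      for (pth in enum_paths(nb, target))
        out[[length(out) + 1L]] <- c(cur, pth)
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- enum_paths(s, t)
    np <- length(paths)
    for (pth in paths) {
      interior <- setdiff(pth, c(s, t))
      btw[interior] <- btw[interior] + 1 / np
    }
  }
  btw
}

# Brute-force global measures from the distance matrix.
brute_global <- function(adj) {
  d <- fw_distances(adj)
  du <- d[upper.tri(d)]
  fin <- is.finite(du)
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (i in 1:n) {
    nb <- which(adj[i, ])
    k <- length(nb)
    cc[i] <- if (k < 2) 0 else
      sum(adj[nb, nb]) / (k * (k - 1))
  }
  list(Lp = if (any(fin)) mean(du[fin]) else NA_real_,
       Eg = mean(ifelse(fin, 1 / du, 0)),
       Cp = mean(cc), degree = deg)
}

# Build a binary_network from an explicit edge list (1-based node pairs).
net_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  for (e in edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  binary_network(adj, sum(adj) / (n * (n - 1)))
}

# A stat_map with prescribed in-mask p-values (for FDR tests).
toy_stat_map <- function(p_values, dm = c(length(p_values), 1, 1)) {
  mask <- array(FALSE, dm)
  mask[seq_along(p_values)] <- TRUE
  p <- array(NA_real_, dm)
  p[seq_along(p_values)] <- p_values
  structure(list(stat = array(NA_real_, dm), p = p, df = c(2, 10),
                 mask = mask, affine = diag(4), distribution = "F"),
            class = "stat_map")
}

# Watts-Strogatz network helper.
ws_net <- function(n, k, p, seed) {
  adj <- with_test_seed(seed, {
    g <- igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE,
                                   multiple = FALSE)
    as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  })
  binary_network(adj, sum(adj) / (n * (n - 1)))
}

# imcn internal not exported; mirror here for helpers.
with_seed <- function(seed, code) with_test_seed(seed, code)

# trapezoidal integral (mirrors the package-internal helper)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
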