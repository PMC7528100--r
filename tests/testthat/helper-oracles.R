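# Independent brute-force oracles, all computed directly from a binary
# symmetric adjacency matrix without igraph, used to cross-check the
# package's metric implementations.

o_density <- function(a) {
  n <- nrow(a)
  sum(a) / (n * (n - 1))
}

# Mean local clustering: realised triangles among each node's neighbours
# over the maximum possible; degree < 2 contributes 0.
o_clustering <- function(a) {
  n <- nrow(a)
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / choose(k, 2)
  }, numeric(1))
  mean(loc)
}

# All-pairs BFS, mean over unordered pairs.
o_pathlength <- function(a) {
  n <- nrow(a)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] == 1))))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    total <- total + sum(dist)
  }
  total / (n * (n - 1))
}

# Coefficient of variation of degrees, population standard deviation.
o_heterogeneity <- function(a) {
  deg <- rowSums(a)
  m <- mean(deg)
  sqrt(mean((deg - m)^2)) / m
}

# Newman degree assortativity: Pearson correlation of end-point degrees
# over the directed edge list (each edge in both orientations).
o_assortativity <- function(a) {
  deg <- rowSums(a)
  idx <- which(a == 1, arr.ind = TRUE)   # both orientations
  x <- deg[idx[, 1]]
  y <- deg[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Parse the connected-graph atlas fixture into adjacency matrices.
load_graph_atlas <- function() {
  path <- system.file("extdata", "connected_graphs_n2_7.txt",
                      package = "skullnet")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    n <- as.integer(parts[1])
    a <- matrix(0L, n, n)
    for (e in parts[-1]) {
      i <- as.integer(substr(e, 1, 1)) + 1L
      j <- as.integer(substr(e, 2, 2)) + 1L
      a[i, j] <- a[j, i] <- 1L
    }
    a
  })
}

# Classical one-way pseudo-F on Euclidean coordinates via per-group
# centroids (trace of sums-of-squares matrices) — the independent route
# to the same statistic as the distance-matrix formula.
o_trace_F <- function(x, labels) {
  f <- factor(labels)
  n <- nrow(x)
  a <- nlevels(f)
  grand <- colMeans(x)
  sst <- sum(sweep(x, 2, grand)^2)
  ssw <- 0
  for (lev in levels(f)) {
    xi <- x[f == lev, , drop = FALSE]
    ssw <- ssw + sum(sweep(xi, 2, colMeans(xi))^2)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Edge-list helpers for small named graphs.
path_edges <- function(names) cbind(names[-length(names)], names[-1])
star_edges <- function(hub, leaves) cbind(hub, leaves)
cycle_edges <- function(names) rbind(path_edges(names),
                                     c(names[length(names)], names[1]))
complete_edges <- function(names) t(combn(names, 2))

# Adjacency matrix of a skull_network, for feeding the oracles.
net_adj <- function(net) adjacency_matrix(net)

# Random connected skull network for property tests: spanning tree plus
# extra random edges.
random_connected_net <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  names <- sprintf("v%02d", seq_len(n))
  edges <- cbind(names[vapply(2:n, function(i) sample.int(i - 1, 1), 1L)],
                 names[2:n])
  all_pairs <- t(combn(names, 2))
  pick <- all_pairs[sample.int(nrow(all_pairs), min(extra, nrow(all_pairs))), ,
                    drop = FALSE]
  skull_network(rbind(edges, pick), specimen_id = sprintf("rand%d", seed))
}
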