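# Independent brute-force oracles and tree generators for the metric tests.
# Everything here avoids the package's own algorithms: trees come from Prüfer
# sequences, paths from breadth-first search over an edge list.

# decode a Prüfer sequence (values in 1..n, length n-2) into a tree edge list
prufer_to_edges <- function(pr) {
  n <- length(pr) + 2L
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 1L
  for (k in seq_along(pr)) {
    leaf <- which(degree == 1L)[1]
    edges[ptr, ] <- sort(c(leaf, pr[k]))
    ptr <- ptr + 1L
    degree[leaf] <- 0L
    degree[pr[k]] <- degree[pr[k]] - 1L
  }
  last <- which(degree == 1L)
  edges[ptr, ] <- sort(last)
  edges
}

random_tree_edges <- function(n) {
  if (n == 2L) return(matrix(c(1L, 2L), 1L))
  prufer_to_edges(sample.int(n, n - 2L, replace = TRUE))
}

# wrap a plain edge list as the package's spanning_tree container
as_spanning_tree <- function(edges, n) {
  structure(list(n_nodes = as.integer(n),
                 edges = cbind(i = as.integer(pmin(edges[, 1], edges[, 2])),
                               j = as.integer(pmax(edges[, 1], edges[, 2]))),
                 pli = rep(1, nrow(edges)),
                 labels = as.character(seq_len(n))),
            class = "spanning_tree")
}

# unique path between two nodes of a tree, by BFS over the adjacency list
bfs_path <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  prev <- rep(NA_integer_, n)
  prev[from] <- from
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (u in adj[[v]]) if (is.na(prev[u])) {
      prev[u] <- v
      queue <- c(queue, u)
    }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# brute-force nodal betweenness: count paths strictly containing each node
bf_betweenness <- function(edges, n, normalized = TRUE) {
  counts <- numeric(n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      p <- bfs_path(edges, n, a, b)
      interior <- p[-c(1, length(p))]
      counts[interior] <- counts[interior] + 1
    }
  }
  if (normalized && n > 2) counts <- counts / ((n - 1) * (n - 2) / 2)
  counts
}

bf_degree <- function(edges, n) tabulate(c(edges[, 1], edges[, 2]), n)

# small synthetic fixture cohort shared by pipeline tests: planted beta-band
# hub effect, 10 regions, enough recording for 4 epochs of 8 s
fixture_config <- function(n_perm = 200, n_iter_robustness = 0, out_dir = NULL) {
  pipeline_config(
    simulation = list(n_regions = 10, n_group_a = 3, n_group_b = 3,
                      recording_duration_s = 36),
    n_epochs = 4,
    n_perm = n_perm,
    n_iter_robustness = n_iter_robustness,
    n_epochs_robustness = 3,
    seeds = list(simulation = 401L, epochs = 402L, permutation = 403L,
                 robustness = 404L),
    out_dir = out_dir)
}

# metric table with a single synthetic test column, for permutation checks
one_metric_table <- function(values, groups) {
  structure(data.frame(subject_id = sprintf("S%03d", seq_along(values)),
                       group = groups, band = "beta", metric = "degree",
                       node = "R001", value = values,
                       stringsAsFactors = FALSE),
            class = c("metric_table", "data.frame"))
}
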