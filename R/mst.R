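#' Minimum spanning tree of a PLI adjacency matrix
#'
#' Edge weights are defined as 1/PLI so that Kruskal's algorithm — which ranks
#' links in ascending weight and adds them one at a time, discarding any link
#' that would close a loop — retains the strongest synchronizations. The
#' result is a loop-less connected graph with N nodes and N - 1 links.
#' Zero-PLI pairs (infinite weight) are treated as absent edges; if they
#' disconnect the graph an error names the components. Ties in weight are
#' broken deterministically by the lexicographic (i, j) edge index.
#'
#' @param adj symmetric non-negative PLI matrix (zero diagonal)
#' @return object of class `spanning_tree`: list with `n_nodes`, `edges`
#'   (m x 2 integer matrix, i < j), `pli` (edge PLI values), `labels`
#' @export
mst_from_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    abort_invalid("adj must be a square matrix")
  n <- nrow(adj)
  if (n < 2L) abort_invalid("need at least 2 nodes")
  if (any(adj < 0, na.rm = TRUE)) abort_invalid("PLI weights must be >= 0")
  ut <- which(upper.tri(adj))
  pli <- adj[ut]
  keep <- which(pli > 0)
  ei <- ((ut - 1L) %% n + 1L)[keep]
  ej <- ((ut - 1L) %/% n + 1L)[keep]
  pli <- pli[keep]
  ord <- order(1 / pli, ei, ej)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  sel <- integer(n - 1L)
  m <- 0L
  for (k in ord) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) {
      parent[ra] <- rb
      m <- m + 1L
      sel[m] <- k
      if (m == n - 1L) break
    }
  }
  if (m < n - 1L) {
    comp <- vapply(seq_len(n), find, integer(1))
    labs <- colnames(adj)
    if (is.null(labs)) labs <- as.character(seq_len(n))
    reps <- vapply(split(labs, comp), `[`, character(1), 1L)
    plimst_stop(sprintf(
      "zero-PLI links disconnect the graph: %d components (containing %s)",
      length(unique(comp)), paste(reps, collapse = ", ")),
      "plimst_disconnected_graph")
  }
  sel <- sel[seq_len(m)]
  structure(list(
    n_nodes = n,
    edges = cbind(i = ei[sel], j = ej[sel]),
    pli = pli[sel],
    labels = if (is.null(colnames(adj))) default_region_labels(n) else colnames(adj),
    band = attr(adj, "band"),
    epoch_index = attr(adj, "epoch_index")),
    class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree> %d nodes, %d edges, total 1/PLI weight %.3f\n",
              x$n_nodes, nrow(x$edges), sum(1 / x$pli)))
  invisible(x)
}

#' Total MST weight (sum of 1/PLI over tree edges)
#'
#' @param tree a `spanning_tree`
#' @return scalar total weight
#' @export
tree_total_weight <- function(tree) sum(1 / tree$pli)

validate_tree <- function(tree) {
  if (!inherits(tree, "spanning_tree")) abort_invalid("not a spanning_tree")
  if (nrow(tree$edges) != tree$n_nodes - 1L)
    abort_invalid("tree must have exactly N - 1 edges")
  invisible(tree)
}
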