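#' Node degree of a spanning tree
#'
#' The number of links incident on each node.
#'
#' @param tree a `spanning_tree`
#' @return named integer vector of length N; sums to 2(N - 1)
#' @export
node_degree <- function(tree) {
  validate_tree(tree)
  d <- tabulate(c(tree$edges[, 1], tree$edges[, 2]), nbins = tree$n_nodes)
  stats::setNames(as.integer(d), tree$labels)
}

#' Betweenness centrality of every node of a tree
#'
#' In a tree the path between any two nodes is unique, so the betweenness of
#' node v is the number of node pairs whose path passes strictly through v,
#' normalized by (N-1)(N-2)/2 to lie in \[0, 1\]. Computed from subtree sizes
#' in one depth-first pass. Leaves score 0.
#'
#' @param tree a `spanning_tree`
#' @param normalized divide by (N-1)(N-2)/2 (default TRUE)
#' @return named numeric vector of length N
#' @export
betweenness_tree <- function(tree, normalized = TRUE) {
  validate_tree(tree)
  n <- tree$n_nodes
  adj <- vector("list", n)
  for (k in seq_len(nrow(tree$edges))) {
    a <- tree$edges[k, 1]; b <- tree$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # iterative DFS from node 1: visitation order + parent pointers
  parent <- integer(n)
  order_v <- integer(n)
  visited <- logical(n)
  stack <- 1L; visited[1L] <- TRUE; ptr <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ptr <- ptr + 1L
    order_v[ptr] <- v
    for (u in adj[[v]]) if (!visited[u]) {
      visited[u] <- TRUE
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  if (ptr < n) abort_invalid("tree is not connected")
  sub <- rep(1L, n)
  for (k in n:2) {
    v <- order_v[k]
    sub[parent[v]] <- sub[parent[v]] + sub[v]
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    parts <- sub[setdiff(adj[[v]], parent[v])]
    if (v != 1L) parts <- c(parts, n - 1L - sum(parts))
    bc[v] <- ((n - 1)^2 - sum(parts^2)) / 2
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, tree$labels)
}

#' Leaf fraction of a tree
#'
#' Fraction of nodes with degree 1. Higher values indicate a more star-like
#' (integrated) topology, lower values a more line-like one.
#'
#' @param tree a `spanning_tree`
#' @return scalar in (0, 1)
#' @export
leaf_fraction <- function(tree) {
  mean(node_degree(tree) == 1L)
}

#' Degree divergence (kappa) of a tree
#'
#' Ratio of the second to the first moment of the degree distribution,
#' kappa = <k^2>/<k>; a measure of the broadness of the degree distribution.
#'
#' @param tree a `spanning_tree`
#' @return scalar >= 1
#' @export
degree_divergence <- function(tree) {
  k <- node_degree(tree)
  mean(k^2) / mean(k)
}

#' Tree hierarchy
#'
#' Balances network integration (many leaves) against hub overload (large
#' maximum betweenness): `Th = L / (2 * M * BC_max)` with L the leaf count,
#' M = N - 1 the link count and BC_max the maximum normalized betweenness
#' (`formula = "reference"`, the conventional MST form, default). The literal
#' reading "number of leaves over the maximum betweenness centrality"
#' (`formula = "literal"`, `L / BC_max`) differs only by the positive constant
#' 2M at fixed N, so group inference is unaffected by the choice.
#'
#' @param tree a `spanning_tree` with at least 3 nodes
#' @param formula `"reference"` (default) or `"literal"`
#' @return scalar; in (0, 1) for the reference form
#' @export
tree_hierarchy <- function(tree, formula = c("reference", "literal")) {
  validate_tree(tree)
  formula <- match.arg(formula)
  if (tree$n_nodes < 3L)
    plimst_stop("tree hierarchy undefined for N < 3", "plimst_undefined_metric")
  L <- sum(node_degree(tree) == 1L)
  bc_max <- max(betweenness_tree(tree))
  if (formula == "reference") L / (2 * (tree$n_nodes - 1L) * bc_max)
  else L / bc_max
}

#' All nodal and global MST metrics at once
#'
#' @param tree a `spanning_tree`
#' @param th_formula passed to [tree_hierarchy()]
#' @return list with `degree`, `bc` (nodal vectors) and `leaf_fraction`,
#'   `degree_divergence`, `tree_hierarchy` (global scalars)
#' @export
tree_metrics <- function(tree, th_formula = "reference") {
  deg <- node_degree(tree)
  bc <- betweenness_tree(tree)
  L <- sum(deg == 1L)
  list(degree = deg,
       bc = bc,
       leaf_fraction = L / tree$n_nodes,
       degree_divergence = mean(deg^2) / mean(deg),
       tree_hierarchy = {
         bcm <- max(bc)
         if (th_formula == "reference") L / (2 * (tree$n_nodes - 1L) * bcm)
         else L / bcm
       })
}
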