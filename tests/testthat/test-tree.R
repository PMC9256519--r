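random_pli_matrix <- function(n, lo = 0.01) {
  a <- matrix(runif(n * n, lo, 1), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

test_that("Kruskal on 1/PLI keeps the strongest links", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.9
  a[2, 3] <- a[3, 2] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.1
  tr <- mst_from_adjacency(a)
  expect_identical(unname(tr$edges), matrix(c(1L, 2L, 2L, 3L), 2, byrow = TRUE))

  set.seed(10)
  big <- random_pli_matrix(90)
  expect_identical(nrow(mst_from_adjacency(big)$edges), 89L)
})

test_that("equal-weight ties resolve deterministically", {
  ones <- matrix(1, 6, 6); diag(ones) <- 0
  t1 <- mst_from_adjacency(ones)
  t2 <- mst_from_adjacency(ones)
  expect_identical(t1$edges, t2$edges)
  expect_identical(nrow(t1$edges), 5L)
  # lexicographic tie-break: node 1 connects to everyone
  expect_true(all(t1$edges[, 1] == 1L))
})

test_that("MST total weight matches an independent routine", {
  set.seed(11)
  for (k in 1:50) {
    n <- sample(4:60, 1)
    a <- random_pli_matrix(n)
    tr <- mst_from_adjacency(a)
    g <- igraph::graph_from_adjacency_matrix(1 / a, mode = "upper",
                                             weighted = TRUE, diag = FALSE)
    ref <- igraph::mst(g, weights = igraph::E(g)$weight)
    expect_equal(tree_total_weight(tr), sum(igraph::E(ref)$weight))
  }
})

test_that("zero-PLI disconnection is reported with components", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.5
  a[3, 4] <- a[4, 3] <- 0.5
  colnames(a) <- rownames(a) <- c("n1", "n2", "n3", "n4")
  expect_error(mst_from_adjacency(a), "components",
               class = "plimst_disconnected_graph")
})

test_that("degree, leaves and divergence match hand arithmetic", {
  star5 <- as_spanning_tree(cbind(1, 2:5), 5)
  path4 <- as_spanning_tree(cbind(1:3, 2:4), 4)
  expect_identical(unname(node_degree(star5)), c(4L, 1L, 1L, 1L, 1L))
  expect_identical(unname(node_degree(path4)), c(1L, 2L, 2L, 1L))
  expect_equal(leaf_fraction(star5), 4 / 5)
  expect_equal(leaf_fraction(path4), 2 / 4)
  star4 <- as_spanning_tree(cbind(1, 2:4), 4)
  expect_equal(degree_divergence(star4), 2)        # (9+1+1+1)/4 over 1.5
  expect_equal(degree_divergence(path4), 5 / 3)    # 2.5 / 1.5
})

test_that("betweenness of canonical trees is exact", {
  path3 <- as_spanning_tree(cbind(1:2, 2:3), 3)
  expect_equal(unname(betweenness_tree(path3)), c(0, 1, 0))
  star5 <- as_spanning_tree(cbind(1, 2:5), 5)
  expect_equal(unname(betweenness_tree(star5)), c(1, 0, 0, 0, 0))
  path5 <- as_spanning_tree(cbind(1:4, 2:5), 5)
  expect_equal(unname(betweenness_tree(path5))[3], 2 / 3)
})

test_that("tree hierarchy matches both formula variants", {
  star5 <- as_spanning_tree(cbind(1, 2:5), 5)
  path5 <- as_spanning_tree(cbind(1:4, 2:5), 5)
  expect_equal(tree_hierarchy(star5), 0.5)            # 4 / (2*4*1)
  expect_equal(tree_hierarchy(path5), 3 / 8)          # 2 / (2*4*(2/3))
  expect_equal(tree_hierarchy(star5, "literal"), 4)   # L / BC_max
  # invariance under node relabelling
  set.seed(12)
  e <- random_tree_edges(9)
  perm <- sample(9)
  e2 <- cbind(perm[e[, 1]], perm[e[, 2]])
  expect_equal(tree_hierarchy(as_spanning_tree(e, 9)),
               tree_hierarchy(as_spanning_tree(e2, 9)))
  two <- as_spanning_tree(matrix(c(1, 2), 1), 2)
  expect_error(tree_hierarchy(two), class = "plimst_undefined_metric")
})

test_that("metrics agree with brute-force enumeration on random trees", {
  set.seed(13)
  for (k in 1:60) {
    n <- sample(3:15, 1)
    e <- random_tree_edges(n)
    tr <- as_spanning_tree(e, n)
    expect_identical(unname(node_degree(tr)), bf_degree(e, n))
    expect_equal(unname(betweenness_tree(tr)), bf_betweenness(e, n))
    expect_equal(leaf_fraction(tr), mean(bf_degree(e, n) == 1L))
    k2 <- bf_degree(e, n)
    expect_equal(degree_divergence(tr), mean(k2^2) / mean(k2))
  }
})

test_that("every MST satisfies the tree invariants", {
  set.seed(14)
  for (k in 1:40) {
    n <- sample(5:90, 1)
    tr <- mst_from_adjacency(random_pli_matrix(n))
    deg <- node_degree(tr)
    expect_identical(sum(deg), 2L * (n - 1L))
    expect_identical(nrow(tr$edges), n - 1L)
    # connectivity: betweenness_tree traverses and errors if disconnected
    expect_silent(betweenness_tree(tr))
    L <- sum(deg == 1L)
    expect_gte(L, 2L)
    expect_lte(L, n - 1L)
  }
})
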