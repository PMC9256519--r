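toy_epoch_metrics <- function(n_subj = 4, n_node = 3, n_ep = 5, n_band = 2,
                              seed = 1) {
  set.seed(seed)
  dn <- list(sprintf("S%02d", 1:n_subj), sprintf("R%03d", 1:n_node), NULL,
             c("alpha", "beta")[1:n_band])
  gl <- list(dn[[1]], c("leaf_fraction", "degree_divergence", "tree_hierarchy"),
             NULL, dn[[4]])
  epoch_metrics(
    degree = array(rnorm(n_subj * n_node * n_ep * n_band), c(n_subj, n_node, n_ep, n_band), dn),
    bc = array(rnorm(n_subj * n_node * n_ep * n_band), c(n_subj, n_node, n_ep, n_band), dn),
    global = array(rnorm(n_subj * 3 * n_ep * n_band), c(n_subj, 3, n_ep, n_band), gl),
    groups = rep(c("A", "B"), length.out = n_subj))
}

test_that("epoch averaging is the per-subject arithmetic mean", {
  em <- toy_epoch_metrics()
  tab <- average_over_epochs(em)
  # independent oracle: straight apply() mean over the epoch dimension
  ref <- apply(em$degree, c(1, 2, 4), mean)
  row <- tab[tab$metric == "degree" & tab$subject_id == "S02" &
               tab$node == "R003" & tab$band == "beta", ]
  expect_equal(row$value, ref["S02", "R003", "beta"])
  expect_identical(nrow(tab), 4L * (2L * 3L + 3L) * 2L)

  # single-epoch subset is the identity
  tab1 <- average_over_epochs(em, epochs = 3L)
  row1 <- tab1[tab1$metric == "bc" & tab1$subject_id == "S01" &
                 tab1$node == "R001" & tab1$band == "alpha", ]
  expect_equal(row1$value, em$bc["S01", "R001", 3, "alpha"])

  # {1, 3} -> 2
  em$degree["S01", "R001", , "alpha"] <- c(1, 3, 0, 0, 0)
  t13 <- average_over_epochs(em, epochs = 1:2)
  expect_equal(t13$value[t13$metric == "degree" & t13$subject_id == "S01" &
                           t13$node == "R001" & t13$band == "alpha"], 2)

  expect_error(average_over_epochs(em, epochs = list(1:2, 1:2, 1:3, 1:2)),
               class = "plimst_invalid_argument")
})

test_that("permutation p-values behave at the analytic extremes", {
  # identical constant groups: observed diff 0, every permutation ties, p = 1
  tab <- one_metric_table(rep(5, 12), rep(c("A", "B"), 6))
  res <- permutation_test(tab, n_perm = 500, seed = 1, return_null = TRUE)
  expect_equal(res$observed_diff, 0)
  expect_equal(res$p_raw, 1)
  expect_identical(nrow(attr(res, "null_diffs")), 500L)

  # N(0,1) vs N(10,1) at 26 vs 29: overwhelming difference
  set.seed(2)
  vals <- c(rnorm(26), rnorm(29, 10))
  tab2 <- one_metric_table(vals, rep(c("A", "B"), c(26, 29)))
  res2 <- permutation_test(tab2, n_perm = 10000, seed = 3)
  expect_lte(res2$p_raw, 0.001)
  expect_gt(abs(res2$observed_diff), 9)

  # determinism
  expect_identical(permutation_test(tab2, 200, seed = 7)$p_raw,
                   permutation_test(tab2, 200, seed = 7)$p_raw)
  expect_error(permutation_test(one_metric_table(1:3, rep("A", 3))),
               class = "plimst_invalid_argument")
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration (3 vs 3)", {
  set.seed(4)
  vals <- rnorm(6) + c(1, 1, 1, 0, 0, 0)
  groups <- rep(c("A", "B"), each = 3)
  tab <- one_metric_table(vals, groups)
  res <- permutation_test(tab, n_perm = 10000, seed = 5)
  # exact p over all choose(6,3) = 20 label assignments
  obs <- mean(vals[1:3]) - mean(vals[4:6])
  combs <- utils::combn(6, 3)
  nulls <- apply(combs, 2, function(a) mean(vals[a]) - mean(vals[-a]))
  p_exact <- mean(abs(nulls) >= abs(obs))
  expect_lt(abs(res$p_raw - p_exact), 0.05)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(fdr_correct(0.03)$p_adjusted, 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  allone <- fdr_correct(rep(1, 6))
  expect_true(all(allone$p_adjusted == 1))
  expect_false(any(allone$rejected))
  expect_identical(fdr_correct(numeric(0))$p_adjusted, numeric(0))
  expect_error(fdr_correct(c(0.5, 0)), class = "plimst_invalid_argument")

  # independent step-up implementation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(6)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_correct(p)$p_adjusted, bh_oracle(p))
  }
})

test_that("FDR families partition the tests as configured", {
  em <- toy_epoch_metrics(n_subj = 8)
  res <- permutation_test(average_over_epochs(em), n_perm = 100, seed = 1)
  per_band <- adjust_fdr(res, fdr_family = "per_band")
  expect_false(any(is.na(per_band$p_fdr)))
  # within one (metric, band) family the BH adjustment is reproducible
  sel <- per_band$metric == "degree" & per_band$band == "alpha"
  expect_equal(per_band$p_fdr[sel], fdr_correct(per_band$p_raw[sel])$p_adjusted)
  # each global metric is one family across bands
  sel_g <- per_band$metric == "tree_hierarchy"
  expect_equal(per_band$p_fdr[sel_g],
               fdr_correct(per_band$p_raw[sel_g])$p_adjusted)
  pooled <- adjust_fdr(res, fdr_family = "all_bands_pooled")
  sel_p <- pooled$metric == "bc"
  expect_equal(pooled$p_fdr[sel_p], fdr_correct(pooled$p_raw[sel_p])$p_adjusted)
})

test_that("epoch resampling with the full subset reproduces the primary analysis", {
  em <- toy_epoch_metrics(n_subj = 6, n_ep = 4)
  primary <- permutation_test(average_over_epochs(em), n_perm = 300, seed = 9)
  rb <- robustness_resample(em, n_iter = 1, n_epochs = 4, seed = 1,
                            n_perm = 300, perm_seed = 9)
  expect_equal(rb$p_table$p_raw, primary$p_raw)
  expect_equal(rb$p_table$observed_diff, primary$observed_diff)

  rb1 <- robustness_resample(em, n_iter = 3, n_epochs = 2, seed = 5,
                             n_perm = 100)
  rb2 <- robustness_resample(em, n_iter = 3, n_epochs = 2, seed = 5,
                             n_perm = 100)
  expect_identical(rb1$p_table, rb2$p_table)
  expect_error(robustness_resample(em, n_iter = 1, n_epochs = 10),
               class = "plimst_invalid_argument")
  expect_identical(nrow(rb1$summary), (2L * 3L + 3L) * 2L)
  expect_true(all(rb1$summary$frac_significant >= 0 &
                    rb1$summary$frac_significant <= 1))
})
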