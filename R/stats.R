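#' Per-epoch MST metrics for a cohort
#'
#' Container produced by [compute_epoch_metrics()]: nodal metrics are
#' `[subject x node x epoch x band]` arrays, global metrics
#' `[subject x metric x epoch x band]`. Metrics are computed per epoch and
#' only averaged across epochs afterwards (per subject), so epoch-resampling
#' procedures can re-average without recomputing connectivity.
#'
#' @param degree,bc nodal arrays `[subject, node, epoch, band]`
#' @param global array `[subject, metric, epoch, band]` with metrics
#'   leaf_fraction, degree_divergence, tree_hierarchy
#' @param groups factor of group labels, one per subject
#' @return list of class `epoch_metrics`
#' @export
epoch_metrics <- function(degree, bc, global, groups) {
  stopifnot(length(dim(degree)) == 4, length(dim(bc)) == 4,
            length(dim(global)) == 4)
  structure(list(degree = degree, bc = bc, global = global,
                 groups = factor(groups)),
            class = "epoch_metrics")
}

#' Average per-epoch metrics to subject level
#'
#' Arithmetic mean across epochs for each subject separately (optionally over
#' an epoch subset), yielding the metric table that is the unit of statistical
#' inference.
#'
#' @param em an [epoch_metrics()] object
#' @param epochs `NULL` for all epochs, an index vector applied to every
#'   subject, or a list of per-subject index vectors (all of equal length:
#'   the cross-subject equalization contract)
#' @return data.frame of class `metric_table`: columns `subject_id`, `group`,
#'   `band`, `metric`, `node` (`NA` for global metrics), `value`
#' @export
average_over_epochs <- function(em, epochs = NULL) {
  stopifnot(inherits(em, "epoch_metrics"))
  dn <- dimnames(em$degree)
  n_subj <- dim(em$degree)[1]
  n_ep <- dim(em$degree)[3]
  if (is.null(epochs)) epochs <- replicate(n_subj, seq_len(n_ep), simplify = FALSE)
  if (!is.list(epochs)) epochs <- replicate(n_subj, epochs, simplify = FALSE)
  if (length(epochs) != n_subj)
    abort_invalid("epoch subsets must be given for every subject")
  if (length(unique(lengths(epochs))) != 1L)
    abort_invalid("unequal epoch counts across subjects violate the equalization contract")

  avg4 <- function(a) {
    # mean over epochs (dim 3) with per-subject subsets
    out <- array(0, dim = dim(a)[c(1, 2, 4)], dimnames = dimnames(a)[c(1, 2, 4)])
    for (s in seq_len(dim(a)[1]))
      out[s, , ] <- apply(a[s, , epochs[[s]], , drop = FALSE], c(2, 4), mean)
    out
  }
  deg <- avg4(em$degree); bc <- avg4(em$bc); glob <- avg4(em$global)

  tidy <- function(a, metric_from_dim2) {
    d <- dim(a)
    data.frame(
      subject_id = rep(dimnames(a)[[1]], times = d[2] * d[3]),
      band = rep(dimnames(a)[[3]], each = d[1] * d[2]),
      node = if (metric_from_dim2) NA_character_
             else rep(rep(dimnames(a)[[2]], each = d[1]), times = d[3]),
      metric = if (metric_from_dim2)
                 rep(rep(dimnames(a)[[2]], each = d[1]), times = d[3])
               else NA_character_,
      value = as.vector(a),
      stringsAsFactors = FALSE)
  }
  td <- tidy(deg, FALSE); td$metric <- "degree"
  tb <- tidy(bc, FALSE); tb$metric <- "bc"
  tg <- tidy(glob, TRUE)
  out <- rbind(td, tb, tg)
  out$group <- as.character(em$groups)[match(out$subject_id, dimnames(em$degree)[[1]])]
  out <- out[, c("subject_id", "group", "band", "metric", "node", "value")]
  class(out) <- c("metric_table", "data.frame")
  out
}

# reshape a metric_table into subjects x tests matrix + test metadata
metric_table_matrix <- function(table) {
  id <- paste(table$band, table$metric, ifelse(is.na(table$node), "", table$node),
              sep = "|")
  tests <- unique(id)
  subjects <- unique(table$subject_id)
  X <- matrix(NA_real_, length(subjects), length(tests),
              dimnames = list(subjects, tests))
  X[cbind(match(table$subject_id, subjects), match(id, tests))] <- table$value
  if (anyNA(X)) abort_invalid("metric table has missing subject/test cells")
  g <- table$group[match(subjects, table$subject_id)]
  meta <- table[match(tests, id), c("band", "metric", "node")]
  rownames(meta) <- NULL
  list(X = X, groups = g, meta = meta)
}

#' Two-group permutation test on a metric table
#'
#' The test statistic is the difference of group means (group A minus group
#' B, A being the first factor level). Subject labels are permuted `n_perm`
#' times preserving the group sizes; the two-sided p-value uses the +1
#' finite-sample correction, p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1),
#' so p is never exactly 0.
#'
#' @param table a `metric_table` from [average_over_epochs()]
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @param return_null keep the null distributions as an attribute
#' @return data.frame of class `perm_result`: columns `band`, `metric`,
#'   `node`, `observed_diff`, `p_raw`; attributes `n_perm`, `seed`, and
#'   optionally `null_diffs` (n_perm x tests matrix)
#' @export
permutation_test <- function(table, n_perm = 10000, seed = 1L,
                             return_null = FALSE) {
  m <- metric_table_matrix(table)
  g <- factor(m$groups)
  if (nlevels(g) != 2L) abort_invalid("exactly two groups are required")
  n_a <- sum(g == levels(g)[1]); n_b <- sum(g == levels(g)[2])
  if (n_a == 0L || n_b == 0L) abort_invalid("both groups must be non-empty")
  n <- n_a + n_b
  contrast <- ifelse(g == levels(g)[1], 1 / n_a, -1 / n_b)
  obs <- as.vector(contrast %*% m$X)

  set.seed(seed)
  W <- matrix(0, n_perm, n)
  for (k in seq_len(n_perm)) W[k, ] <- contrast[sample.int(n)]
  null <- W %*% m$X
  # a relative tolerance counts float-level ties (e.g. constant data) as ties
  eps <- 1e-10 * apply(abs(m$X), 2, max)
  exceed <- colSums(abs(null) >= matrix(abs(obs) - eps, n_perm, ncol(null),
                                        byrow = TRUE))
  res <- cbind(m$meta,
               data.frame(observed_diff = obs,
                          p_raw = (1 + exceed) / (n_perm + 1)))
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "groups") <- levels(g)
  if (return_null) attr(res, "null_diffs") <- null
  class(res) <- c("perm_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with a rejection mask at level `q`.
#'
#' @param p_values numeric vector of raw p-values in (0, 1]
#' @param q FDR level (default 0.05)
#' @return list with `p_adjusted` and logical `rejected`
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  if (any(p_values <= 0 | p_values > 1))
    abort_invalid("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Apply FDR correction to a permutation-result table by family
#'
#' Nodal metrics (degree, bc) are adjusted within each (metric, band) family
#' across nodes; each global metric is adjusted across the bands
#' (`fdr_family = "per_band"`, default). With `"all_bands_pooled"` each nodal
#' metric is adjusted across all bands and nodes jointly, and the global
#' metrics are pooled likewise.
#'
#' @param res a `perm_result` data.frame
#' @param q FDR level (default 0.05)
#' @param fdr_family `"per_band"` or `"all_bands_pooled"`
#' @return `res` with columns `p_fdr` and `significant` added
#' @export
adjust_fdr <- function(res, q = 0.05,
                       fdr_family = c("per_band", "all_bands_pooled")) {
  fdr_family <- match.arg(fdr_family)
  nodal <- !is.na(res$node)
  fam <- if (fdr_family == "per_band")
    ifelse(nodal, paste(res$metric, res$band), res$metric)
  else
    ifelse(nodal, res$metric, "global")
  res$p_fdr <- NA_real_
  res$significant <- NA
  for (f in unique(fam)) {
    sel <- fam == f
    fc <- fdr_correct(res$p_raw[sel], q)
    res$p_fdr[sel] <- fc$p_adjusted
    res$significant[sel] <- fc$rejected
  }
  attr(res, "q") <- q
  attr(res, "fdr_family") <- fdr_family
  res
}

#' Epoch-resampling robustness of the group comparison
#'
#' Repeats the whole subject-averaging + permutation-test + FDR procedure
#' `n_iter` times, each time drawing a fresh random subset of `n_epochs`
#' epochs per subject, to check that the significant set is stable against
#' the epoch selection.
#'
#' @param em an [epoch_metrics()] object holding all available epochs
#' @param n_iter iterations (default 100)
#' @param n_epochs epochs drawn per subject per iteration (default 24)
#' @param seed seed for the epoch draws
#' @param n_perm permutations per test (default 10000)
#' @param perm_seed seed for the permutation test (held fixed across
#'   iterations so only the epoch choice varies; defaults to `seed`)
#' @param q,fdr_family passed to [adjust_fdr()]
#' @return list with `p_table` (long data.frame: iteration, band, metric,
#'   node, observed_diff, p_raw, p_fdr, significant) and `summary` (per test:
#'   fraction of iterations significant, median p_raw and p_fdr)
#' @export
robustness_resample <- function(em, n_iter = 100, n_epochs = 24, seed = 1L,
                                n_perm = 10000, perm_seed = seed, q = 0.05,
                                fdr_family = "per_band") {
  stopifnot(inherits(em, "epoch_metrics"))
  n_subj <- dim(em$degree)[1]
  n_avail <- dim(em$degree)[3]
  if (n_epochs > n_avail)
    abort_invalid(sprintf(
      "requested %d epochs but only %d are available per subject",
      n_epochs, n_avail))
  iter_seeds <- derive_seeds(seed, n_iter)
  out <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(iter_seeds[it])
    subsets <- replicate(n_subj, sort(sample.int(n_avail, n_epochs)),
                         simplify = FALSE)
    tab <- average_over_epochs(em, subsets)
    res <- adjust_fdr(permutation_test(tab, n_perm, perm_seed), q, fdr_family)
    res$iteration <- it
    out[[it]] <- as.data.frame(res)
  }
  p_table <- do.call(rbind, out)
  key <- paste(p_table$band, p_table$metric, p_table$node)
  summary <- do.call(rbind, lapply(split(p_table, key), function(d) {
    data.frame(band = d$band[1], metric = d$metric[1], node = d$node[1],
               frac_significant = mean(d$significant),
               median_p_raw = median(d$p_raw),
               median_p_fdr = median(d$p_fdr))
  }))
  rownames(summary) <- NULL
  list(p_table = p_table, summary = summary)
}
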