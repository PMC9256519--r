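#' Pipeline configuration
#'
#' Single object describing an end-to-end run: either a manifest of existing
#' source time series or a synthetic-cohort specification, plus all analysis
#' parameters and seeds. Round-trips through YAML unchanged.
#'
#' @param manifest path to a cohort manifest CSV, or `NULL` to simulate
#' @param simulation list of arguments for the synthetic cohort (see
#'   [default_network_pair()] and [cohort_spec()]): `n_regions`, `n_group_a`,
#'   `n_group_b`, `recording_duration_s`, `hub`, `n_extra`, `effect_strength`,
#'   `effect_lag`, `effect_band`, `network_seed`
#' @param bands band definition table (default [canonical_bands()])
#' @param epoch_length_s epoch length in seconds (default 8)
#' @param n_epochs epochs per subject (`"min"` or a count; default 24)
#' @param filter_order Butterworth design order (default 4)
#' @param target_fs analysis sampling rate in Hz (default 512)
#' @param n_perm permutations (default 10000)
#' @param n_iter_robustness epoch-resampling iterations (default 100; 0 skips)
#' @param n_epochs_robustness epochs drawn per robustness iteration
#'   (default 24)
#' @param q FDR level (default 0.05)
#' @param th_formula tree-hierarchy variant, `"reference"` or `"literal"`
#' @param fdr_family `"per_band"` or `"all_bands_pooled"`
#' @param seeds named list: `simulation`, `epochs`, `permutation`, `robustness`
#' @param out_dir output directory, or `NULL` to skip writing
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(manifest = NULL,
                            simulation = list(),
                            bands = canonical_bands(),
                            epoch_length_s = 8,
                            n_epochs = 24,
                            filter_order = 4,
                            target_fs = 512,
                            n_perm = 10000,
                            n_iter_robustness = 100,
                            n_epochs_robustness = 24,
                            q = 0.05,
                            th_formula = "reference",
                            fdr_family = "per_band",
                            seeds = list(simulation = 1L, epochs = 2L,
                                         permutation = 3L, robustness = 4L),
                            out_dir = NULL) {
  sim_defaults <- list(n_regions = 90, n_group_a = 26, n_group_b = 29,
                       recording_duration_s = 240, hub = NULL, n_extra = 3,
                       effect_strength = 0.8, effect_lag = pi / 4,
                       effect_band = "beta", network_seed = 20220507L)
  merged <- sim_defaults # modifyList would drop NULL-valued entries (hub)
  for (nm in names(simulation)) merged[nm] <- list(simulation[[nm]])
  simulation <- merged
  cfg <- list(manifest = manifest, simulation = simulation, bands = bands,
              epoch_length_s = epoch_length_s, n_epochs = n_epochs,
              filter_order = filter_order, target_fs = target_fs,
              n_perm = n_perm, n_iter_robustness = n_iter_robustness,
              n_epochs_robustness = n_epochs_robustness, q = q,
              th_formula = th_formula, fdr_family = fdr_family,
              seeds = seeds, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bands)) raw$bands <- as.data.frame(raw$bands)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$bands <- as.list(x$bands)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' Write a cohort to disk (per-subject TSV matrices + manifest CSV)
#'
#' @param cohort a `cohort_dataset` from [simulate_cohort()]
#' @param dir output directory
#' @return path of the manifest CSV
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- file.path(dir, paste0(man$subject_id, ".tsv"))
  for (k in seq_along(cohort$subjects)) {
    utils::write.table(cohort$subjects[[k]]$data, man$path[k], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(man[, c("subject_id", "group", "path", "fs")], mpath,
            row.names = FALSE)
  mpath
}

#' Load a cohort from a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `path`, `fs`.
#' Every referenced file must be a readable delimited-text matrix with a
#' consistent region count; non-finite data or mismatched region counts are
#' rejected with the subject named.
#'
#' @param manifest path to the manifest CSV
#' @param region_labels optional labels (defaults by region count)
#' @return list of [source_ts()]
#' @export
load_cohort <- function(manifest, region_labels = NULL) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "path", "fs")
  if (!all(req %in% names(man)))
    abort_invalid("manifest needs columns subject_id, group, path, fs")
  if (nrow(man) == 0L) abort_invalid("empty cohort: manifest has no rows")
  subjects <- vector("list", nrow(man))
  names(subjects) <- man$subject_id
  n_regions <- NULL
  for (k in seq_len(nrow(man))) {
    p <- man$path[k]
    if (!file.exists(p)) {
      # allow paths relative to the manifest location
      p2 <- file.path(dirname(manifest), basename(p))
      if (!file.exists(p2))
        abort_invalid(sprintf("subject %s: file not found: %s",
                              man$subject_id[k], man$path[k]))
      p <- p2
    }
    x <- as.matrix(read.table(p, sep = "\t"))
    dimnames(x) <- NULL
    if (is.null(n_regions)) n_regions <- nrow(x)
    if (nrow(x) != n_regions)
      abort_invalid(sprintf(
        "subject %s: region count %d differs from the cohort's %d",
        man$subject_id[k], nrow(x), n_regions))
    labs <- if (is.null(region_labels)) default_region_labels(nrow(x))
            else region_labels
    subjects[[k]] <- source_ts(x, man$fs[k], labs, man$subject_id[k],
                               man$group[k])
  }
  subjects
}

#' Per-epoch MST metrics for a whole cohort
#'
#' For every subject and band: zero-phase band-pass, Hilbert phase, slicing
#' into the pre-selected epochs, PLI adjacency per epoch, minimum spanning
#' tree, and nodal/global tree metrics.
#'
#' @param subjects list of [source_ts()] (all at the same fs and region count)
#' @param epoch_sel per-subject epoch index list from [select_epochs()]
#' @param bands band table (default [canonical_bands()])
#' @param epoch_length_s epoch length in seconds
#' @param filter_order Butterworth design order
#' @param th_formula tree-hierarchy variant
#' @param verbose print per-subject progress
#' @return an [epoch_metrics()] object
#' @export
compute_epoch_metrics <- function(subjects, epoch_sel,
                                  bands = canonical_bands(),
                                  epoch_length_s = 8, filter_order = 4,
                                  th_formula = "reference", verbose = FALSE) {
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  groups <- vapply(subjects, `[[`, character(1), "group")
  compute_epoch_metrics_lazy(
    function(s) subjects[[s]], length(subjects), ids, groups,
    nrow(subjects[[1]]$data), subjects[[1]]$region_labels, epoch_sel,
    bands, epoch_length_s, filter_order, th_formula, verbose)
}

# streaming variant: `fetch(s)` materializes subject s on demand, so only one
# subject's signals are in memory at a time (a full simulated cohort of
# 90 x 240 s recordings would not fit otherwise)
compute_epoch_metrics_lazy <- function(fetch, n_subj, ids, groups, n_reg,
                                       labels, epoch_sel,
                                       bands = canonical_bands(),
                                       epoch_length_s = 8, filter_order = 4,
                                       th_formula = "reference",
                                       verbose = FALSE) {
  n_ep <- length(epoch_sel[[1]])
  gnames <- c("leaf_fraction", "degree_divergence", "tree_hierarchy")
  dn_nodal <- list(ids, labels, NULL, bands$name)
  deg <- array(NA_real_, c(n_subj, n_reg, n_ep, nrow(bands)), dn_nodal)
  bc <- array(NA_real_, c(n_subj, n_reg, n_ep, nrow(bands)), dn_nodal)
  glob <- array(NA_real_, c(n_subj, 3, n_ep, nrow(bands)),
                list(ids, gnames, NULL, bands$name))
  for (s in seq_len(n_subj)) {
    ts <- fetch(s)
    if (nrow(ts$data) != n_reg)
      abort_invalid(sprintf(
        "subject %s: region count %d differs from the cohort's %d",
        ts$subject_id, nrow(ts$data), n_reg))
    if (verbose)
      message(sprintf("[%d/%d] subject %s", s, n_subj, ts$subject_id))
    for (b in seq_len(nrow(bands))) {
      bd <- band_definition(bands$name[b], bands$low_hz[b], bands$high_hz[b])
      ph <- extract_phase(bandpass(ts, bd, filter_order))
      ep <- slice_epochs(ph, ts$fs, epoch_length_s, epoch_sel[[s]])
      for (k in seq_len(n_ep)) {
        tree <- mst_from_adjacency(pli_matrix(ep, k))
        tm <- tree_metrics(tree, th_formula)
        deg[s, , k, b] <- tm$degree
        bc[s, , k, b] <- tm$bc
        glob[s, , k, b] <- c(tm$leaf_fraction, tm$degree_divergence,
                             tm$tree_hierarchy)
      }
    }
  }
  epoch_metrics(deg, bc, glob, groups)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> resample -> band-pass -> Hilbert phase -> epoch with
#' cross-subject equalization -> PLI adjacency per epoch -> MST -> nodal and
#' global tree metrics -> epoch averaging -> two-group permutation tests with
#' FDR correction -> optional epoch-resampling robustness. Re-running with an
#' identical configuration reproduces all outputs exactly.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return list of class `pipeline_result`: `config`, `metric_table`,
#'   `stats` (per-test permutation + FDR results), `robustness` (or `NULL`),
#'   `epoch_metrics`, `provenance`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(config$manifest)) {
    say("stage load: reading manifest %s", config$manifest)
    subjects <- lapply(load_cohort(config$manifest), resample_ts,
                       target_fs = config$target_fs)
    ids <- vapply(subjects, `[[`, character(1), "subject_id")
    groups <- vapply(subjects, `[[`, character(1), "group")
    n_avail <- vapply(subjects, function(s)
      n_available_epochs(ncol(s$data), s$fs, config$epoch_length_s),
      integer(1))
    n_reg <- nrow(subjects[[1]]$data)
    labels <- subjects[[1]]$region_labels
    fetch <- function(s) subjects[[s]]
    n_subj <- length(subjects)
  } else {
    sim <- config$simulation
    say("stage simulate: %d + %d subjects, %d regions (streamed)",
        sim$n_group_a, sim$n_group_b, sim$n_regions)
    nets <- default_network_pair(
      n_regions = sim$n_regions, hub = sim$hub,
      effect_band = sim$effect_band, n_extra = sim$n_extra,
      effect_strength = sim$effect_strength, effect_lag = sim$effect_lag,
      seed = sim$network_seed)
    plan <- cohort_plan(nets$net_a, nets$net_b,
                        cohort_spec(sim$n_group_a, sim$n_group_b,
                                    sim$recording_duration_s,
                                    config$target_fs,
                                    config$seeds$simulation))
    ids <- plan$ids
    groups <- plan$groups
    n_subj <- plan$n_total
    n_avail <- rep(n_available_epochs(
      round(sim$recording_duration_s * config$target_fs), config$target_fs,
      config$epoch_length_s), n_subj)
    n_reg <- sim$n_regions
    labels <- default_region_labels(n_reg)
    fetch <- plan$simulate
  }
  names(n_avail) <- ids

  say("stage epochs: equalizing epoch counts")
  epoch_sel <- select_epochs(n_avail, config$n_epochs, config$seeds$epochs)

  say("stage connectivity/trees: PLI + MST metrics per epoch and band")
  em <- compute_epoch_metrics_lazy(fetch, n_subj, ids, groups, n_reg, labels,
                                   epoch_sel, config$bands,
                                   config$epoch_length_s, config$filter_order,
                                   config$th_formula, verbose)

  say("stage stats: %d permutations", config$n_perm)
  table <- average_over_epochs(em)
  stats <- adjust_fdr(
    permutation_test(table, config$n_perm, config$seeds$permutation),
    config$q, config$fdr_family)

  robustness <- NULL
  if (config$n_iter_robustness > 0) {
    n_rb <- min(config$n_epochs_robustness, min(lengths(epoch_sel)))
    say("stage robustness: %d iterations of %d epochs",
        config$n_iter_robustness, n_rb)
    robustness <- robustness_resample(
      em, config$n_iter_robustness, n_rb, config$seeds$robustness,
      config$n_perm, config$seeds$permutation, config$q, config$fdr_family)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("plimst")),
    r_version = R.version.string,
    seeds = config$seeds,
    n_subjects = n_subj,
    n_epochs_used = length(epoch_sel[[1]]),
    timestamp = NULL) # deliberately not recorded: outputs must be bit-reproducible

  result <- structure(list(config = config, metric_table = table,
                           stats = stats, robustness = robustness,
                           epoch_metrics = em, provenance = provenance),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' Write the result bundle of a pipeline run
#'
#' @param result a `pipeline_result`
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metric_table, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$stats), file.path(dir, "stats.csv"),
            row.names = FALSE)
  if (!is.null(result$robustness)) {
    write.csv(result$robustness$p_table,
              file.path(dir, "robustness_iterations.csv"), row.names = FALSE)
    write.csv(result$robustness$summary,
              file.path(dir, "robustness_summary.csv"), row.names = FALSE)
  }
  cfg <- unclass(result$config)
  cfg$bands <- as.list(cfg$bands)
  jsonlite::write_json(list(config = cfg, provenance = result$provenance),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Significant nodes of a pipeline run
#'
#' @param result a `pipeline_result`
#' @return data.frame of FDR-significant tests
#' @export
significant_nodes <- function(result) {
  s <- result$stats
  as.data.frame(s[which(s$significant), ])
}
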