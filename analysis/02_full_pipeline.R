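#!/usr/bin/env Rscript
# Step 2 — the end-to-end study on a synthetic two-group cohort: band-pass ->
# Hilbert phase -> equalized 8-s epochs -> PLI adjacency per epoch -> minimum
# spanning tree -> nodal (degree, betweenness) and global (leaf fraction,
# degree divergence, tree hierarchy) metrics -> epoch averaging -> label
# permutation tests with BH-FDR -> epoch-resampling robustness.
#
#   Rscript analysis/02_full_pipeline.R [desk|full]
#
# "full" runs the complete study design (90 regions, 26 vs 29 subjects, 24
# epochs, 10000 permutations, 100 robustness iterations; ~30 min on one CPU).
# "desk" (default) is a reduced rendition for quick inspection: 24 regions,
# 12 epochs, 2000 permutations, 20 robustness iterations (~3 min).

suppressMessages(library(plimst))

scale <- if (length(commandArgs(TRUE))) commandArgs(TRUE)[1] else "desk"
cfg <- if (scale == "full") {
  pipeline_config(
    n_iter_robustness = 100,
    seeds = list(simulation = 1L, epochs = 2L, permutation = 3L,
                 robustness = 4L),
    out_dir = "results/02_pipeline_full")
} else {
  pipeline_config(
    simulation = list(n_regions = 24, recording_duration_s = 104),
    n_epochs = 12, n_perm = 2000, n_iter_robustness = 20,
    n_epochs_robustness = 8,
    seeds = list(simulation = 1L, epochs = 2L, permutation = 3L,
                 robustness = 4L),
    out_dir = "results/02_pipeline_desk")
}

cat(sprintf("Scale: %s (%d regions, %s epochs, %d permutations)\n", scale,
            cfg$simulation$n_regions, cfg$n_epochs, cfg$n_perm))
t0 <- proc.time()
res <- run_pipeline(cfg, verbose = TRUE)
cat(sprintf("Pipeline finished in %.1f min; outputs in %s\n",
            (proc.time() - t0)[3] / 60, cfg$out_dir))

hub <- if (cfg$simulation$n_regions == 90) "Postcentral_L" else
  default_region_labels(cfg$simulation$n_regions)[ceiling(cfg$simulation$n_regions / 2)]
sig <- significant_nodes(res)
cat(sprintf("\n%d of %d tests significant at FDR q = %.2f:\n",
            nrow(sig), nrow(res$stats), cfg$q))
print(sig[, c("band", "metric", "node", "observed_diff", "p_raw", "p_fdr")],
      row.names = FALSE)

hub_rows <- res$stats[!is.na(res$stats$node) & res$stats$node == hub &
                        res$stats$band == "beta", ]
cat(sprintf("\nPlanted hub (%s), beta band:\n", hub))
print(as.data.frame(hub_rows[, c("metric", "observed_diff", "p_raw", "p_fdr",
                                 "significant")]), row.names = FALSE)

if (!is.null(res$robustness)) {
  rb <- res$robustness$summary
  rb_hub <- rb[!is.na(rb$node) & rb$node == hub & rb$band == "beta", ]
  cat("\nEpoch-resampling robustness at the hub (fraction of iterations",
      "significant after FDR):\n")
  print(rb_hub, row.names = FALSE)
}
cat("\nFinding: the planted beta-band hub effect should appear as positive",
    "degree and betweenness differences at the hub, significant after FDR,",
    "with untouched bands silent.\n")
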