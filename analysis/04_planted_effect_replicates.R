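#!/usr/bin/env Rscript
# Step 4 — replicate study of planted-effect recovery: repeats the scaled
# end-to-end analysis over independently seeded cohorts and tabulates how
# often the planted beta-band hub is FDR-significant for degree and
# betweenness while all untouched bands stay silent.
#
#   Rscript analysis/04_planted_effect_replicates.R [n_replicates]   (default 5)

suppressMessages(library(plimst))

n_rep <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 5L
out_dir <- "results/04_replicates"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_regions <- 24
hub <- default_region_labels(n_regions)[ceiling(n_regions / 2)]
rows <- vector("list", n_rep)
for (r in seq_len(n_rep)) {
  cfg <- pipeline_config(
    simulation = list(n_regions = n_regions, recording_duration_s = 52),
    n_epochs = 6, n_perm = 2000, n_iter_robustness = 0,
    seeds = list(simulation = 100L + r, epochs = 200L + r,
                 permutation = 300L + r, robustness = 1L))
  res <- run_pipeline(cfg)
  s <- res$stats
  nodal_sig <- s[!is.na(s$node) & s$significant, ]
  hub_deg <- any(nodal_sig$metric == "degree" & nodal_sig$band == "beta" &
                   nodal_sig$node == hub & nodal_sig$observed_diff > 0)
  hub_bc <- any(nodal_sig$metric == "bc" & nodal_sig$band == "beta" &
                  nodal_sig$node == hub & nodal_sig$observed_diff > 0)
  off_band <- sum(nodal_sig$band != "beta")
  rows[[r]] <- data.frame(replicate = r, hub_degree_sig = hub_deg,
                          hub_bc_sig = hub_bc, off_band_hits = off_band,
                          n_beta_sig = sum(nodal_sig$band == "beta"))
  cat(sprintf("replicate %d: hub degree %s, hub bc %s, off-band hits %d\n",
              r, hub_deg, hub_bc, off_band))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "replicates.csv"), row.names = FALSE)
success <- tab$hub_degree_sig & tab$hub_bc_sig & tab$off_band_hits == 0
cat(sprintf("\nFinding: full recovery (hub significant for both metrics, no\noff-band false positive) in %d of %d replicates.\n",
            sum(success), n_rep))
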