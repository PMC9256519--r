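#!/usr/bin/env Rscript
# Step 1 — synthetic cohort generator: builds the two group networks (shared
# random backbone in every band, plus three strong lagged couplings converging
# on one hub region in the beta band for group A), simulates one example
# subject per group, and verifies that each band's oscillators put their
# spectral power where the analysis expects it.

suppressMessages(library(plimst))

out_dir <- "results/01_simulate"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

nets <- default_network_pair(n_regions = 90, seed = 20220507L)
cat(sprintf("Hub region: %s (index %d); partners: %s\n",
            aal90_labels()[nets$hub], nets$hub,
            paste(aal90_labels()[nets$partners], collapse = ", ")))
cat(sprintf("Backbone: %d couplings per band, strengths %.2f-%.2f\n",
            sum(nets$net_b$coupling_edges$band == "beta"),
            min(nets$net_b$coupling_edges$strength),
            max(nets$net_b$coupling_edges$strength)))

# one subject per group, full-length recording
cohort <- simulate_cohort(nets$net_a, nets$net_b,
                          cohort_spec(1, 1, recording_duration_s = 240,
                                      seed = 1L))
sa <- cohort$subjects[[1]]

# spectral placement: single-band generators peak inside their band
bands <- canonical_bands()
rows <- lapply(seq_len(nrow(bands)), function(b) {
  ctr <- stats::setNames(band_centers()[b], bands$name[b])
  spec1 <- oscillator_network_spec(n_regions = 3, band_center_hz = ctr)
  ts1 <- simulate_subject(spec1, 30, 512, seed = 100 + b)
  pg <- stats::spec.pgram(stats::ts(ts1$data[1, ], frequency = 512),
                          taper = 0, plot = FALSE, span = 5)
  data.frame(band = bands$name[b], low_hz = bands$low_hz[b],
             high_hz = bands$high_hz[b],
             peak_hz = pg$freq[which.max(pg$spec)])
})
spectra <- do.call(rbind, rows)
spectra$inside <- spectra$peak_hz > spectra$low_hz &
  spectra$peak_hz < spectra$high_hz
write.csv(spectra, file.path(out_dir, "spectral_placement.csv"),
          row.names = FALSE)
cat("\nSpectral placement of single-band generators:\n")
print(spectra, row.names = FALSE)

# planted-edge visibility: beta-band PLI of the hub edges, group A vs B
check_hub_pli <- function(ts) {
  ph <- extract_phase(bandpass(ts, "beta"))
  w <- pli_matrix(slice_epochs(ph, 512, 8, 1:3), 1)
  mean(w[nets$hub, nets$partners])
}
pli_a <- check_hub_pli(sa)
pli_b <- check_hub_pli(cohort$subjects[[2]])
cat(sprintf("\nMean beta PLI on the planted hub edges: group A %.2f, group B %.2f\n",
            pli_a, pli_b))
write.csv(data.frame(group = c("A", "B"), hub_edge_pli = c(pli_a, pli_b)),
          file.path(out_dir, "hub_edge_pli.csv"), row.names = FALSE)

if (all(spectra$inside) && pli_a > 0.8 && pli_a > pli_b)
  cat("\nFinding: the generator produces band-limited signals and the planted\n",
      "hub couplings are visible as strong beta-band PLI in group A only.\n")
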