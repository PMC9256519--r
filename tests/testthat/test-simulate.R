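one_band_spec <- function(n_regions, edges = empty_edges(), center = c(alpha = 10.5),
                          ...) {
  oscillator_network_spec(n_regions = n_regions, band_center_hz = center,
                          coupling_edges = edges, ...)
}

test_that("simulation is reproducible bit-for-bit from the seed", {
  spec <- one_band_spec(4)
  a <- simulate_subject(spec, 10, 512, seed = 99)
  b <- simulate_subject(spec, 10, 512, seed = 99)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         simulate_subject(spec, 10, 512, seed = 100)$data))

  nets <- default_network_pair(n_regions = 8, seed = 5)
  cs <- cohort_spec(2, 2, recording_duration_s = 10, seed = 7)
  c1 <- simulate_cohort(nets$net_a, nets$net_b, cs)
  c2 <- simulate_cohort(nets$net_a, nets$net_b, cs)
  expect_identical(lapply(c1$subjects, `[[`, "data"),
                   lapply(c2$subjects, `[[`, "data"))
  # byte-wise identity of the stored form
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, "\\.tsv$", full.names = TRUE)
  f2 <- list.files(d2, "\\.tsv$", full.names = TRUE)
  expect_identical(lapply(f1, readBin, what = "raw", n = 1e7),
                   lapply(f2, readBin, what = "raw", n = 1e7))
})

test_that("per-region spectra peak inside the oscillators' band", {
  bands <- canonical_bands()
  for (b in seq_len(nrow(bands))) {
    ctr <- stats::setNames(band_centers()[b], bands$name[b])
    spec <- one_band_spec(3, center = ctr)
    ts <- simulate_subject(spec, 30, 512, seed = 10 + b)
    for (r in 1:3) {
      pg <- stats::spec.pgram(stats::ts(ts$data[r, ], frequency = 512),
                              taper = 0, plot = FALSE, span = 5)
      fpeak <- pg$freq[which.max(pg$spec)]
      expect_gt(fpeak, bands$low_hz[b])
      expect_lt(fpeak, bands$high_hz[b])
    }
  }
})

test_that("a planted lag is recovered by the extracted phase difference", {
  tau <- 0.6
  spec <- one_band_spec(
    2, edges = data.frame(band = "alpha", i = 1L, j = 2L, strength = 1,
                          lag = tau),
    noise_sd = 0, detuning_hz = 0, freq_noise_sd = 0)
  ts <- simulate_subject(spec, 20, 512, seed = 3)
  ph <- extract_phase(bandpass(ts, "alpha"))
  mid <- 2000:8000 # away from record edges and the locking transient
  d <- ph[1, mid] - ph[2, mid]
  circ_mean <- Arg(mean(exp(1i * d)))
  expect_lt(abs(circ_mean - tau), 0.05)
})

test_that("coupling extremes map to the PLI extremes", {
  # strength-1 edge, lag pi/4, no noise: perfect nonzero-lag synchronization
  spec1 <- one_band_spec(
    2, edges = data.frame(band = "alpha", i = 1L, j = 2L, strength = 1,
                          lag = pi / 4),
    noise_sd = 0, freq_noise_sd = 0)
  ts1 <- simulate_subject(spec1, 16, 512, seed = 11)
  ph1 <- extract_phase(bandpass(ts1, "alpha"))
  ep1 <- slice_epochs(ph1, 512, 8, 2)
  expect_gt(pli_matrix(ep1, 1)[1, 2], 0.99)

  # zero-lag edge: perfectly coupled yet invisible (the PLI blind spot)
  expect_warning(
    spec0 <- one_band_spec(
      2, edges = data.frame(band = "alpha", i = 1L, j = 2L, strength = 1,
                            lag = 0),
      noise_sd = 0, detuning_hz = 0),
    "zero-lag")
  ts0 <- simulate_subject(spec0, 16, 512, seed = 12)
  ph0 <- extract_phase(bandpass(ts0, "alpha"))
  expect_lt(pli_matrix(slice_epochs(ph0, 512, 8, 2), 1)[1, 2], 0.15)

  # no coupling at all: PLI decays toward 0 with record length
  specn <- one_band_spec(2)
  tsn <- simulate_subject(specn, 80, 512, seed = 13)
  phn <- extract_phase(bandpass(tsn, "alpha"))
  epn <- slice_epochs(phn, 512, 80, 1)
  expect_lt(pli_matrix(epn, 1)[1, 2], 0.2)
})

test_that("invalid simulation arguments are rejected", {
  spec <- one_band_spec(3)
  expect_error(simulate_subject(spec, -1, 512), class = "plimst_invalid_argument")
  expect_error(simulate_subject(spec, 10, 0), class = "plimst_invalid_argument")
  expect_error(
    oscillator_network_spec(3, coupling_edges = data.frame(
      band = "delta", i = 1L, j = 9L, strength = .5, lag = .1)),
    class = "plimst_invalid_argument")
  expect_error(
    oscillator_network_spec(3, coupling_edges = data.frame(
      band = "delta", i = 1L, j = 2L, strength = 1.5, lag = .1)),
    class = "plimst_invalid_argument")
  nets <- default_network_pair(n_regions = 10, seed = 2)
  other <- one_band_spec(5)
  expect_error(
    simulate_cohort(nets$net_a, other, cohort_spec(2, 2, 10)),
    class = "plimst_invalid_argument")
  expect_error(cohort_spec(0, 5), class = "plimst_invalid_argument")
})
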