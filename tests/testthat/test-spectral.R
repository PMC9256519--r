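sine_ts <- function(freq, fs = 512, dur = 20, phase = 0, n_chan = 1) {
  t <- (0:(dur * fs - 1)) / fs
  source_ts(matrix(rep(sin(2 * pi * freq * t + phase), n_chan),
                   nrow = n_chan, byrow = TRUE), fs)
}

test_that("band-pass keeps in-band energy and rejects out-of-band energy", {
  ts <- sine_ts(10)
  mid <- 3000:7000
  inband <- bandpass(ts, "alpha")
  expect_lt(abs(sd(inband$data[1, mid]) / sd(ts$data[1, mid]) - 1), 0.05)
  outband <- bandpass(ts, "gamma")
  expect_lt(sd(outband$data[1, mid]) / sd(ts$data[1, mid]), 0.01)
  zeros <- source_ts(matrix(0, 2, 4096), 512)
  expect_true(all(bandpass(zeros, "alpha")$data == 0))
  expect_error(bandpass(source_ts(matrix(rnorm(500), 1), 90), "gamma"),
               class = "plimst_invalid_argument")
})

test_that("filtering is zero-phase: no lag between input and output", {
  ts <- sine_ts(10)
  y <- bandpass(ts, "alpha")$data[1, ]
  x <- ts$data[1, ]
  mid <- 3000:7000
  lags <- -20:20
  cc <- vapply(lags, function(l) sum(x[mid] * y[mid + l]), numeric(1))
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("resampling preserves spectral content and rescales length", {
  ts <- sine_ts(10, fs = 1024, dur = 10)
  expect_identical(resample_ts(ts, 1024), ts)
  down <- resample_ts(ts, 512)
  expect_identical(ncol(down$data), 5120L)
  expect_identical(down$fs, 512)
  pg <- stats::spec.pgram(stats::ts(down$data[1, ], frequency = 512),
                          taper = 0, plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)], 10, tolerance = 0.05)
  expect_error(resample_ts(ts, -5), class = "plimst_invalid_argument")
})

test_that("instantaneous phase behaves like the analytic-signal argument", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  ts <- source_ts(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs)
  ph <- extract_phase(ts)
  expect_true(all(ph > -pi & ph <= pi))
  mid <- 1000:4000
  d <- wrap_phase(ph[1, mid] - ph[2, mid])
  expect_equal(mean(d), pi / 2, tolerance = 1e-3)   # quadrature pair
  expect_true(all(ph[1, ] - ph[1, ] == 0))          # any signal vs itself

  # unwrapped phase of a 10 Hz tone advances at 2*pi*10 rad/s
  up <- ph[2, ] + 2 * pi * cumsum(c(0, diff(ph[2, ]) < -pi))
  slope <- stats::coef(stats::lm(up[mid] ~ t[mid]))[2]
  expect_lt(abs(slope / (2 * pi * 10) - 1), 0.01)
})

test_that("constant channels are flagged and poison downstream PLI", {
  m <- rbind(sin(2 * pi * 10 * (0:4095) / 512), 0.7)
  ts <- source_ts(m, 512, c("ok", "flat"))
  expect_warning(ph <- extract_phase(ts), "flat")
  expect_identical(attr(ph, "degenerate_regions"), 2L)
  ep <- slice_epochs(ph, 512, 8, 1)
  expect_error(pli_matrix(ep, 1), class = "plimst_degenerate_input")
})

test_that("epoch selection equalizes counts across subjects", {
  n_avail <- c(s1 = 30L, s2 = 25L, s3 = 24L)
  sel <- select_epochs(n_avail, "min", seed = 1)
  expect_true(all(lengths(sel) == 24L))
  expect_true(all(vapply(seq_along(sel), function(i)
    all(sel[[i]] %in% seq_len(n_avail[i])), logical(1))))
  expect_identical(select_epochs(n_avail, "min", seed = 1), sel)
  expect_false(identical(select_epochs(n_avail, "min", seed = 2), sel))
  expect_error(select_epochs(n_avail, 26, seed = 1), "s2",
               class = "plimst_invalid_argument")

  # 200-s recordings at 512 Hz hold 25 complete 8-s epochs; 24 selected
  # epochs of 4096 samples each
  ph <- matrix(rnorm(2 * 200 * 512), 2)
  eq <- epoch_and_equalize(list(a = ph, b = ph), fs = 512, epoch_length_s = 8,
                           n_epochs = 24, seed = 3)
  expect_identical(dim(eq$a), c(2L, 4096L, 24L))
  expect_identical(dim(eq$b), c(2L, 4096L, 24L))
})
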