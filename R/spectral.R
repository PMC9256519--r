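#' Construct a source-level time-series object
#'
#' One subject's region-by-sample matrix of source-reconstructed signals,
#' together with the sampling rate, region labels and cohort metadata.
#'
#' @param data numeric matrix, regions in rows, samples in columns
#' @param fs sampling rate in Hz
#' @param region_labels character vector, one label per row; defaults to the
#'   90-region atlas labels when `nrow(data) == 90`
#' @param subject_id subject identifier
#' @param group group label (e.g. "A"/"B")
#' @return object of class `source_ts`
#' @export
source_ts <- function(data, fs, region_labels = default_region_labels(nrow(data)),
                      subject_id = "S01", group = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    abort_invalid("data must be a numeric matrix (regions x samples)")
  if (any(!is.finite(data)))
    abort_invalid(sprintf("subject %s: data contain non-finite samples", subject_id))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_invalid("fs must be a positive scalar")
  if (length(region_labels) != nrow(data))
    abort_invalid("region_labels length must equal the number of rows of data")
  structure(list(data = data, fs = fs,
                 region_labels = as.character(region_labels),
                 subject_id = subject_id, group = group),
            class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  cat(sprintf("<source_ts> subject %s (group %s): %d regions x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth IIR band-pass of the given design order
#' forward-backward (`signal::filtfilt`), so no net phase shift is introduced
#' in the passband; the effective attenuation order is twice the design order.
#'
#' @param ts a [source_ts()]
#' @param band a `band_definition` (or canonical band name)
#' @param order Butterworth design order (default 4)
#' @return a filtered `source_ts` of identical shape
#' @export
bandpass <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "source_ts"))
  if (is.character(band)) band <- get_band(band)
  nyq <- ts$fs / 2
  if (band$high_hz >= nyq)
    abort_invalid(sprintf("band edge %g Hz >= Nyquist %g Hz", band$high_hz, nyq))
  bf <- signal::butter(order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  # reflection padding of ~3 cycles of the lowest passband frequency keeps
  # low-band edge transients of the forward-backward pass out of the record
  npad <- min(ncol(ts$data) - 1L, as.integer(ceiling(3 * ts$fs / band$low_hz)))
  ts$data <- filtfilt_rows_cpp(bf$b, bf$a, ts$data, npad)
  ts$band <- band$name
  ts
}

#' Resample a source time series
#'
#' Polyphase resampling with anti-aliasing (via `signal::resample`); the
#' output length is `floor(n * target_fs / fs)`.
#'
#' @param ts a [source_ts()]
#' @param target_fs target sampling rate in Hz (default 512)
#' @return a `source_ts` at `target_fs`
#' @export
resample_ts <- function(ts, target_fs = 512) {
  stopifnot(inherits(ts, "source_ts"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    abort_invalid("target_fs must be a positive scalar")
  if (target_fs == ts$fs) return(ts)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(round(target_fs * 1000), round(ts$fs * 1000))
  p <- round(target_fs * 1000) / d
  q <- round(ts$fs * 1000) / d
  n_out <- floor(ncol(ts$data) * target_fs / ts$fs)
  out <- matrix(0, nrow(ts$data), n_out)
  for (r in seq_len(nrow(ts$data))) {
    y <- signal::resample(ts$data[r, ], p, q)
    out[r, ] <- y[seq_len(n_out)]
  }
  ts$data <- out
  ts$fs <- target_fs
  ts
}

#' Instantaneous phase of every region via the Hilbert transform
#'
#' Computes the analytic signal per region and returns its argument, wrapped
#' to (-pi, pi]. Intended for band-limited input (apply [bandpass()] first).
#' Zero-variance (constant) channels have undefined phase: they are flagged in
#' the `degenerate_regions` attribute with a warning, and downstream PLI
#' computation on them raises a degenerate-input error.
#'
#' @param ts a band-limited [source_ts()]
#' @return numeric matrix of phases (regions x samples) with attributes
#'   `fs`, `band`, `degenerate_regions`
#' @export
extract_phase <- function(ts) {
  stopifnot(inherits(ts, "source_ts"))
  n <- ncol(ts$data)
  rng <- apply(ts$data, 1, function(x) max(x) - min(x))
  degen <- which(rng == 0)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(ts$data)) * h
  ph <- t(Arg(mvfft(X, inverse = TRUE)))
  ph[ph == -pi] <- pi # principal value in (-pi, pi]
  if (length(degen)) ph[degen, ] <- 0
  if (length(degen))
    warning(sprintf("constant (zero-variance) channel(s): %s; phase undefined",
                    paste(ts$region_labels[degen], collapse = ", ")))
  rownames(ph) <- ts$region_labels
  attr(ph, "fs") <- ts$fs
  attr(ph, "band") <- if (is.null(ts$band)) NA_character_ else ts$band
  attr(ph, "degenerate_regions") <- degen
  ph
}

#' Wrap angles to the principal value (-pi, pi]
#'
#' @param x angles in radians
#' @return wrapped angles
#' @export
wrap_phase <- function(x) {
  w <- Arg(exp(1i * x))
  w[w == -pi] <- pi
  w
}

#' Number of complete epochs available in a recording
#'
#' @param n_samples samples in the recording
#' @param fs sampling rate (Hz)
#' @param epoch_length_s epoch length in seconds
#' @return integer count
#' @export
n_available_epochs <- function(n_samples, fs, epoch_length_s = 8) {
  as.integer(floor(n_samples / (epoch_length_s * fs)))
}

#' Random epoch selection with cross-subject equalization
#'
#' Chooses, for every subject, which complete epochs enter the analysis so
#' that all subjects contribute exactly the same number. Selection is uniform
#' without replacement and deterministic given the seed.
#'
#' @param n_avail named integer vector: complete epochs available per subject
#' @param n_epochs requested count, or `"min"` for the cohort-wide minimum
#' @param seed integer seed
#' @return named list of sorted epoch-index vectors, one per subject
#' @export
select_epochs <- function(n_avail, n_epochs = "min", seed = 1L) {
  if (length(n_avail) == 0L) abort_invalid("empty cohort")
  if (identical(n_epochs, "min")) n_epochs <- min(n_avail)
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 1L) abort_invalid("n_epochs must be >= 1")
  short <- names(n_avail)[n_avail < n_epochs]
  if (length(short))
    abort_invalid(sprintf(
      "subject(s) with fewer than %d complete epochs: %s",
      n_epochs, paste(short, collapse = ", ")))
  seeds <- derive_seeds(seed, length(n_avail))
  out <- vector("list", length(n_avail))
  names(out) <- names(n_avail)
  for (i in seq_along(n_avail)) {
    set.seed(seeds[i])
    out[[i]] <- sort(sample.int(n_avail[i], n_epochs))
  }
  out
}

#' Slice a phase matrix into selected epochs
#'
#' @param phases regions x samples phase matrix (from [extract_phase()])
#' @param fs sampling rate in Hz
#' @param epoch_length_s epoch length in seconds
#' @param indices which epochs to keep (1-based, from [select_epochs()])
#' @return 3-d array regions x samples-per-epoch x epoch, class `epoch_phases`
#' @export
slice_epochs <- function(phases, fs, epoch_length_s = 8,
                         indices = seq_len(n_available_epochs(ncol(phases), fs, epoch_length_s))) {
  len <- as.integer(round(epoch_length_s * fs))
  n_av <- floor(ncol(phases) / len)
  if (any(indices < 1L | indices > n_av))
    abort_invalid("epoch index out of range")
  arr <- array(0, dim = c(nrow(phases), len, length(indices)),
               dimnames = list(rownames(phases), NULL, NULL))
  for (k in seq_along(indices)) {
    off <- (indices[k] - 1L) * len
    arr[, , k] <- phases[, (off + 1L):(off + len), drop = FALSE]
  }
  structure(arr, fs = fs, epoch_length_s = epoch_length_s,
            band = attr(phases, "band"),
            epoch_indices = indices,
            degenerate_regions = attr(phases, "degenerate_regions"),
            class = c("epoch_phases", "array"))
}

#' Epoch a cohort of phase series with equalized epoch counts
#'
#' Convenience composition of [select_epochs()] and [slice_epochs()] for one
#' frequency band: every subject ends up with exactly the same number of
#' randomly selected 8-s (by default) epochs.
#'
#' @param phase_list named list of regions x samples phase matrices
#' @param fs sampling rate in Hz
#' @param epoch_length_s epoch length in seconds (default 8)
#' @param n_epochs requested epoch count or `"min"`
#' @param seed integer seed for the random selection
#' @return named list of `epoch_phases` arrays
#' @export
epoch_and_equalize <- function(phase_list, fs, epoch_length_s = 8,
                               n_epochs = "min", seed = 1L) {
  n_avail <- vapply(phase_list, function(p)
    n_available_epochs(ncol(p), fs, epoch_length_s), integer(1))
  sel <- select_epochs(n_avail, n_epochs, seed)
  out <- Map(function(p, idx) slice_epochs(p, fs, epoch_length_s, idx),
             phase_list, sel)
  out
}
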