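#' Phase Lag Index between two phase series
#'
#' PLI = | < sign( sin( phase_a - phase_b ) ) > | where < > averages over
#' samples and sign(0) = 0. The PLI lies in \[0, 1\]: 1 for a perfectly
#' consistent nonzero phase lag, 0 when the lag is zero or the sign of the
#' lag is balanced. Zero-lag (volume-conduction-like) coupling is invisible
#' by construction.
#'
#' @param phase_a,phase_b numeric phase vectors of equal length (radians)
#' @return scalar PLI in \[0, 1\]
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 512)
#' pli_pair(2 * pi * 10 * t, 2 * pi * 10 * t + pi / 4) # constant lag -> 1
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    abort_invalid("phase series must have equal length")
  if (length(phase_a) < 2L)
    abort_invalid("phase series must have length >= 2")
  if (any(!is.finite(phase_a)) || any(!is.finite(phase_b)))
    abort_invalid("phase series must be finite")
  if (max(phase_a) - min(phase_a) == 0 || max(phase_b) - min(phase_b) == 0)
    abort_degenerate("constant phase series: channel phase is undefined")
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' PLI adjacency matrix for one epoch
#'
#' Computes the PLI for every unordered region pair of one epoch, returning a
#' symmetric zero-diagonal weighted adjacency matrix.
#'
#' @param epochs an `epoch_phases` array (regions x samples x epochs)
#' @param epoch_index which epoch of the array to use
#' @return symmetric numeric matrix with attributes `band`, `epoch_index`
#' @export
pli_matrix <- function(epochs, epoch_index = 1L) {
  stopifnot(inherits(epochs, "epoch_phases"))
  if (epoch_index < 1L || epoch_index > dim(epochs)[3])
    abort_invalid(sprintf("epoch_index %d out of range (1..%d)",
                          epoch_index, dim(epochs)[3]))
  degen <- attr(epochs, "degenerate_regions")
  labels <- dimnames(epochs)[[1]]
  if (length(degen)) {
    nm <- if (is.null(labels)) as.character(degen) else labels[degen]
    abort_degenerate(sprintf(
      "degenerate (constant) channel(s) %s: PLI undefined", paste(nm, collapse = ", ")))
  }
  ph <- epochs[, , epoch_index, drop = TRUE]
  w <- pli_matrix_cpp(ph)
  dimnames(w) <- list(labels, labels)
  attr(w, "band") <- attr(epochs, "band")
  attr(w, "epoch_index") <- epoch_index
  w
}

#' Reference PLI matrix (plain double loop over pairs)
#'
#' Slow but transparent implementation used for cross-checking the compiled
#' kernel; computes each pair with [pli_pair()].
#'
#' @param phases regions x samples numeric phase matrix
#' @return symmetric PLI matrix
#' @export
pli_matrix_reference <- function(phases) {
  n <- nrow(phases)
  w <- matrix(0, n, n, dimnames = list(rownames(phases), rownames(phases)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- phases[i, ] - phases[j, ]
      w[i, j] <- w[j, i] <- abs(mean(sign(sin(d))))
    }
  }
  w
}

#' Write per-epoch adjacency matrices as delimited text
#'
#' @param mats list of adjacency matrices
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
write_adjacency <- function(mats, dir, prefix = "pli") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(mats))
  for (k in seq_along(mats)) {
    paths[k] <- file.path(dir, sprintf("%s_epoch%03d.tsv", prefix, k))
    utils::write.table(mats[[k]], paths[k], sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
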