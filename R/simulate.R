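#' Specification of a lag-coupled oscillator network
#'
#' Defines the generative model for one group's synthetic source signals: per
#' frequency band, a set of phase oscillators (one per region, natural
#' frequencies drawn within `detuning_hz` of the band centre) coupled along
#' the listed edges with a fixed phase lag. The observed signal is the sum
#' over bands of `sin(theta)` plus white measurement noise — a direct,
#' controllable source of band-limited phase-lag structure, which is exactly
#' what the PLI measures.
#'
#' @param n_regions number of regions (default 90)
#' @param band_center_hz named vector of band centre frequencies in Hz
#'   (defaults to the midpoints of the five canonical bands)
#' @param coupling_edges data.frame with columns `band`, `i`, `j`,
#'   `strength` (in \[0, 1\]), `lag` (radians, nonzero: zero-lag coupling is
#'   invisible to the PLI so planting it would be undetectable by design)
#' @param noise_sd SD of additive white measurement noise (signal amplitude
#'   per band is 1)
#' @param hub_regions indices of regions receiving extra couplings in the
#'   effect group (metadata; used by [default_network_pair()])
#' @param effect_band band carrying the planted group difference (metadata)
#' @param detuning_hz natural frequencies are uniform in band centre +/- this
#'   (default 0.5 Hz), so uncoupled regions drift apart
#' @param freq_noise_sd SD of white frequency noise in rad/sqrt(s)
#'   (default 1): decorrelates uncoupled pairs within an epoch
#' @param coupling_scale rad/s corresponding to strength 1 (default 4*pi)
#' @return list of class `oscillator_network_spec`
#' @export
oscillator_network_spec <- function(n_regions = 90,
                                    band_center_hz = band_centers(),
                                    coupling_edges = empty_edges(),
                                    noise_sd = 0.5,
                                    hub_regions = integer(0),
                                    effect_band = NA_character_,
                                    detuning_hz = 0.5,
                                    freq_noise_sd = 1,
                                    coupling_scale = 4 * pi) {
  coupling_edges <- as.data.frame(coupling_edges)
  if (nrow(coupling_edges)) {
    req <- c("band", "i", "j", "strength", "lag")
    if (!all(req %in% names(coupling_edges)))
      abort_invalid("coupling_edges needs columns band, i, j, strength, lag")
    if (any(coupling_edges$strength < 0 | coupling_edges$strength > 1))
      abort_invalid("coupling strengths must lie in [0, 1]")
    if (any(coupling_edges$lag == 0))
      warning("zero-lag coupling is invisible to the PLI by construction; ",
              "a planted zero-lag edge cannot be recovered")
    idx <- c(coupling_edges$i, coupling_edges$j)
    if (any(idx < 1 | idx > n_regions))
      abort_invalid("edge region indices must lie in [1, n_regions]")
    if (!all(coupling_edges$band %in% names(band_center_hz)))
      abort_invalid("edge band not present in band_center_hz")
  }
  structure(list(n_regions = as.integer(n_regions),
                 band_center_hz = band_center_hz,
                 coupling_edges = coupling_edges,
                 noise_sd = noise_sd,
                 hub_regions = as.integer(hub_regions),
                 effect_band = effect_band,
                 detuning_hz = detuning_hz,
                 freq_noise_sd = freq_noise_sd,
                 coupling_scale = coupling_scale),
            class = "oscillator_network_spec")
}

#' Empty coupling-edge table
#' @return zero-row data.frame with the edge columns
#' @export
empty_edges <- function() {
  data.frame(band = character(0), i = integer(0), j = integer(0),
             strength = numeric(0), lag = numeric(0))
}

#' Cohort-level simulation parameters
#'
#' @param n_group_a subjects in group A (default 26)
#' @param n_group_b subjects in group B (default 29)
#' @param recording_duration_s recording length per subject in seconds
#'   (default 240, enough for 30 complete 8-s epochs)
#' @param sampling_rate_hz sampling rate (default 512)
#' @param seed master seed; reproduces the cohort exactly
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_group_a = 26, n_group_b = 29,
                        recording_duration_s = 240,
                        sampling_rate_hz = 512, seed = 1L) {
  if (n_group_a < 1 || n_group_b < 1)
    abort_invalid("group sizes must be positive")
  if (recording_duration_s <= 0 || sampling_rate_hz <= 0)
    abort_invalid("duration and sampling rate must be positive")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 recording_duration_s = recording_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Matched network pair with a planted hub effect
#'
#' Builds two `oscillator_network_spec`s sharing an identical random coupling
#' backbone in every band; the effect-group network (A) additionally receives
#' `n_extra` strong lagged couplings converging on one hub region in the
#' effect band. Group B is the backbone alone, so all non-effect bands are
#' exchangeable between groups.
#'
#' @param n_regions regions (default 90)
#' @param hub hub region index; default: the left postcentral region for the
#'   90-region atlas, otherwise `ceiling(n_regions / 2)`
#' @param effect_band band carrying the effect (default "beta")
#' @param n_extra number of extra couplings onto the hub (default 3)
#' @param effect_strength strength of the extra couplings (default 0.8)
#' @param effect_lag phase lag of the extra couplings (default pi/4)
#' @param backbone_edges_per_band random backbone couplings per band
#'   (default `n_regions`)
#' @param backbone_strength range of backbone strengths (default 0.05-0.25:
#'   the partially-locking regime, giving a realistic spread of low-to-
#'   moderate PLI values instead of a globally synchronized band)
#' @param seed seed fixing the shared backbone and hub partners
#' @param ... passed to [oscillator_network_spec()] (noise levels etc.)
#' @return list with elements `net_a` (effect) and `net_b` (control)
#' @export
default_network_pair <- function(n_regions = 90,
                                 hub = NULL,
                                 effect_band = "beta",
                                 n_extra = 3,
                                 effect_strength = 0.8,
                                 effect_lag = pi / 4,
                                 backbone_edges_per_band = n_regions,
                                 backbone_strength = c(0.05, 0.25),
                                 seed = 20220507L, ...) {
  if (is.null(hub))
    hub <- if (n_regions == 90) match("Postcentral_L", aal90_labels())
           else ceiling(n_regions / 2)
  if (hub < 1 || hub > n_regions) abort_invalid("hub index out of range")
  centers <- band_centers()
  set.seed(seed)
  backbone <- do.call(rbind, lapply(names(centers), function(bn) {
    # distinct unordered pairs, sampled without replacement
    pool <- sample.int(n_regions * (n_regions - 1L) / 2L,
                       backbone_edges_per_band)
    ij <- pair_from_index(pool, n_regions)
    data.frame(band = bn, i = ij[, 1], j = ij[, 2],
               strength = runif(backbone_edges_per_band,
                                backbone_strength[1], backbone_strength[2]),
               lag = sample(c(-1, 1), backbone_edges_per_band, TRUE) *
                 runif(backbone_edges_per_band, pi / 8, pi / 2))
  }))
  taken <- unique(c(backbone$i[backbone$band == effect_band &
                                 backbone$j == hub],
                    backbone$j[backbone$band == effect_band &
                                 backbone$i == hub]))
  avail <- setdiff(seq_len(n_regions), c(hub, taken))
  if (length(avail) < n_extra)
    abort_invalid("too few regions free of backbone hub couplings to plant the extra edges")
  partners <- sample(avail, n_extra)
  # the hub leads every partner by the same lag: partner-partner phase
  # differences are then ~0 (invisible to the PLI), so the planted strong
  # links converge on the hub in PLI space, not just in the coupling graph
  extra <- data.frame(band = effect_band,
                      i = hub, j = partners,
                      strength = effect_strength, lag = effect_lag)
  net_b <- oscillator_network_spec(n_regions, centers, backbone, ...)
  net_a <- oscillator_network_spec(n_regions, centers, rbind(backbone, extra),
                                   hub_regions = hub,
                                   effect_band = effect_band, ...)
  list(net_a = net_a, net_b = net_b, hub = hub, partners = sort(partners))
}

# unordered pair (i < j) from a linear index over the upper triangle,
# column-major as in which(upper.tri(.))
pair_from_index <- function(idx, n) {
  ut <- which(upper.tri(matrix(0, n, n)))
  k <- ut[idx]
  cbind(i = (k - 1L) %% n + 1L, j = (k - 1L) %/% n + 1L)
}

#' Simulate one subject's source time series
#'
#' Integrates, independently per band, the lag-coupled phase-oscillator system
#' of the spec (Euler-Maruyama, dt = 1/fs) and observes the sum over bands of
#' `sin(theta)` plus white measurement noise. Deterministic given the seed.
#'
#' @param spec an [oscillator_network_spec()]
#' @param duration_s recording duration in seconds
#' @param fs sampling rate in Hz
#' @param seed integer seed
#' @param subject_id,group metadata stored on the result
#' @return a [source_ts()]
#' @export
simulate_subject <- function(spec, duration_s, fs, seed = 1L,
                             subject_id = "S01", group = NA_character_) {
  stopifnot(inherits(spec, "oscillator_network_spec"))
  if (duration_s <= 0 || fs <= 0)
    abort_invalid("duration and sampling rate must be positive")
  n_samples <- as.integer(round(duration_s * fs))
  n <- spec$n_regions
  set.seed(seed)
  x <- matrix(0, n, n_samples)
  dt <- 1 / fs
  for (bn in names(spec$band_center_hz)) {
    e <- spec$coupling_edges[spec$coupling_edges$band == bn, , drop = FALSE]
    omega <- 2 * pi * (spec$band_center_hz[[bn]] +
                         runif(n, -spec$detuning_hz, spec$detuning_hz))
    theta0 <- runif(n, -pi, pi)
    theta <- sim_phase_oscillators_cpp(
      n, n_samples, dt, omega,
      as.integer(e$i) - 1L, as.integer(e$j) - 1L,
      e$strength * spec$coupling_scale, e$lag,
      spec$freq_noise_sd, theta0)
    x <- x + sin(theta)
  }
  if (spec$noise_sd > 0)
    x <- x + matrix(rnorm(n * n_samples, 0, spec$noise_sd), n, n_samples)
  source_ts(x, fs, default_region_labels(n), subject_id, group)
}

#' Simulate a two-group cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed, so
#' the whole cohort is reproducible bit-for-bit.
#'
#' @param net_a,net_b [oscillator_network_spec()] for groups A and B; must
#'   share `n_regions` and band structure
#' @param cohort a [cohort_spec()]
#' @return list of class `cohort_dataset`: `subjects` (list of [source_ts()])
#'   and `manifest` (data.frame subject_id, group, fs, n_samples, seed)
#' @export
simulate_cohort <- function(net_a, net_b, cohort) {
  plan <- cohort_plan(net_a, net_b, cohort)
  subjects <- lapply(seq_len(plan$n_total), plan$simulate)
  names(subjects) <- plan$ids
  structure(list(
    subjects = subjects,
    manifest = data.frame(subject_id = plan$ids, group = plan$groups,
                          fs = cohort$sampling_rate_hz,
                          n_samples = as.integer(round(cohort$recording_duration_s *
                                                         cohort$sampling_rate_hz)),
                          seed = plan$seeds)),
    class = "cohort_dataset")
}

#' Deterministic per-subject simulation plan for a two-group cohort
#'
#' Validates the network pair, derives the per-subject seeds and returns a
#' closure that materializes any single subject on demand — the building
#' block for both [simulate_cohort()] (eager) and the streaming path of
#' [run_pipeline()], which never holds more than one subject's signals in
#' memory.
#'
#' @inheritParams simulate_cohort
#' @return list with `ids`, `groups`, `seeds`, `n_total` and
#'   `simulate(s)` returning subject `s` as a [source_ts()]
#' @export
cohort_plan <- function(net_a, net_b, cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (net_a$n_regions != net_b$n_regions)
    abort_invalid("group networks must share n_regions")
  if (!identical(names(net_a$band_center_hz), names(net_b$band_center_hz)))
    abort_invalid("group networks must share the band structure")
  n_tot <- cohort$n_group_a + cohort$n_group_b
  seeds <- derive_seeds(cohort$seed, n_tot)
  ids <- c(sprintf("A%02d", seq_len(cohort$n_group_a)),
           sprintf("B%02d", seq_len(cohort$n_group_b)))
  groups <- rep(c("A", "B"), c(cohort$n_group_a, cohort$n_group_b))
  list(ids = ids, groups = groups, seeds = seeds, n_total = n_tot,
       simulate = function(s) {
         net <- if (groups[s] == "A") net_a else net_b
         simulate_subject(net, cohort$recording_duration_s,
                          cohort$sampling_rate_hz, seeds[s], ids[s], groups[s])
       })
}
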