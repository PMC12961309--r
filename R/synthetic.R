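#' Synthetic fixture specification
#'
#' Describes the synthetic inputs that stand in for the empirical data
#' of a TMS-EEG study: a 200-region connectome, a 62-channel lead
#' field, five stimulated left-hemispheric regions, and a target TEP
#' with deflections at the canonical N45/P60/N100/P185 latencies.
#'
#' @param n_regions Number of regions (default 200).
#' @param n_channels Number of EEG channels (default 62).
#' @param n_stim_regions Number of stimulated regions (default 5).
#' @param seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @param tep_peaks Data frame with columns `latency_ms`, `sign`,
#'   `amplitude_uv`, `width_ms`; defaults to the four canonical peaks
#'   with alternating signs.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_regions = 200, n_channels = 62,
                         n_stim_regions = 5, seed = 1L,
                         tep_peaks = default_tep_peaks()) {
  if (n_stim_regions > n_regions)
    stop("n_stim_regions cannot exceed n_regions", call. = FALSE)
  if (is.unsorted(tep_peaks$latency_ms, strictly = TRUE))
    stop("tep peak latencies must be strictly increasing",
         call. = FALSE)
  structure(list(n_regions = n_regions, n_channels = n_channels,
                 n_stim_regions = n_stim_regions,
                 seed = as.integer(seed), tep_peaks = tep_peaks),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_tep_peaks <- function() {
  data.frame(
    name = c("N45", "P60", "N100", "P185"),
    latency_ms = c(45, 60, 100, 185),
    sign = c(-1, 1, -1, 1),
    amplitude_uv = c(6, 7, 8, 5),
    width_ms = c(7, 9, 18, 30))
}

# region coordinates: uniform in a sphere of the given diameter (mm),
# centred at the origin; first half of the regions get x < 0 ("left")
synth_coords <- function(n, seed, diameter = 140) {
  set.seed(as.integer(seed))
  r <- diameter / 2
  pts <- matrix(NA_real_, n, 3)
  filled <- 0L
  while (filled < n) {
    cand <- matrix(stats::runif(3 * (n - filled) * 2, -r, r), ncol = 3)
    keep <- rowSums(cand^2) <= r^2
    cand <- cand[keep, , drop = FALSE]
    take <- min(nrow(cand), n - filled)
    if (take > 0) {
      pts[(filled + 1):(filled + take), ] <- cand[seq_len(take), ]
      filled <- filled + take
    }
  }
  # sort by x so hemispheres are contiguous index blocks
  pts[order(pts[, 1]), , drop = FALSE]
}

#' Generate a synthetic structural connectome
#'
#' Weights combine a log-normal magnitude distribution with an
#' exponential decay in inter-region distance, the two features of
#' empirical streamline-count connectomes that matter for delay-coupled
#' dynamics: heavy-tailed coupling and distance-dependent sparsity.
#' Distances are Euclidean between random region coordinates in a
#' 140 mm-diameter sphere. The matrix is exactly symmetric with a zero
#' diagonal and deterministic per seed; region coordinates are attached
#' as attribute `"coords"`.
#'
#' @param n Number of regions (>= 2).
#' @param seed Integer seed.
#' @param decay_mm Distance-decay length scale (mm).
#' @return A `connectome`.
#' @export
synth_connectome <- function(n, seed = 1L, decay_mm = 40) {
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  coords <- synth_coords(n, seed)
  dist <- as.matrix(stats::dist(coords))
  dimnames(dist) <- NULL
  set.seed(as.integer(seed) + 1L)
  lognorm <- matrix(stats::rlnorm(n * n, meanlog = 0, sdlog = 1), n, n)
  w <- lognorm * exp(-dist / decay_mm)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  conn <- connectome(w, dist)
  attr(conn, "coords") <- coords
  conn
}

#' Generate a synthetic EEG lead field
#'
#' Places electrodes on the upper hemisphere of a scalp sphere
#' (radius 10 mm beyond the source sphere) via a Fibonacci lattice and
#' assigns each region a randomly oriented unit dipole; the gain is the
#' dipole moment projected on the source-to-electrode direction with
#' inverse-square falloff, scaled so typical entries are order one.
#'
#' @param channels Number of electrodes.
#' @param regions Number of source regions.
#' @param seed Integer seed.
#' @param coords Optional region coordinates (from
#'   [synth_connectome()]); generated from `seed` when missing.
#' @return A [lead_field()].
#' @export
synth_leadfield <- function(channels, regions, seed = 1L,
                            coords = NULL) {
  if (channels < 1 || regions < 1)
    stop("channels and regions must be >= 1", call. = FALSE)
  if (is.null(coords)) coords <- synth_coords(regions, seed)
  if (nrow(coords) != regions)
    stop("coords must have one row per region", call. = FALSE)
  scalp_r <- 80
  i <- seq_len(channels)
  golden <- pi * (3 - sqrt(5))
  z <- 0.05 + 0.95 * (i - 0.5) / channels  # upper hemisphere
  rho <- sqrt(1 - z^2)
  elec <- scalp_r * cbind(rho * cos(golden * i), rho * sin(golden * i),
                          z)
  set.seed(as.integer(seed) + 2L)
  dip <- matrix(stats::rnorm(3 * regions), regions, 3)
  dip <- dip / sqrt(rowSums(dip^2))
  gain <- matrix(0, channels, regions)
  for (ch in seq_len(channels)) {
    d <- sweep(coords, 2L, elec[ch, ], function(a, b) b - a)
    r2 <- rowSums(d^2)
    u <- d / sqrt(r2)
    gain[ch, ] <- rowSums(dip * u) / r2
  }
  gain <- gain / stats::sd(gain) * 0.5
  lead_field(gain, sprintf("ch_%02d", seq_len(channels)))
}

#' Generate a synthetic stimulus weight map
#'
#' Exactly the listed regions receive a nonzero amplitude; amplitudes
#' fall off as a Gaussian of the rank distance from the first (focal)
#' region, emulating the decaying TMS electric field around the coil
#' focus.
#'
#' @param n Number of regions.
#' @param stim_indices Indices of stimulated regions (first = focal).
#' @param amplitude Focal amplitude (model-input units, 1/s).
#' @return A [stimulus_spec()].
#' @export
synth_stimulus <- function(n, stim_indices, amplitude = 500) {
  if (anyDuplicated(stim_indices))
    stop("duplicate stimulus indices", call. = FALSE)
  if (length(stim_indices) > 0 &&
      (max(stim_indices) > n || min(stim_indices) < 1))
    stop("stimulus indices out of range", call. = FALSE)
  amp <- rep(0, n)
  if (length(stim_indices) > 0) {
    falloff <- exp(-(seq_along(stim_indices) - 1)^2 /
                     (2 * (length(stim_indices) / 2)^2))
    amp[stim_indices] <- amplitude * falloff
  }
  stimulus_spec(amp)
}

#' Generate a synthetic target TEP
#'
#' Builds the target in source space — Gaussian-windowed deflections at
#' the specified latencies with alternating signs, each carried by a
#' small set of regions around the stimulation site — then projects it
#' through the lead field and adds seeded channel noise. Building in
#' source space keeps the SC-fitting problem well posed: the target is
#' reachable by a source configuration the forward model can express.
#' Amplitudes are scaled so channel-space peaks are in the +-5-10 uV
#' range typical of TEPs.
#'
#' @param spec A [fixture_spec()].
#' @param lf A [lead_field()] with `spec$n_regions` columns.
#' @param stim_indices Regions carrying the earliest component;
#'   successive components spread to neighbouring index blocks.
#' @param channel_noise_uv Standard deviation of additive channel noise
#'   (uV).
#' @return An [eeg_timeseries()], epoch -0.1 to 0.4 s at 1 kHz.
#' @export
synth_target_tep <- function(spec, lf, stim_indices = NULL,
                             channel_noise_uv = 0.1) {
  n <- spec$n_regions
  if (ncol(lf$gain) != n)
    stop("lead field does not match spec$n_regions", call. = FALSE)
  if (is.null(stim_indices))
    stim_indices <- seq_len(spec$n_stim_regions)
  time <- seq(-0.1, 0.4, by = 1e-3)
  src <- matrix(0, n, length(time))
  peaks <- spec$tep_peaks
  set.seed(spec$seed + 3L)
  for (i in seq_len(nrow(peaks))) {
    # later components recruit wider rings around the focal block
    width_regions <- length(stim_indices) * i * 2L
    lo <- max(1L, min(stim_indices))
    regions <- unique(pmin(n, seq(lo, lo + width_regions)))
    spat <- exp(-(seq_along(regions) - 1)^2 /
                  (2 * (width_regions / 2)^2))
    env <- peaks$sign[i] *
      exp(-(time * 1000 - peaks$latency_ms[i])^2 /
            (2 * peaks$width_ms[i]^2))
    src[regions, ] <- src[regions, ] +
      peaks$amplitude_uv[i] * spat %o% env
  }
  data <- lf$gain %*% src
  # scale so the largest channel deflection matches the largest
  # requested peak amplitude
  mx <- max(abs(data))
  if (mx > 0) data <- data * max(peaks$amplitude_uv) / mx
  if (channel_noise_uv > 0)
    data <- data + matrix(stats::rnorm(length(data), 0,
                                       channel_noise_uv),
                          nrow(data), ncol(data))
  eeg_timeseries(time, data, lf$channel_names)
}

#' Generate a complete, mutually consistent input bundle
#'
#' Creates connectome, lead field, stimulus map and target TEP from one
#' spec, optionally writing everything to a directory as plain-text
#' files. Two presets are provided: `"test"` (20 regions, 16 channels;
#' builds in seconds, for unit tests) and `"paper"` (200 regions, 62
#' channels, the reference configuration).
#'
#' @param spec A [fixture_spec()]; ignored when `preset` is given.
#' @param preset `"custom"`, `"test"` or `"paper"`.
#' @param dir Optional output directory.
#' @param seed Seed used when a preset constructs its own spec.
#' @return A `fixture` bundle: list with `spec`, `connectome`,
#'   `lead_field`, `stimulus`, `target`, `stim_indices`.
#' @export
make_fixture <- function(spec = fixture_spec(),
                         preset = c("custom", "test", "paper"),
                         dir = NULL, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "test")
    spec <- fixture_spec(n_regions = 20, n_channels = 16,
                         n_stim_regions = 3, seed = seed)
  if (preset == "paper")
    spec <- fixture_spec(seed = seed)

  conn <- synth_connectome(spec$n_regions, spec$seed)
  conn <- normalize_weights(conn, "log_scaled")
  # regional coupling-strength heterogeneity: empirical (and optimized
  # per-subject) connectomes have hub regions whose total coupling far
  # exceeds the median; a log-normal strength factor per region
  # emulates this and spreads regional operating points
  set.seed(spec$seed + 4L)
  hub <- stats::rlnorm(spec$n_regions, 0, 0.4)
  conn$weights <- outer(hub, hub) * conn$weights
  # scale so the mean total input weight per region is 1: the summed
  # delayed PSP input then lives on the scale of a single region's PSP
  conn$weights <- conn$weights / mean(rowSums(conn$weights))
  lf <- synth_leadfield(spec$n_channels, spec$n_regions, spec$seed,
                        coords = attr(conn, "coords"))
  # stimulate adjacent regions in the left (x < 0) hemisphere,
  # emulating an M1 coil position
  stim_indices <- seq_len(spec$n_stim_regions) +
    max(0L, spec$n_regions %/% 4L - spec$n_stim_regions %/% 2L)
  stim <- synth_stimulus(spec$n_regions, stim_indices,
                         amplitude = 4000)
  target <- synth_target_tep(spec, lf, stim_indices)

  bundle <- structure(
    list(spec = spec, connectome = conn, lead_field = lf,
         stimulus = stim, target = target,
         stim_indices = stim_indices),
    class = "fixture")
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

#' Write / read a fixture bundle as plain-text files
#'
#' @param bundle A `fixture` from [make_fixture()].
#' @param dir Directory (created if missing).
#' @return The bundle (writer) or a partial bundle (reader: connectome,
#'   lead field, stimulus amplitudes, target epoch).
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_connectome(bundle$connectome,
                   file.path(dir, "weights.tsv"),
                   file.path(dir, "distances.tsv"),
                   file.path(dir, "labels.txt"))
  utils::write.table(bundle$lead_field$gain,
                     file.path(dir, "leadfield.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  writeLines(bundle$lead_field$channel_names,
             file.path(dir, "channels.txt"))
  utils::write.table(
    data.frame(region = seq_along(bundle$stimulus$region_amplitudes),
               amplitude = bundle$stimulus$region_amplitudes),
    file.path(dir, "stimulus.tsv"), row.names = FALSE, sep = "\t")
  write_eeg_csv(bundle$target, file.path(dir, "target_tep.csv"))
  invisible(bundle)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  conn <- read_connectome(file.path(dir, "weights.tsv"),
                          file.path(dir, "distances.tsv"),
                          file.path(dir, "labels.txt"))
  gain <- read_matrix_file(file.path(dir, "leadfield.tsv"))
  channels <- readLines(file.path(dir, "channels.txt"))
  stim_df <- utils::read.table(file.path(dir, "stimulus.tsv"),
                               header = TRUE)
  list(connectome = conn,
       lead_field = lead_field(gain, channels),
       stimulus = stimulus_spec(stim_df$amplitude),
       target = read_eeg_csv(file.path(dir, "target_tep.csv")))
}
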