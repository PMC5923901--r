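#' Acquisition patterns: per-readout echo times and flip angles
#'
#' Container for the TE and flip-angle trains that generate contrast variation
#' along the fingerprint, plus the fixed duration of one readout module
#' (excitation, fat-suppression dead time, EPI train and spoiling).
#'
#' @param te_ms Numeric vector of echo times in ms, all positive.
#' @param flip_deg Numeric vector of nominal flip angles in degrees, same
#'   length as `te_ms`, all non-negative.
#' @param readout_overhead_ms Duration of one readout module in ms; must be at
#'   least `max(te_ms)` so the echo fits inside the module.
#' @return An object of class `mrf_patterns`.
#' @seealso [default_patterns()], [interpolate_patterns()]
#' @export
acquisition_patterns <- function(te_ms, flip_deg, readout_overhead_ms = 80) {
  te_ms <- as.numeric(te_ms)
  flip_deg <- as.numeric(flip_deg)
  if (length(te_ms) < 1L || length(te_ms) != length(flip_deg)) {
    mrf_stop("mrfepi_invalid_argument",
             "`te_ms` and `flip_deg` must have equal length >= 1")
  }
  if (any(!is.finite(te_ms)) || any(te_ms <= 0)) {
    mrf_stop("mrfepi_invalid_argument", "all `te_ms` must be positive")
  }
  if (any(!is.finite(flip_deg)) || any(flip_deg < 0)) {
    mrf_stop("mrfepi_invalid_argument", "all `flip_deg` must be >= 0")
  }
  readout_overhead_ms <- check_positive(readout_overhead_ms, "readout_overhead_ms")
  if (readout_overhead_ms < max(te_ms)) {
    mrf_stop("mrfepi_invalid_argument",
             "`readout_overhead_ms` (%.2f) must be >= max(te_ms) (%.2f)",
             readout_overhead_ms, max(te_ms))
  }
  structure(list(te_ms = te_ms, flip_deg = flip_deg,
                 readout_overhead_ms = readout_overhead_ms),
            class = "mrf_patterns")
}

#' Default 160-point TE / flip-angle trains
#'
#' The exact trains used on the scanner are a protocol input; this default
#' respects the published operating ranges (TE 17--78 ms, flip angle 4--58
#' degrees): flip angles form smooth sinusoidal lobes between 4 and 58 degrees
#' and echo times are drawn pseudo-randomly and uniformly from 17--78 ms with a
#' fixed internal seed, so the default is fully reproducible.
#'
#' @param n Number of readouts in the base pattern (default 160, the baseline
#'   image count of the single-slice protocol).
#' @param readout_overhead_ms Readout module duration in ms (default 80, the
#'   shortest repetition time of the published protocol).
#' @return An `mrf_patterns` object of length `n`.
#' @export
default_patterns <- function(n = 160, readout_overhead_ms = 80) {
  n <- check_count(n, "n")
  x <- seq(0, 1, length.out = n)
  flip <- 4 + 54 * abs(sin(4 * pi * x))
  te <- withr::with_seed(42L, runif(n, min = 17, max = 78))
  acquisition_patterns(te, flip, readout_overhead_ms)
}

#' Interpolate TE / flip-angle patterns to a new length
#'
#' When fewer baseline images are acquired per slice, the TE and flip-angle
#' trains are interpolated (piecewise linearly over the normalized readout
#' index 0..1) to the requested number of readouts, preserving the endpoints.
#'
#' @param base An `mrf_patterns` object.
#' @param n_out Desired number of readouts (>= 1). With `n_out = 1` the first
#'   pattern value is kept.
#' @return An `mrf_patterns` object of length `n_out`.
#' @export
interpolate_patterns <- function(base, n_out) {
  stopifnot(inherits(base, "mrf_patterns"))
  n_out <- check_count(n_out, "n_out")
  n_in <- length(base$te_ms)
  if (n_out == n_in) return(base)
  if (n_in == 1L) {
    return(acquisition_patterns(rep(base$te_ms, n_out), rep(base$flip_deg, n_out),
                                base$readout_overhead_ms))
  }
  x_in <- seq(0, 1, length.out = n_in)
  x_out <- seq(0, 1, length.out = n_out)
  acquisition_patterns(
    approx(x_in, base$te_ms, xout = x_out)$y,
    approx(x_in, base$flip_deg, xout = x_out)$y,
    base$readout_overhead_ms
  )
}

#' Uniform event start times filling a group duration
#'
#' Distributes `n_events` readout modules uniformly over the group duration,
#' i.e. the repetition time is maximized under the scan-time budget. Events end
#' on the uniform grid `i * spacing` (so the last module ends exactly at the
#' group duration) and each start time is the module end minus the readout
#' overhead; start times are measured from the global inversion pulse.
#'
#' @param n_events Number of readout events (>= 1).
#' @param group_duration_ms Total group acquisition time in ms.
#' @param overhead_ms Duration of one readout module in ms.
#' @return Numeric vector of strictly increasing event start times (ms).
#' @export
allocate_event_times <- function(n_events, group_duration_ms, overhead_ms) {
  n_events <- check_count(n_events, "n_events")
  group_duration_ms <- check_positive(group_duration_ms, "group_duration_ms")
  overhead_ms <- check_positive(overhead_ms, "overhead_ms")
  if (n_events * overhead_ms > group_duration_ms) {
    mrf_stop("mrfepi_infeasible_schedule",
             "%d events of %.2f ms do not fit in %.2f ms; minimum achievable duration is %.2f ms",
             n_events, overhead_ms, group_duration_ms, n_events * overhead_ms)
  }
  spacing <- group_duration_ms / n_events
  seq_len(n_events) * spacing - overhead_ms
}

#' Block-wise randomized slice ordering
#'
#' Draws `n_blocks` independent uniform permutations of the slice indices and
#' concatenates them, so every consecutive block of `n_slices` events acquires
#' each slice exactly once while the within-block order is pseudo-random. This
#' keeps the early inversion-recovery sampling comparable across slices while
#' producing dissimilar effective-TR patterns.
#'
#' @param n_slices Number of slices in the group.
#' @param n_blocks Number of blocks (readouts per slice).
#' @param seed Integer randomization seed; the result is a pure function of
#'   `(n_slices, n_blocks, seed)`.
#' @return Integer vector of length `n_slices * n_blocks` with 1-based slice
#'   indices.
#' @export
randomize_slice_order <- function(n_slices, n_blocks, seed) {
  n_slices <- check_count(n_slices, "n_slices")
  n_blocks <- check_count(n_blocks, "n_blocks")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  withr::with_seed(seed, {
    as.vector(vapply(seq_len(n_blocks),
                     function(b) sample.int(n_slices),
                     integer(n_slices)))
  })
}

#' Build one interleaved slice-group schedule
#'
#' Lays out `n_slices * images_per_slice` readout modules uniformly over the
#' group duration, assigns slices to events by block-wise randomization (or a
#' fixed sequential order) and derives one [slice timeline][SliceTimeline] per
#' slice. The j-th readout of every slice carries the j-th interpolated TE and
#' flip angle, so all slices see the same contrast train but different
#' effective repetition times.
#'
#' @param patterns `mrf_patterns` base trains; interpolated to
#'   `images_per_slice` readouts.
#' @param n_slices Slices acquired in the group (default 4).
#' @param images_per_slice Baseline images per slice (default 40).
#' @param group_duration_ms Group acquisition time in ms (default 17000).
#' @param seed Randomization seed for the slice ordering.
#' @param ordering `"randomized"` (block-wise permutations) or `"sequential"`
#'   (slice 1..n in every block; the comparison scheme).
#' @return An object of class `mrf_group_schedule` with fields `n_slices`,
#'   `slice_sequence`, `event_start_ms`, `group_duration_ms`, `seed`,
#'   `ordering` and `timelines` (a list of `mrf_slice_timeline`).
#' @name SliceTimeline
#' @aliases build_group_schedule
#' @export
build_group_schedule <- function(patterns, n_slices = 4, images_per_slice = 40,
                                 group_duration_ms = 17000, seed = 1L,
                                 ordering = c("randomized", "sequential")) {
  stopifnot(inherits(patterns, "mrf_patterns"))
  ordering <- match.arg(ordering)
  n_slices <- check_count(n_slices, "n_slices")
  images_per_slice <- check_count(images_per_slice, "images_per_slice")
  pat <- interpolate_patterns(patterns, images_per_slice)
  n_events <- n_slices * images_per_slice
  starts <- allocate_event_times(n_events, group_duration_ms,
                                 patterns$readout_overhead_ms)
  slice_seq <- if (ordering == "randomized") {
    randomize_slice_order(n_slices, images_per_slice, seed)
  } else {
    rep(seq_len(n_slices), images_per_slice)
  }
  timelines <- lapply(seq_len(n_slices), function(s) {
    idx <- which(slice_seq == s)
    times <- starts[idx]
    structure(list(
      slice_index = s,
      readout_times_ms = times,
      te_ms = pat$te_ms,
      flip_deg = pat$flip_deg,
      effective_tr_ms = diff(times),
      timeline_id = sprintf("g%dx%d-d%g-%s-seed%d-s%d", n_slices,
                            images_per_slice, group_duration_ms, ordering, seed, s)
    ), class = "mrf_slice_timeline")
  })
  structure(list(
    n_slices = n_slices,
    images_per_slice = images_per_slice,
    slice_sequence = slice_seq,
    event_start_ms = starts,
    group_duration_ms = as.numeric(group_duration_ms),
    seed = seed,
    ordering = ordering,
    patterns = pat,
    timelines = timelines
  ), class = "mrf_group_schedule")
}

#' Build a whole multi-group protocol
#'
#' Splits `n_total_slices` into consecutive groups of `slices_per_group`, each
#' preceded by its own global inversion pulse and followed by a recovery pause
#' that restores full longitudinal magnetization before the next inversion.
#' Each group draws its own slice ordering from `seed + group - 1`.
#'
#' @param n_total_slices Total slice count; must be divisible by
#'   `slices_per_group`.
#' @param slices_per_group Slices per interleaved group (default 4).
#' @param group_duration_ms Acquisition time per group in ms (default 17000).
#' @param pause_ms Recovery pause per group in ms (default 10000).
#' @param patterns `mrf_patterns` base trains (default [default_patterns()]).
#' @param images_per_slice Baseline images per slice (default 40).
#' @param seed Base randomization seed.
#' @param ordering Slice-ordering scheme, see [build_group_schedule()].
#' @return An object of class `mrf_protocol` with fields `groups`, `pause_ms`,
#'   `total_duration_ms`, `n_total_slices`, `slices_per_group`.
#' @export
build_protocol <- function(n_total_slices, slices_per_group = 4,
                           group_duration_ms = 17000, pause_ms = 10000,
                           patterns = default_patterns(),
                           images_per_slice = 40, seed = 1L,
                           ordering = "randomized") {
  n_total_slices <- check_count(n_total_slices, "n_total_slices")
  slices_per_group <- check_count(slices_per_group, "slices_per_group")
  pause_ms <- check_positive(pause_ms, "pause_ms", strict = FALSE)
  if (n_total_slices %% slices_per_group != 0L) {
    mrf_stop("mrfepi_invalid_argument",
             "`n_total_slices` (%d) must be divisible by `slices_per_group` (%d)",
             n_total_slices, slices_per_group)
  }
  n_groups <- n_total_slices %/% slices_per_group
  groups <- lapply(seq_len(n_groups), function(g) {
    build_group_schedule(patterns, slices_per_group, images_per_slice,
                         group_duration_ms, seed = seed + g - 1L,
                         ordering = ordering)
  })
  structure(list(
    groups = groups,
    pause_ms = pause_ms,
    total_duration_ms = n_groups * (as.numeric(group_duration_ms) + pause_ms),
    n_total_slices = n_total_slices,
    slices_per_group = slices_per_group,
    seed = seed
  ), class = "mrf_protocol")
}

#' Timeline of one global slice within a protocol
#'
#' @param protocol An `mrf_protocol`.
#' @param slice Global slice index (1-based).
#' @return The `mrf_slice_timeline` of that slice within its group.
#' @export
protocol_timeline <- function(protocol, slice) {
  stopifnot(inherits(protocol, "mrf_protocol"))
  slice <- check_count(slice, "slice")
  if (slice > protocol$n_total_slices) {
    mrf_stop("mrfepi_invalid_argument", "slice %d exceeds protocol slices (%d)",
             slice, protocol$n_total_slices)
  }
  g <- (slice - 1L) %/% protocol$slices_per_group + 1L
  s <- (slice - 1L) %% protocol$slices_per_group + 1L
  protocol$groups[[g]]$timelines[[s]]
}

#' @export
print.mrf_group_schedule <- function(x, ...) {
  cat(sprintf("MRF slice-group schedule: %d slices x %d images (%s order)\n",
              x$n_slices, x$images_per_slice, x$ordering))
  cat(sprintf("  group duration %.1f ms, event spacing %.2f ms, seed %d\n",
              x$group_duration_ms, x$group_duration_ms / length(x$event_start_ms),
              x$seed))
  invisible(x)
}

#' @export
print.mrf_protocol <- function(x, ...) {
  cat(sprintf("MRF protocol: %d slices in %d groups of %d, total %.1f s (%d:%02.0f min)\n",
              x$n_total_slices, length(x$groups), x$slices_per_group,
              x$total_duration_ms / 1000,
              x$total_duration_ms %/% 60000,
              (x$total_duration_ms %% 60000) / 1000))
  invisible(x)
}
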