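#' Read a protocol configuration file
#'
#' YAML or JSON with keys `n_slices`, `slices_per_group`, `images_per_slice`,
#' `group_duration_ms`, `pause_ms`, `seed` and optionally `patterns` (a map
#' with `te_ms`, `flip_deg`, `readout_overhead_ms`; defaults to
#' [default_patterns()] when absent).
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` vs
#'   `.json`).
#' @return The configuration as a named list.
#' @export
read_protocol_config <- function(path) {
  if (!file.exists(path)) {
    mrf_stop("mrfepi_invalid_argument", "config file `%s` does not exist", path)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Build a protocol from a configuration list
#'
#' @param config Named list as returned by [read_protocol_config()].
#' @return An `mrf_protocol`.
#' @export
protocol_from_config <- function(config) {
  pats <- if (!is.null(config$patterns)) {
    acquisition_patterns(config$patterns$te_ms, config$patterns$flip_deg,
                         config$patterns$readout_overhead_ms %||% 80)
  } else {
    default_patterns()
  }
  build_protocol(
    n_total_slices = config$n_slices,
    slices_per_group = config$slices_per_group %||% 4,
    group_duration_ms = config$group_duration_ms %||% 17000,
    pause_ms = config$pause_ms %||% 10000,
    patterns = pats,
    images_per_slice = config$images_per_slice %||% 40,
    seed = config$seed %||% 1L
  )
}

#' Export a schedule as JSON
#'
#' Writes the event list of every group (global slice index, start time, TE,
#' flip angle) plus protocol-level timing.
#'
#' @param protocol An `mrf_protocol`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "mrf_protocol"))
  groups <- lapply(seq_along(protocol$groups), function(g) {
    grp <- protocol$groups[[g]]
    counter <- integer(grp$n_slices)
    te <- flip <- numeric(length(grp$slice_sequence))
    for (i in seq_along(grp$slice_sequence)) {
      s <- grp$slice_sequence[i]
      counter[s] <- counter[s] + 1L
      te[i] <- grp$patterns$te_ms[counter[s]]
      flip[i] <- grp$patterns$flip_deg[counter[s]]
    }
    list(group = g, seed = grp$seed, ordering = grp$ordering,
         events = data.frame(
           slice = (g - 1L) * grp$n_slices + grp$slice_sequence,
           start_ms = grp$event_start_ms,
           te_ms = te, flip_deg = flip))
  })
  jsonlite::write_json(list(
    n_total_slices = protocol$n_total_slices,
    slices_per_group = protocol$slices_per_group,
    pause_ms = protocol$pause_ms,
    total_duration_ms = protocol$total_duration_ms,
    groups = groups
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Export per-slice timelines as CSV
#'
#' One row per readout: slice, readout index, start time, TE, flip angle and
#' effective TR (NA for the first readout of a slice).
#'
#' @param group An `mrf_group_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timelines_csv <- function(group, path) {
  stopifnot(inherits(group, "mrf_group_schedule"))
  rows <- do.call(rbind, lapply(group$timelines, function(tl) {
    n <- length(tl$readout_times_ms)
    data.frame(slice = tl$slice_index, readout = seq_len(n),
               start_ms = tl$readout_times_ms, te_ms = tl$te_ms,
               flip_deg = tl$flip_deg,
               effective_tr_ms = c(NA, tl$effective_tr_ms))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a 4D NIfTI volume as a baseline series
#'
#' Accepts a 3D+time (rows x cols x 1 x n) or rows x cols x n volume and
#' returns the series for a single slice.
#'
#' @param path NIfTI file path.
#' @param timeline_id Timeline identifier of the matching schedule.
#' @param mask Optional logical mask image.
#' @return An `mrf_baseline_series`.
#' @export
read_series_nifti <- function(path, timeline_id, mask = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  a <- array(as.numeric(a), dim = dim(a))   # drop NIfTI header attributes
  if (length(dim(a)) == 4L) {
    if (dim(a)[3] != 1L) {
      mrf_stop("mrfepi_invalid_argument",
               "expected a single-slice 4D volume; got %d slices", dim(a)[3])
    }
    a <- array(a, dim = dim(a)[c(1, 2, 4)])
  }
  if (length(dim(a)) != 3L) {
    mrf_stop("mrfepi_invalid_argument", "`%s` is not a 3D/4D volume", path)
  }
  baseline_series(a, timeline_id, mask = mask)
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes one float NIfTI per available map (`t1_ms`, `t2star_ms`,
#' `b1_scale`, `m0`, `score`, `pd_pu`) named `<prefix>_<map>.nii.gz`.
#'
#' @param maps An `mrf_maps`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"maps"`).
#' @param voxel_mm In-plane voxel size stored in the header (default 1).
#' @return Character vector of written paths, invisibly.
#' @export
write_maps_nifti <- function(maps, dir, prefix = "maps", voxel_mm = 1) {
  stopifnot(inherits(maps, "mrf_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  for (p in c("t1_ms", "t2star_ms", "b1_scale", "m0", "score", "pd_pu")) {
    if (is.null(maps[[p]])) next
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, p))
    img <- RNifti::asNifti(maps[[p]], datatype = "float",
                           pixdim = c(voxel_mm, voxel_mm))
    RNifti::writeNifti(img, path)
    written <- c(written, path)
  }
  invisible(written)
}
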