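#' Smooth low-order harmonic field
#'
#' Generates a smooth field from a random low-order polynomial/harmonic basis
#' and rescales it linearly to the requested range. Used for B1+ and
#' coil-sensitivity fields.
#'
#' @noRd
.smooth_field <- function(nr, nc, range, seed) {
  x <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  y <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  basis <- list(x, y, x * y, x^2 - y^2, cos(pi * x / 2), cos(pi * y / 2))
  f <- withr::with_seed(seed, {
    w <- rnorm(length(basis))
    Reduce(`+`, Map(`*`, basis, w))
  })
  lo <- min(f); hi <- max(f)
  if (hi - lo < 1e-12) return(matrix(mean(range), nr, nc))
  range[1] + (f - lo) / (hi - lo) * (range[2] - range[1])
}

#' Digital brain phantom
#'
#' Concentric 2D-per-slice geometry: a grey-matter outer ring enclosing white
#' matter, with two ellipsoidal CSF "ventricles" in the centre and an optional
#' white-matter lesion. Tissue defaults are representative in-vivo values
#' (T1 ms / T2* ms / PD pu): WM 746/57/72, GM 1200/53/92, lesion 1285/95/62;
#' CSF is set to 4000/200/100 (full water), inside the dictionary grid bounds.
#' Smooth B1+ (range 0.8--1.2) and coil-sensitivity fields are generated from
#' low-order harmonics.
#'
#' @param shape Image dimensions `c(rows, cols)`, each >= 16.
#' @param n_slices Number of (independent, identical-geometry) slices.
#' @param seed RNG seed for the fields.
#' @param lesion Include the lesion compartment (default `TRUE`).
#' @param noise_sigma Additive noise level for rendering, as a fraction of the
#'   mean rendered tissue signal (default 0.01).
#' @param fov_mm In-plane field of view in mm (default 220); fixes the voxel
#'   size `fov_mm / shape[1]` used by bias-field estimation.
#' @return An object of class `mrf_phantom`: `labels` (`rows x cols x
#'   n_slices`; 0 = background, 1 = WM, 2 = GM, 3 = CSF, 4 = lesion),
#'   `tissue_table` (per-label `t1_ms`, `t2star_ms`, `pd_pu`), `b1_field`,
#'   `sens_field`, `noise_sigma`, `voxel_mm`, `seed`.
#' @export
make_digital_brain <- function(shape = c(64, 64), n_slices = 4, seed = 1L,
                               lesion = TRUE, noise_sigma = 0.01,
                               fov_mm = 220) {
  if (length(shape) != 2L || any(shape < 16)) {
    mrf_stop("mrfepi_invalid_argument", "`shape` must be two dimensions >= 16")
  }
  n_slices <- check_count(n_slices, "n_slices")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  x <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  y <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  lab2d <- matrix(0L, nr, nc)
  lab2d[(x / 0.88)^2 + (y / 0.92)^2 < 1] <- 2L                # GM head
  lab2d[(x / 0.62)^2 + (y / 0.68)^2 < 1] <- 1L                # WM core
  lab2d[((x - 0.02) / 0.10)^2 + ((y + 0.22) / 0.16)^2 < 1] <- 3L  # ventricle L
  lab2d[((x - 0.02) / 0.10)^2 + ((y - 0.22) / 0.16)^2 < 1] <- 3L  # ventricle R
  if (lesion) {
    lab2d[((x + 0.32) / 0.09)^2 + ((y + 0.30) / 0.07)^2 < 1] <- 4L
  }
  labels <- array(lab2d, dim = c(nr, nc, n_slices))
  tissue_table <- data.frame(
    label = 1:4,
    name = c("WM", "GM", "CSF", "lesion"),
    t1_ms = c(746, 1200, 4000, 1285),
    t2star_ms = c(57, 53, 200, 95),
    pd_pu = c(72, 92, 100, 62)
  )
  if (!lesion) tissue_table <- tissue_table[tissue_table$label != 4L, ]
  structure(list(
    labels = labels,
    tissue_table = tissue_table,
    b1_field = array(.smooth_field(nr, nc, c(0.8, 1.2), seed), c(nr, nc, n_slices)),
    sens_field = array(.smooth_field(nr, nc, c(0.7, 1.3), seed + 1L), c(nr, nc, n_slices)),
    noise_sigma = check_positive(noise_sigma, "noise_sigma", strict = FALSE),
    voxel_mm = fov_mm / nr,
    seed = seed
  ), class = "mrf_phantom")
}

#' Agarose-vial phantom
#'
#' Disk compartments on an empty background, emulating gadolinium-doped
#' agarose vials: T1 and T2* are log-spaced across the requested ranges and
#' increase monotonically with the vial index; `t1 >= t2star` is enforced per
#' vial. All vials have PD 100 pu (water-based gel).
#'
#' @param n_vials Number of vials (default 9).
#' @param t1_range_ms T1 range in ms (default `c(300, 2000)`).
#' @param t2star_range_ms T2* range in ms (default `c(30, 150)`).
#' @param shape Image dimensions (default `c(64, 64)`).
#' @param seed RNG seed for the fields.
#' @param noise_sigma Rendering noise level (default 0.01).
#' @param fov_mm Field of view in mm (default 220).
#' @return An `mrf_phantom` with one slice; labels 1..`n_vials`.
#' @export
make_vial_phantom <- function(n_vials = 9, t1_range_ms = c(300, 2000),
                              t2star_range_ms = c(30, 150),
                              shape = c(64, 64), seed = 1L,
                              noise_sigma = 0.01, fov_mm = 220) {
  n_vials <- check_count(n_vials, "n_vials")
  if (any(t1_range_ms <= 0) || any(t2star_range_ms <= 0)) {
    mrf_stop("mrfepi_invalid_argument", "parameter ranges must be positive")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  n_side <- ceiling(sqrt(n_vials))
  radius <- 0.9 / n_side * 0.42
  if (radius * min(nr, nc) < 2) {
    mrf_stop("mrfepi_layout_error",
             "%d vials do not fit in a %d x %d image without overlap", n_vials, nr, nc)
  }
  centers <- seq(-1, 1, length.out = n_side + 2)[2:(n_side + 1)]
  x <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  y <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  lab2d <- matrix(0L, nr, nc)
  for (v in seq_len(n_vials)) {
    cx <- centers[(v - 1L) %% n_side + 1L]
    cy <- centers[(v - 1L) %/% n_side + 1L]
    lab2d[(x - cx)^2 + (y - cy)^2 < radius^2] <- v
  }
  lspace <- function(r, n) if (n == 1L) r[1] else exp(seq(log(r[1]), log(r[2]), length.out = n))
  t1 <- lspace(sort(t1_range_ms), n_vials)
  t2s <- pmin(lspace(sort(t2star_range_ms), n_vials), t1)
  structure(list(
    labels = array(lab2d, dim = c(nr, nc, 1L)),
    tissue_table = data.frame(label = seq_len(n_vials),
                              name = sprintf("vial%02d", seq_len(n_vials)),
                              t1_ms = t1, t2star_ms = t2s,
                              pd_pu = rep(100, n_vials)),
    b1_field = array(.smooth_field(nr, nc, c(0.8, 1.2), seed), c(nr, nc, 1L)),
    sens_field = array(.smooth_field(nr, nc, c(0.7, 1.3), seed + 1L), c(nr, nc, 1L)),
    noise_sigma = check_positive(noise_sigma, "noise_sigma", strict = FALSE),
    voxel_mm = fov_mm / nr,
    seed = seed
  ), class = "mrf_phantom")
}

#' Ground-truth parameter maps of one phantom slice
#'
#' @param phantom An `mrf_phantom`.
#' @param slice Slice index.
#' @return An `mrf_maps` object: the true T1/T2*/B1/M0/PD images (M0 is the
#'   product of sensitivity and fractional PD, the amplitude the matcher
#'   should recover).
#' @export
phantom_truth_maps <- function(phantom, slice = 1L) {
  stopifnot(inherits(phantom, "mrf_phantom"))
  lab <- phantom$labels[, , slice]
  mask <- lab > 0L
  tt <- phantom$tissue_table
  row <- match(lab[mask], tt$label)
  if (any(is.na(row))) {
    mrf_stop("mrfepi_invalid_argument", "labels present without a tissue_table row")
  }
  blank <- matrix(NA_real_, nrow(lab), ncol(lab))
  fill <- function(v) { m <- blank; m[mask] <- v; m }
  sens <- phantom$sens_field[, , slice]
  structure(list(
    t1_ms = fill(tt$t1_ms[row]),
    t2star_ms = fill(tt$t2star_ms[row]),
    b1_scale = fill(phantom$b1_field[, , slice][mask]),
    m0 = fill(sens[mask] * tt$pd_pu[row] / 100),
    score = fill(1),
    pd_pu = fill(tt$pd_pu[row]),
    mask = mask
  ), class = "mrf_maps")
}

#' Render baseline image series from a phantom and a protocol
#'
#' Forward model per voxel: `signal = S * (PD/100) * fingerprint(T1, T2*, B1)`
#' along the slice's timeline, where `S` is the coil-sensitivity field and the
#' fingerprint uses the local B1+ field value. Independent zero-mean Gaussian
#' noise with standard deviation `noise_sigma * mean(non-zero noiseless
#' signal)` is added to every sample and magnitudes are taken. Ground truth is
#' recorded before noise.
#'
#' @param phantom An `mrf_phantom`.
#' @param protocol An `mrf_protocol` covering at least as many slices as the
#'   phantom.
#' @param seed RNG seed for the noise.
#' @return An object of class `mrf_study`: `series` (list of
#'   `mrf_baseline_series`, one per slice), `truth` (list of `mrf_maps`),
#'   `protocol`, `phantom`, `seed`.
#' @export
render_baseline_series <- function(phantom, protocol, seed = 1L) {
  stopifnot(inherits(phantom, "mrf_phantom"), inherits(protocol, "mrf_protocol"))
  n_slices <- dim(phantom$labels)[3]
  if (protocol$n_total_slices < n_slices) {
    mrf_stop("mrfepi_invalid_argument",
             "protocol covers %d slices but phantom has %d",
             protocol$n_total_slices, n_slices)
  }
  tt <- phantom$tissue_table
  withr::with_seed(seed, {
    series <- vector("list", n_slices)
    truth <- vector("list", n_slices)
    for (s in seq_len(n_slices)) {
      tl <- protocol_timeline(protocol, s)
      lab <- phantom$labels[, , s]
      mask <- lab > 0L
      row <- match(lab[mask], tt$label)
      if (any(is.na(row))) {
        mrf_stop("mrfepi_invalid_argument", "labels present without a tissue_table row")
      }
      b1v <- phantom$b1_field[, , s][mask]
      sensv <- phantom$sens_field[, , s][mask]
      base <- .mz_signal_matrix(tl$readout_times_ms, tl$flip_deg * pi / 180,
                                t1_ms = tt$t1_ms[row], b1_scale = b1v)
      decay <- exp(-outer(1 / tt$t2star_ms[row], tl$te_ms))
      sig <- (sensv * tt$pd_pu[row] / 100) * base * decay
      n <- length(tl$readout_times_ms)
      data <- array(0, dim = c(nrow(lab), ncol(lab), n))
      flat <- matrix(0, nrow(lab) * ncol(lab), n)
      flat[mask, ] <- sig
      if (phantom$noise_sigma > 0) {
        sd_noise <- phantom$noise_sigma * mean(sig[sig > 0])
        flat <- abs(flat + matrix(rnorm(length(flat), sd = sd_noise),
                                  nrow = nrow(flat)))
      }
      data[] <- flat
      series[[s]] <- baseline_series(data, tl$timeline_id, mask = mask)
      truth[[s]] <- phantom_truth_maps(phantom, s)
    }
    structure(list(series = series, truth = truth, protocol = protocol,
                   phantom = phantom, seed = seed),
              class = "mrf_study")
  })
}

#' Compare reconstructed maps with ground truth per ROI
#'
#' For every ROI label and every available parameter, reports the mean
#' relative deviation (percent, signed) and the normalized root-mean-square
#' error (RMSE divided by the mean of the truth over the ROI, percent).
#' Empty ROIs are skipped with a warning.
#'
#' @param maps Reconstructed `mrf_maps`.
#' @param truth Ground-truth `mrf_maps`, voxel-aligned with `maps`.
#' @param rois Integer label image; 0 = not evaluated.
#' @return data.frame with columns `roi`, `parameter`, `mean_dev_pct`,
#'   `nrmse_pct`, `n_voxels`.
#' @export
evaluate_against_truth <- function(maps, truth, rois) {
  stopifnot(inherits(maps, "mrf_maps"), inherits(truth, "mrf_maps"))
  if (!identical(dim(rois), dim(maps$t1_ms))) {
    mrf_stop("mrfepi_invalid_argument", "`rois` must match the map dimensions")
  }
  params <- c("t1_ms", "t2star_ms", "b1_scale", "m0", "pd_pu")
  params <- params[vapply(params, function(p) !is.null(maps[[p]]) &&
                            !is.null(truth[[p]]), logical(1))]
  out <- list()
  for (r in sort(unique(rois[rois > 0]))) {
    sel <- rois == r & !is.na(maps$t1_ms) & !is.na(truth$t1_ms)
    if (!any(sel)) {
      warning(sprintf("ROI %d contains no evaluable voxels; skipped", r))
      next
    }
    for (p in params) {
      est <- maps[[p]][sel]; ref <- truth[[p]][sel]
      out[[length(out) + 1L]] <- data.frame(
        roi = r, parameter = p,
        mean_dev_pct = mean((est - ref) / ref) * 100,
        nrmse_pct = sqrt(mean((est - ref)^2)) / mean(ref) * 100,
        n_voxels = sum(sel)
      )
    }
  }
  do.call(rbind, out)
}

#' @export
print.mrf_phantom <- function(x, ...) {
  cat(sprintf("MRF digital phantom: %d x %d x %d, %d tissue classes, noise sigma %.3g\n",
              dim(x$labels)[1], dim(x$labels)[2], dim(x$labels)[3],
              nrow(x$tissue_table), x$noise_sigma))
  print(x$tissue_table, row.names = FALSE)
  invisible(x)
}
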