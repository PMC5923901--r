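#' Baseline image series of one slice
#'
#' @param data Numeric array `rows x cols x n_images` of non-negative
#'   magnitude images.
#' @param timeline_id Identifier of the slice timeline (TR pattern) the series
#'   was acquired or rendered with.
#' @param mask Optional logical `rows x cols` image of voxels to quantify;
#'   default: all voxels.
#' @return An object of class `mrf_baseline_series`.
#' @export
baseline_series <- function(data, timeline_id, mask = NULL) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L) {
    mrf_stop("mrfepi_invalid_argument", "`data` must be a rows x cols x n_images array")
  }
  if (any(data < 0, na.rm = TRUE)) {
    mrf_stop("mrfepi_invalid_argument", "`data` must be non-negative magnitudes")
  }
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
      mrf_stop("mrfepi_invalid_argument", "`mask` must be a logical rows x cols image")
    }
  }
  structure(list(data = data, timeline_id = as.character(timeline_id),
                 mask = mask),
            class = "mrf_baseline_series")
}

#' Reconstruct parameter maps from a baseline series
#'
#' Per-voxel dictionary matching: every voxel's magnitude trace is matched
#' against the slice's precomputed dictionary, yielding T1, T2*, B1 and M0
#' maps plus the matching score. Voxels outside the mask and voxels with an
#' all-zero trace are set to `NA`.
#'
#' @param series An `mrf_baseline_series`.
#' @param dict The `mrf_dictionary` built for the same timeline; their
#'   `timeline_id`s must agree.
#' @param chunk_size Voxels matched per matrix product (memory/speed
#'   trade-off; default 256).
#' @return An object of class `mrf_maps`: list of `rows x cols` matrices
#'   `t1_ms`, `t2star_ms`, `b1_scale`, `m0`, `score`, plus the logical `mask`
#'   of quantified voxels and `pd_pu = NULL` (filled by [normalize_pd()]).
#' @export
reconstruct_maps <- function(series, dict, chunk_size = 256L) {
  stopifnot(inherits(series, "mrf_baseline_series"), inherits(dict, "mrf_dictionary"))
  if (!identical(series$timeline_id, dict$timeline_id)) {
    mrf_stop("mrfepi_invalid_argument",
             "series timeline (%s) does not match dictionary timeline (%s)",
             series$timeline_id, dict$timeline_id)
  }
  d <- dim(series$data)
  if (d[3] != dict$n_readouts) {
    mrf_stop("mrfepi_invalid_argument",
             "series has %d images but dictionary expects %d", d[3], dict$n_readouts)
  }
  nvox <- prod(d[1:2])
  mask <- series$mask %||% matrix(TRUE, d[1], d[2])
  sig <- matrix(abs(series$data), nrow = nvox)[as.vector(mask), , drop = FALSE]
  energy <- rowSums(sig^2)
  live <- energy > 0
  idx <- rep(NA_integer_, nrow(sig))
  raw <- rep(NA_real_, nrow(sig))
  rows_live <- which(live)
  for (start in seq(1L, length.out = ceiling(length(rows_live) / chunk_size),
                    by = chunk_size)) {
    rows <- rows_live[start:min(start + chunk_size - 1L, length(rows_live))]
    scores <- dict$entries %*% t(sig[rows, , drop = FALSE])  # n_entries x n_chunk
    best <- max.col(t(scores), ties.method = "first")
    idx[rows] <- best
    raw[rows] <- scores[cbind(best, seq_along(rows))]
  }
  blank <- matrix(NA_real_, d[1], d[2])
  fill <- function(values) { m <- blank; m[mask] <- values; m }
  out_mask <- blank
  out_mask <- mask
  out_mask[mask] <- live
  structure(list(
    t1_ms = fill(dict$params$t1_ms[idx]),
    t2star_ms = fill(dict$params$t2star_ms[idx]),
    b1_scale = fill(dict$params$b1_scale[idx]),
    m0 = fill(energy / (dict$norms[idx] * raw)),
    score = fill(raw / sqrt(energy)),
    pd_pu = NULL,
    mask = out_mask
  ), class = "mrf_maps")
}

#' Estimate a multiplicative bias (coil-sensitivity) field from an M0 map
#'
#' The semi-quantitative M0 map factorizes as `C * rho * S` with `S` the
#' smooth receive-coil sensitivity. The field is estimated in the log domain
#' by mask-aware Gaussian smoothing (normalized convolution) with the given
#' full-width-at-half-maximum cutoff, then renormalized to unit geometric mean
#' inside the mask so its arbitrary scale is fixed.
#'
#' @param m0_map Numeric image, positive inside `mask`.
#' @param mask Logical image of valid voxels.
#' @param fwhm_mm Smoothness cutoff as FWHM in mm (default 60).
#' @param voxel_mm In-plane voxel size in mm (default 1).
#' @return An object of class `mrf_bias_field`: list with the positive field
#'   image `s` (`NA` outside the mask) and `fwhm_mm`.
#' @export
estimate_bias_field <- function(m0_map, mask, fwhm_mm = 60, voxel_mm = 1) {
  if (!is.logical(mask) || !identical(dim(mask), dim(m0_map))) {
    mrf_stop("mrfepi_invalid_argument", "`mask` must be a logical image matching `m0_map`")
  }
  if (!any(mask)) mrf_stop("mrfepi_invalid_argument", "`mask` is empty")
  if (any(m0_map[mask] <= 0, na.rm = TRUE) || any(is.na(m0_map[mask]))) {
    mrf_stop("mrfepi_invalid_argument", "`m0_map` must be finite and positive inside `mask`")
  }
  fwhm_mm <- check_positive(fwhm_mm, "fwhm_mm")
  voxel_mm <- check_positive(voxel_mm, "voxel_mm")
  sigma_px <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  # truncate the kernel so it never exceeds the image (small fields of view)
  radius <- min(2 * ceiling(2.5 * sigma_px) + 1,
                2 * ((min(dim(m0_map)) - 1) %/% 2) + 1)
  logm <- matrix(0, nrow(m0_map), ncol(m0_map))
  logm[mask] <- log(m0_map[mask])
  num <- EBImage::gblur(logm, sigma = sigma_px, radius = radius)
  den <- EBImage::gblur(mask * 1.0, sigma = sigma_px, radius = radius)
  sm <- matrix(NA_real_, nrow(m0_map), ncol(m0_map))
  sm[mask] <- num[mask] / den[mask]
  sm[mask] <- sm[mask] - mean(sm[mask])      # unit geometric mean
  s <- exp(sm)
  structure(list(s = s, fwhm_mm = fwhm_mm, voxel_mm = voxel_mm),
            class = "mrf_bias_field")
}

#' Proton density in percentage units via CSF normalization
#'
#' Divides the M0 map by the bias field and scales it so the mean over the
#' cerebrospinal-fluid reference region equals 100 pu. By definition 100 pu
#' corresponds to the proton density of pure water at 37 C, 110.3 mol/l.
#' Values above 100 pu are possible under noise and are reported as-is.
#'
#' @param m0_map Numeric image of semi-quantitative M0 (NA where unquantified).
#' @param bias An `mrf_bias_field` (or a positive numeric image).
#' @param csf_roi Logical image marking the CSF reference region (non-empty,
#'   inside the quantified area).
#' @return Numeric image of PD in pu, `NA` where `m0_map` is `NA`.
#' @export
normalize_pd <- function(m0_map, bias, csf_roi) {
  s <- if (inherits(bias, "mrf_bias_field")) bias$s else bias
  if (!identical(dim(s), dim(m0_map))) {
    mrf_stop("mrfepi_invalid_argument", "bias field does not match `m0_map` dimensions")
  }
  if (!is.logical(csf_roi) || !identical(dim(csf_roi), dim(m0_map)) || !any(csf_roi)) {
    mrf_stop("mrfepi_invalid_argument", "`csf_roi` must be a non-empty logical image")
  }
  corrected <- m0_map / s
  ref <- corrected[csf_roi]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0L) {
    mrf_stop("mrfepi_invalid_argument", "CSF ROI contains no quantified voxels")
  }
  C <- mean(ref) / 100
  corrected / C
}

#' Reference proton density from multi-echo GRE and measured field maps
#'
#' Phantom reference formula `rho = C * I * B1 * S / exp(-TE / T2*)`:
#' the long-TR GRE intensity is corrected for transmit field, receive
#' sensitivity and T2* echo decay, then `C` is fixed by normalizing a
#' designated full-water region to 100 pu.
#'
#' @param intensity GRE magnitude image at echo time `te_ms`.
#' @param b1_map Transmit-field scale image.
#' @param s_map Receive-sensitivity image.
#' @param te_ms Echo time in ms.
#' @param t2star_map T2* image in ms, positive.
#' @param water_roi Logical image marking the full-water reference region.
#' @return PD image in pu.
#' @export
phantom_pd_reference <- function(intensity, b1_map, s_map, te_ms, t2star_map,
                                 water_roi) {
  if (any(t2star_map <= 0, na.rm = TRUE)) {
    mrf_stop("mrfepi_invalid_argument", "`t2star_map` must be positive")
  }
  if (!is.logical(water_roi) || !any(water_roi)) {
    mrf_stop("mrfepi_invalid_argument", "`water_roi` must be a non-empty logical image")
  }
  rho <- intensity * b1_map * s_map / exp(-te_ms / t2star_map)
  C <- mean(rho[water_roi], na.rm = TRUE) / 100
  rho / C
}

#' Two-parameter magnitude inversion-recovery T1 fit
#'
#' Fits `|A * (1 - 2 * exp(-TI / T1))|` to magnitude signals over inversion
#' times by Levenberg-Marquardt least squares, with a multi-start over a
#' logarithmic T1 grid to avoid the sign ambiguity near the signal null.
#'
#' @param signals Magnitude signals, one per inversion time.
#' @param ti_ms Inversion times in ms (>= 3 values).
#' @return List with `amplitude` and `t1_ms`.
#' @export
fit_ir_t1 <- function(signals, ti_ms) {
  if (length(signals) != length(ti_ms) || length(ti_ms) < 3L) {
    mrf_stop("mrfepi_invalid_argument", "need >= 3 (signal, TI) pairs of equal length")
  }
  model <- function(A, t1) A * abs(1 - 2 * exp(-ti_ms / t1))
  best <- NULL
  for (t1_init in exp(seq(log(30), log(6000), length.out = 25))) {
    m <- abs(1 - 2 * exp(-ti_ms / t1_init))
    A_init <- sum(signals * m) / sum(m^2)
    if (!is.finite(A_init) || A_init <= 0) next
    fit <- tryCatch(
      minpack.lm::nlsLM(
        signals ~ model(A, t1),
        start = list(A = A_init, t1 = t1_init),
        lower = c(A = 0, t1 = 1), upper = c(A = Inf, t1 = 1e5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, coef = coef(fit))
    }
  }
  if (is.null(best)) {
    mrf_stop("mrfepi_fit_failure",
             "inversion-recovery T1 fit did not converge from any start")
  }
  list(amplitude = unname(best$coef["A"]), t1_ms = unname(best$coef["t1"]))
}

#' Three-parameter multi-echo T2* fit
#'
#' Fits `S0 * exp(-TE / T2*) + c` to magnitude signals over echo times,
#' initialized from a log-linear regression on offset-subtracted data.
#'
#' @param signals Magnitude signals, one per echo time.
#' @param te_ms Echo times in ms (>= 4 values).
#' @return List with `s0`, `t2star_ms`, `offset`.
#' @export
fit_gre_t2star <- function(signals, te_ms) {
  if (length(signals) != length(te_ms) || length(te_ms) < 4L) {
    mrf_stop("mrfepi_invalid_argument", "need >= 4 (signal, TE) pairs of equal length")
  }
  if (sd(signals) < 1e-12 * max(abs(signals), 1e-12)) {
    mrf_stop("mrfepi_fit_failure",
             "signals are constant; T2* is unidentifiable from this decay")
  }
  c0 <- 0.5 * min(signals)
  pos <- signals - c0 > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(signals[pos] - c0) ~ te_ms[pos])
    t2_init <- unname(-1 / coef(lf)[2])
    s0_init <- unname(exp(coef(lf)[1]))
  } else {
    t2_init <- NA_real_
  }
  if (!is.finite(t2_init) || t2_init <= 0) {
    t2_init <- diff(range(te_ms)) / 3
    s0_init <- max(signals)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signals ~ s0 * exp(-te_ms / t2) + cc,
      start = list(s0 = s0_init, t2 = t2_init, cc = c0),
      lower = c(s0 = 0, t2 = 1e-3, cc = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      mrf_stop("mrfepi_fit_failure", "T2* fit failed: %s", conditionMessage(e))
    }
  )
  cf <- coef(fit)
  list(s0 = unname(cf["s0"]), t2star_ms = unname(cf["t2"]),
       offset = unname(cf["cc"]))
}

#' Double-angle B1+ mapping
#'
#' In the long-TR regime the GRE image ratio satisfies
#' `I(2a) / (2 I(a)) = cos(a_actual)`, so the achieved flip angle is
#' `acos(ratio)` and the B1+ scale is `a_actual / a_nominal`. Ratios outside
#' `[-1, 1]` (noise) are clamped with a warning.
#'
#' @param i_alpha Image acquired at the nominal flip angle.
#' @param i_2alpha Image acquired at twice the nominal flip angle.
#' @param alpha_deg Nominal flip angle in degrees (default 45).
#' @return B1+ scale image (1 = nominal field).
#' @export
double_angle_b1 <- function(i_alpha, i_2alpha, alpha_deg = 45) {
  if (any(i_alpha <= 0, na.rm = TRUE)) {
    mrf_stop("mrfepi_invalid_argument", "`i_alpha` must be positive")
  }
  ratio <- i_2alpha / (2 * i_alpha)
  n_out <- sum(ratio < -1 | ratio > 1, na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf("double_angle_b1: %d voxel(s) with |ratio| > 1 clamped", n_out))
  }
  acos(pmin(pmax(ratio, -1), 1)) / (alpha_deg * pi / 180)
}

#' @export
print.mrf_maps <- function(x, ...) {
  n <- sum(x$mask, na.rm = TRUE)
  cat(sprintf("MRF parameter maps: %d x %d, %d quantified voxels\n",
              nrow(x$t1_ms), ncol(x$t1_ms), n))
  if (n > 0) {
    cat(sprintf("  median T1 %.0f ms, T2* %.1f ms, B1 %.2f%s\n",
                stats::median(x$t1_ms[x$mask], na.rm = TRUE),
                stats::median(x$t2star_ms[x$mask], na.rm = TRUE),
                stats::median(x$b1_scale[x$mask], na.rm = TRUE),
                if (!is.null(x$pd_pu)) sprintf(", PD %.1f pu",
                  stats::median(x$pd_pu[x$mask], na.rm = TRUE)) else ""))
  }
  invisible(x)
}
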