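#' Tissue parameters for fingerprint simulation
#'
#' @param t1_ms Longitudinal relaxation time in ms (> 0).
#' @param t2star_ms Effective transverse relaxation time in ms (> 0).
#' @param m0 Equilibrium magnetization, arbitrary units (>= 0, default 1).
#' @param b1_scale Transmit-field (B1+) scale on the nominal flip angle
#'   (> 0, default 1).
#' @param inv_efficiency Inversion efficiency in `[0, 1]` (default 1, an ideal
#'   adiabatic global inversion).
#' @return An object of class `mrf_tissue`.
#' @export
tissue_params <- function(t1_ms, t2star_ms, m0 = 1, b1_scale = 1,
                          inv_efficiency = 1) {
  t1_ms <- check_positive(t1_ms, "t1_ms")
  t2star_ms <- check_positive(t2star_ms, "t2star_ms")
  m0 <- check_positive(m0, "m0", strict = FALSE)
  b1_scale <- check_positive(b1_scale, "b1_scale")
  if (length(inv_efficiency) != 1L || !is.finite(inv_efficiency) ||
      inv_efficiency < 0 || inv_efficiency > 1) {
    mrf_stop("mrfepi_invalid_argument", "`inv_efficiency` must be in [0, 1]")
  }
  structure(list(t1_ms = t1_ms, t2star_ms = t2star_ms, m0 = m0,
                 b1_scale = b1_scale, inv_efficiency = inv_efficiency),
            class = "mrf_tissue")
}

#' Longitudinal relaxation over a time interval
#'
#' Bloch longitudinal recovery: `m0 + (mz - m0) * exp(-dt / t1)`. Vectorized
#' over all arguments.
#'
#' @param mz Current longitudinal magnetization.
#' @param m0 Equilibrium magnetization.
#' @param t1_ms Longitudinal relaxation time in ms.
#' @param dt_ms Elapsed time in ms (>= 0).
#' @return Relaxed longitudinal magnetization.
#' @export
relax_longitudinal <- function(mz, m0, t1_ms, dt_ms) {
  if (any(t1_ms <= 0)) mrf_stop("mrfepi_invalid_argument", "`t1_ms` must be > 0")
  if (any(dt_ms < 0)) mrf_stop("mrfepi_invalid_argument", "`dt_ms` must be >= 0")
  m0 + (mz - m0) * exp(-dt_ms / t1_ms)
}

#' Longitudinal-signal recursion, vectorized over parameter combinations
#'
#' Core of all fingerprint simulation. For each (t1, b1) combination (vectors
#' recycled to equal length) it runs the inversion-prepared spoiled-GRE
#' recursion along the readout times and returns the magnitude pre-echo signal
#' `|Mz- * sin(b1 * alpha_j)|` for unit m0, without T2* echo decay (which is a
#' separable factor `exp(-TE_j / t2star)`).
#'
#' @param times_ms Readout (excitation) times from the inversion pulse, ms.
#' @param flip_rad Nominal flip angles in radians, one per readout.
#' @param t1_ms,b1_scale Parameter vectors, recycled to a common length.
#' @param inv_efficiency Inversion efficiency in `[0, 1]`.
#' @return Matrix `n_combo x n_readouts` of non-negative signals.
#' @noRd
.mz_signal_matrix <- function(times_ms, flip_rad, t1_ms, b1_scale = 1,
                              inv_efficiency = 1) {
  n <- length(times_ms)
  m <- max(length(t1_ms), length(b1_scale))
  t1 <- rep_len(as.numeric(t1_ms), m)
  b1 <- rep_len(as.numeric(b1_scale), m)
  out <- matrix(0, nrow = m, ncol = n)
  mz <- rep(-inv_efficiency, m)    # unit m0, flipped by the global inversion
  prev <- 0
  for (j in seq_len(n)) {
    dt <- times_ms[j] - prev
    if (dt < 0) mrf_stop("mrfepi_invalid_argument", "readout times must be increasing")
    mz <- 1 + (mz - 1) * exp(-dt / t1)
    a <- b1 * flip_rad[j]
    out[, j] <- abs(mz * sin(a))
    mz <- mz * cos(a)
    prev <- times_ms[j]
  }
  out
}

#' Simulate a magnitude fingerprint along a slice timeline
#'
#' Sequential Bloch model for the inversion-prepared, perfectly spoiled
#' gradient echo: the global inversion flips Mz to `-inv_efficiency * m0`;
#' before each readout of this slice Mz relaxes freely over the elapsed time
#' (excitations of the other slices only consume time, since excitation is
#' slice-selective); readout j emits
#' `|Mz * sin(b1 * alpha_j)| * exp(-TE_j / t2star)` and the excitation scales
#' Mz by `cos(b1 * alpha_j)`. Transverse magnetization is assumed fully
#' spoiled between readouts.
#'
#' @param timeline An `mrf_slice_timeline` (see [build_group_schedule()]).
#' @param tissue An `mrf_tissue` (see [tissue_params()]).
#' @return Numeric vector of non-negative magnitude signals, one per readout.
#' @export
simulate_fingerprint <- function(timeline, tissue) {
  stopifnot(inherits(timeline, "mrf_slice_timeline"))
  if (!inherits(tissue, "mrf_tissue")) {
    tissue <- do.call(tissue_params, as.list(tissue))
  }
  base <- .mz_signal_matrix(timeline$readout_times_ms,
                            timeline$flip_deg * pi / 180,
                            tissue$t1_ms, tissue$b1_scale,
                            tissue$inv_efficiency)
  as.vector(tissue$m0 * base[1L, ] * exp(-timeline$te_ms / tissue$t2star_ms))
}

#' Ernst steady-state signal of a spoiled gradient echo
#'
#' Closed form for constant flip angle and TR:
#' `m0 * sin(a) * (1 - E1) / (1 - E1 * cos(a)) * exp(-TE / T2*)`,
#' `E1 = exp(-TR / T1)`. Used as an independent oracle for the long-train
#' limit of [simulate_fingerprint()].
#'
#' @param alpha_deg Flip angle in degrees.
#' @param tr_ms Repetition time in ms.
#' @param t1_ms Longitudinal relaxation time in ms.
#' @param te_ms Echo time in ms (default 0).
#' @param t2star_ms Effective transverse relaxation time in ms (default `Inf`).
#' @param m0 Equilibrium magnetization (default 1).
#' @return Steady-state signal magnitude.
#' @export
ernst_signal <- function(alpha_deg, tr_ms, t1_ms, te_ms = 0, t2star_ms = Inf,
                         m0 = 1) {
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  abs(m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te_ms / t2star_ms))
}

#' Construct a standalone slice timeline
#'
#' Convenience constructor for a timeline outside a group schedule (e.g. a
#' single-slice acquisition or a design-analysis sweep point).
#'
#' @param readout_times_ms Strictly increasing readout times from inversion, ms.
#' @param te_ms,flip_deg Per-readout echo times (ms) and flip angles (deg).
#' @param slice_index Slice label (default 1).
#' @param timeline_id Identifier string (default derived from the inputs).
#' @return An `mrf_slice_timeline`.
#' @export
slice_timeline <- function(readout_times_ms, te_ms, flip_deg, slice_index = 1L,
                           timeline_id = NULL) {
  n <- length(readout_times_ms)
  if (n < 1L || length(te_ms) != n || length(flip_deg) != n) {
    mrf_stop("mrfepi_invalid_argument",
             "`readout_times_ms`, `te_ms`, `flip_deg` must have equal length >= 1")
  }
  if (n > 1L && any(diff(readout_times_ms) <= 0)) {
    mrf_stop("mrfepi_invalid_argument", "`readout_times_ms` must be strictly increasing")
  }
  structure(list(
    slice_index = as.integer(slice_index),
    readout_times_ms = as.numeric(readout_times_ms),
    te_ms = as.numeric(te_ms),
    flip_deg = as.numeric(flip_deg),
    effective_tr_ms = diff(as.numeric(readout_times_ms)),
    timeline_id = timeline_id %||%
      sprintf("tl-n%d-%.4f", n, sum(readout_times_ms) + sum(te_ms) + sum(flip_deg))
  ), class = "mrf_slice_timeline")
}
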