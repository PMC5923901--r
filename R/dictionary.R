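#' Default T1 grid (ms)
#'
#' 20--2000 ms in steps of 10 ms joined with 2000--6000 ms in steps of 500 ms
#' (the joint value 2000 included once): 207 values.
#' @return Sorted numeric vector.
#' @export
default_t1_grid <- function() {
  unique(c(seq(20, 2000, by = 10), seq(2000, 6000, by = 500)))
}

#' Default T2* grid (ms)
#'
#' 10--100 ms in steps of 2 ms joined with 100--300 ms in steps of 5 ms (the
#' joint value 100 included once): 86 values.
#' @return Sorted numeric vector.
#' @export
default_t2star_grid <- function() {
  unique(c(seq(10, 100, by = 2), seq(100, 300, by = 5)))
}

#' Default B1+ scale grid
#'
#' Linear flip-angle scaling factors 0.6--1.4 in steps of 0.1: 9 values.
#' @return Sorted numeric vector.
#' @export
default_b1_grid <- function() {
  round(seq(0.6, 1.4, by = 0.1), 10)
}

#' Dictionary parameter grid
#'
#' Strictly increasing, positive grids for T1, T2* and the B1+ scale. The
#' defaults are the standard acquisition grids (see [default_t1_grid()] and
#' friends); any of them may be replaced, e.g. `b1 = 1` to restrict matching
#' to the nominal transmit field.
#'
#' @param t1_ms,t2star_ms,b1 Numeric grids; duplicates are removed and values
#'   sorted.
#' @return An object of class `mrf_grid`.
#' @export
parameter_grid <- function(t1_ms = default_t1_grid(),
                           t2star_ms = default_t2star_grid(),
                           b1 = default_b1_grid()) {
  clean <- function(x, name) {
    x <- sort(unique(as.numeric(x)))
    if (length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
      mrf_stop("mrfepi_invalid_argument", "`%s` must be positive and finite", name)
    }
    x
  }
  structure(list(t1_ms = clean(t1_ms, "t1_ms"),
                 t2star_ms = clean(t2star_ms, "t2star_ms"),
                 b1 = clean(b1, "b1")),
            class = "mrf_grid")
}

#' Build a fingerprint dictionary for one TR pattern
#'
#' Simulates one magnitude fingerprint per grid triple (t1, t2*, b1) along the
#' given slice timeline with unit m0, discards unphysical entries with
#' `t1 < t2star`, and normalizes every entry to unit Euclidean norm (the
#' pre-normalization norms are retained for M0 estimation). Entries are ordered
#' lexicographically by (b1, t1, t2star), which fixes tie-breaking.
#'
#' Because every slice in an interleaved group has its own effective-TR
#' pattern, one dictionary must be built per slice timeline.
#'
#' @param grid An `mrf_grid`.
#' @param timeline An `mrf_slice_timeline`.
#' @param inv_efficiency Inversion efficiency used in the simulation.
#' @return An object of class `mrf_dictionary` with fields `entries`
#'   (`n_entries x n_readouts` unit-norm matrix), `params` (data.frame with
#'   `t1_ms`, `t2star_ms`, `b1_scale`), `norms`, `timeline_id`, `n_readouts`.
#' @export
build_dictionary <- function(grid, timeline, inv_efficiency = 1) {
  stopifnot(inherits(grid, "mrf_grid"), inherits(timeline, "mrf_slice_timeline"))
  t1g <- grid$t1_ms; t2g <- grid$t2star_ms; b1g <- grid$b1
  n_t1 <- length(t1g); n_b1 <- length(b1g)
  # number of admissible t2* values (t2* <= t1) per t1
  k <- findInterval(t1g, t2g)
  if (sum(k) == 0L) {
    mrf_stop("mrfepi_invalid_argument",
             "no grid triple satisfies t1 >= t2star")
  }
  # base signals without echo decay, one row per (b1, t1) in lexicographic order
  base <- .mz_signal_matrix(timeline$readout_times_ms,
                            timeline$flip_deg * pi / 180,
                            t1_ms = rep(t1g, times = n_b1),
                            b1_scale = rep(b1g, each = n_t1),
                            inv_efficiency = inv_efficiency)
  decay <- exp(-outer(1 / t2g, timeline$te_ms))   # n_t2 x n_readouts
  t2_idx_per_t1 <- unlist(lapply(seq_len(n_t1), function(i) seq_len(k[i])))
  base_row_per_t1 <- rep(seq_len(n_t1), times = k)
  n_pairs <- length(t2_idx_per_t1)
  base_rows <- rep((seq_len(n_b1) - 1L) * n_t1, each = n_pairs) +
    rep(base_row_per_t1, times = n_b1)
  t2_rows <- rep(t2_idx_per_t1, times = n_b1)
  entries <- base[base_rows, , drop = FALSE] * decay[t2_rows, , drop = FALSE]
  params <- data.frame(
    t1_ms = rep(rep(t1g, times = k), times = n_b1),
    t2star_ms = t2g[t2_rows],
    b1_scale = rep(b1g, each = n_pairs)
  )
  norms <- sqrt(rowSums(entries^2))
  if (any(norms < 1e-300)) {
    mrf_stop("mrfepi_degenerate_entry",
             "dictionary contains all-zero fingerprints (e.g. all flip angles zero)")
  }
  structure(list(
    entries = entries / norms,
    params = params,
    norms = norms,
    timeline_id = timeline$timeline_id,
    n_readouts = length(timeline$readout_times_ms),
    grid = grid
  ), class = "mrf_dictionary")
}

#' Closed-form semi-quantitative M0
#'
#' Least-squares amplitude of the measured trace `k` against a matched
#' fingerprint `f`: `|k'k| / |k'f|`. With `f` the *unnormalized* unit-m0
#' fingerprint of the matched entry (`norms[i] * entries[i, ]`) this returns
#' the tissue amplitude directly; with unit-norm `f` it returns that amplitude
#' times the fingerprint norm.
#'
#' @param k Measured magnitude trace.
#' @param f Matched fingerprint, same length.
#' @return Scalar amplitude.
#' @export
compute_m0 <- function(k, f) {
  if (length(k) != length(f)) {
    mrf_stop("mrfepi_invalid_argument", "`k` and `f` must have equal length")
  }
  den <- abs(sum(k * f))
  if (den == 0) {
    mrf_stop("mrfepi_no_match", "`k` and `f` are orthogonal; M0 undefined")
  }
  abs(sum(k * k)) / den
}

#' Match a measured trace against a dictionary
#'
#' Selects the dictionary entry with the highest inner product between the
#' magnitude of the measured signal and the unit-norm magnitude entry (cosine
#' similarity; ties broken deterministically by lowest entry index). M0 is the
#' closed-form amplitude of [compute_m0()] evaluated against the matched
#' entry's unnormalized fingerprint, so a trace `c * fingerprint(t1, t2*, b1)`
#' returns amplitude `c`.
#'
#' @param signal Numeric magnitude trace, length equal to the dictionary's
#'   readout count, not all zero.
#' @param dict An `mrf_dictionary`.
#' @return An object of class `mrf_match`: list with `t1_ms`, `t2star_ms`,
#'   `b1_scale`, `m0`, `score` (normalized inner product in `[0, 1]`) and
#'   `entry_index`.
#' @export
match_fingerprint <- function(signal, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  signal <- abs(as.numeric(signal))
  if (length(signal) != dict$n_readouts) {
    mrf_stop("mrfepi_invalid_argument",
             "signal length (%d) does not match dictionary readouts (%d)",
             length(signal), dict$n_readouts)
  }
  nrm <- sqrt(sum(signal^2))
  if (nrm == 0) mrf_stop("mrfepi_no_match", "signal is all zero; no match possible")
  raw <- as.vector(dict$entries %*% signal)
  i <- which.max(raw)          # first maximum = lowest entry index on ties
  structure(list(
    t1_ms = dict$params$t1_ms[i],
    t2star_ms = dict$params$t2star_ms[i],
    b1_scale = dict$params$b1_scale[i],
    m0 = sum(signal^2) / (dict$norms[i] * raw[i]),
    score = raw[i] / nrm,
    entry_index = i
  ), class = "mrf_match")
}

#' Number of dictionary entries implied by a grid
#'
#' Enumerates the (t1, t2*) pairs with `t1 >= t2star` and multiplies by the
#' B1 grid size; equals `nrow(build_dictionary(...)$params)` without
#' simulating anything.
#'
#' @param grid An `mrf_grid`.
#' @return Integer entry count (151,938 for the default grids).
#' @export
count_dictionary_entries <- function(grid) {
  stopifnot(inherits(grid, "mrf_grid"))
  sum(findInterval(grid$t1_ms, grid$t2star_ms)) * length(grid$b1)
}

#' Save / load a dictionary
#'
#' Dictionaries are plain R lists; they are serialized with [saveRDS()]. The
#' parameter table can additionally be exported as CSV for inspection.
#'
#' @param dict An `mrf_dictionary`.
#' @param path File path.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns the `mrf_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  saveRDS(dict, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  dict <- readRDS(path)
  if (!inherits(dict, "mrf_dictionary")) {
    mrf_stop("mrfepi_invalid_argument", "`%s` does not contain an mrf_dictionary", path)
  }
  dict
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d entries x %d readouts (timeline %s)\n",
              nrow(x$params), x$n_readouts, x$timeline_id))
  cat(sprintf("  T1 %g-%g ms (%d), T2* %g-%g ms (%d), B1 %g-%g (%d)\n",
              min(x$grid$t1_ms), max(x$grid$t1_ms), length(x$grid$t1_ms),
              min(x$grid$t2star_ms), max(x$grid$t2star_ms), length(x$grid$t2star_ms),
              min(x$grid$b1), max(x$grid$b1), length(x$grid$b1)))
  invisible(x)
}

#' @export
print.mrf_match <- function(x, ...) {
  cat(sprintf("MRF match: T1 = %g ms, T2* = %g ms, B1 = %g, M0 = %.4g, score = %.6f\n",
              x$t1_ms, x$t2star_ms, x$b1_scale, x$m0, x$score))
  invisible(x)
}
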