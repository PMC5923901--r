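#' Default in-vivo evaluation set
#'
#' 18 (T1, T2*) pairs covering the in-vivo brain range, laid out as a 6 x 3
#' grid over T1 {1000, 1300, 1600, 1900, 2200, 2500} ms and T2* {50, 60, 70}
#' ms. Used to average design metrics over representative tissues.
#'
#' @return data.frame with columns `t1_ms`, `t2star_ms` (18 rows).
#' @export
evaluation_set <- function() {
  data.frame(
    t1_ms = rep(c(1000, 1300, 1600, 1900, 2200, 2500), each = 3),
    t2star_ms = rep(c(50, 60, 70), times = 6)
  )
}

#' Sensitivity of a unit-norm fingerprint to relative parameter changes
#'
#' Central finite-difference Jacobian of the unit-normalized fingerprint with
#' respect to log T1 and log T2* (i.e. columns are `d f / d ln(theta)`), so
#' the derived noise amplification is expressed per *relative* parameter
#' change and is comparable between T1 and T2*.
#'
#' @param timeline An `mrf_slice_timeline`.
#' @param tissue An `mrf_tissue`.
#' @param rel_step Relative step of the central difference, in (0, 0.1]
#'   (default 0.01).
#' @return `n_readouts x 2` matrix with columns `t1`, `t2star`.
#' @export
fingerprint_jacobian <- function(timeline, tissue, rel_step = 0.01) {
  stopifnot(inherits(timeline, "mrf_slice_timeline"), inherits(tissue, "mrf_tissue"))
  if (!(rel_step > 0 && rel_step <= 0.1)) {
    mrf_stop("mrfepi_invalid_argument", "`rel_step` must be in (0, 0.1]")
  }
  unit_fp <- function(t1, t2s) {
    f <- simulate_fingerprint(timeline, tissue_params(
      t1_ms = t1, t2star_ms = t2s, m0 = tissue$m0,
      b1_scale = tissue$b1_scale, inv_efficiency = tissue$inv_efficiency))
    nrm <- sqrt(sum(f^2))
    if (nrm == 0) mrf_stop("mrfepi_degenerate_entry", "fingerprint is all zero")
    f / nrm
  }
  h <- rel_step
  # d f / d ln(theta) ~ [f(theta e^h) - f(theta e^-h)] / (2 h)
  j_t1 <- (unit_fp(tissue$t1_ms * exp(h), tissue$t2star_ms) -
           unit_fp(tissue$t1_ms * exp(-h), tissue$t2star_ms)) / (2 * h)
  j_t2 <- (unit_fp(tissue$t1_ms, tissue$t2star_ms * exp(h)) -
           unit_fp(tissue$t1_ms, tissue$t2star_ms * exp(-h))) / (2 * h)
  cbind(t1 = j_t1, t2star = j_t2)
}

#' Noise amplification of the linearized fingerprinting system
#'
#' Cramer-Rao-style proxy for the relative parameter uncertainty per unit
#' measurement noise: `sqrt(diag((J'J)^-1))` for the relative-parameter
#' Jacobian of [fingerprint_jacobian()]. The combined value is the unweighted
#' mean of the T1 and T2* amplifications.
#'
#' @param jacobian `n x 2` sensitivity matrix.
#' @return List with `na_t1`, `na_t2star`, `na_combined`.
#' @export
noise_amplification <- function(jacobian) {
  m <- crossprod(jacobian)
  if (!all(is.finite(m)) || rcond_2x2(m) < 1e-14) {
    mrf_stop("mrfepi_unidentifiable_design",
             "J'J is singular; the design does not identify both parameters")
  }
  v <- sqrt(diag(solve(m)))
  list(na_t1 = v[[1]], na_t2star = v[[2]], na_combined = mean(v))
}

#' Reciprocal condition estimate of a symmetric 2x2 matrix
#' @noRd
rcond_2x2 <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Monte-Carlo matching precision for a timeline
#'
#' For each evaluation pair, simulates the noiseless fingerprint, adds
#' independent zero-mean Gaussian noise of standard deviation
#' `sigma * norm(fingerprint) / sqrt(n_readouts)` (i.e. `sigma` is relative to
#' the root-mean-square sample amplitude) to every sample of every draw,
#' matches each noisy magnitude trace against the dictionary, and records the
#' relative standard deviation (coefficient of variation) of the matched T1
#' and T2*. Precision values are averaged over the evaluation set.
#'
#' @param timeline An `mrf_slice_timeline`.
#' @param eval_set data.frame with `t1_ms`, `t2star_ms` (default
#'   [evaluation_set()]).
#' @param dict `mrf_dictionary` built for this timeline.
#' @param sigma Relative noise level (>= 0; default 0.05).
#' @param n_draws Monte-Carlo repetitions per pair (default 1000).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @return List with `precision_t1`, `precision_t2star` (mean CV over pairs)
#'   and `per_pair` (data.frame of per-pair CVs).
#' @export
monte_carlo_precision <- function(timeline, eval_set = evaluation_set(), dict,
                                  sigma = 0.05, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(timeline, "mrf_slice_timeline"), inherits(dict, "mrf_dictionary"))
  if (nrow(eval_set) < 1L) {
    mrf_stop("mrfepi_invalid_argument", "`eval_set` must contain at least one pair")
  }
  sigma <- check_positive(sigma, "sigma", strict = FALSE)
  n_draws <- check_count(n_draws, "n_draws")
  n <- dict$n_readouts
  cv <- withr::with_seed(seed, {
    t(vapply(seq_len(nrow(eval_set)), function(i) {
      fp <- simulate_fingerprint(timeline, tissue_params(
        t1_ms = eval_set$t1_ms[i], t2star_ms = eval_set$t2star_ms[i]))
      sd_noise <- sigma * sqrt(sum(fp^2)) / sqrt(n)
      noisy <- abs(fp + matrix(rnorm(n * n_draws, sd = sd_noise), nrow = n))
      scores <- dict$entries %*% noisy               # n_entries x n_draws
      best <- max.col(t(scores), ties.method = "first")
      t1m <- dict$params$t1_ms[best]
      t2m <- dict$params$t2star_ms[best]
      c(stats::sd(t1m) / mean(t1m), stats::sd(t2m) / mean(t2m))
    }, numeric(2)))
  })
  list(precision_t1 = mean(cv[, 1]),
       precision_t2star = mean(cv[, 2]),
       per_pair = data.frame(t1_ms = eval_set$t1_ms,
                             t2star_ms = eval_set$t2star_ms,
                             cv_t1 = cv[, 1], cv_t2star = cv[, 2]))
}

#' Design sweep over the number of baseline images
#'
#' For each requested baseline-image count `n`, interpolates the TE and
#' flip-angle trains to `n` readouts, maximizes TR by spreading the readouts
#' uniformly over the group time, and evaluates (a) the average linearized
#' noise amplification over the evaluation set and (b, optionally) the
#' Monte-Carlo matching precision against a dictionary built for that
#' timeline. Infeasible counts (readout modules exceeding the budget) are
#' skipped with a message.
#'
#' @param base `mrf_patterns` base trains (default [default_patterns()]).
#' @param n_range Baseline-image counts to evaluate (default `1:160`).
#' @param group_duration_ms Group time budget in ms (default 17000).
#' @param eval_set Evaluation pairs (default [evaluation_set()]).
#' @param sigma Relative Monte-Carlo noise level (default 0.05).
#' @param n_draws Monte-Carlo repetitions (default 1000; `0` skips the
#'   Monte-Carlo columns).
#' @param seed RNG seed.
#' @param grid `mrf_grid` for the Monte-Carlo dictionaries; default: the
#'   standard T1/T2* grids restricted to nominal B1 (the design study
#'   concerns T1/T2*).
#' @return data.frame of class `mrf_design_curve` with columns `n_images`,
#'   `na_t1`, `na_t2star`, `na_combined` and (if `n_draws > 0`) `mc_t1`,
#'   `mc_t2star`; attributes `sigma`, `n_draws`, `seed`.
#' @export
sweep_baseline_images <- function(base = default_patterns(), n_range = 1:160,
                                  group_duration_ms = 17000,
                                  eval_set = evaluation_set(), sigma = 0.05,
                                  n_draws = 1000, seed = 1L,
                                  grid = parameter_grid(b1 = 1)) {
  stopifnot(inherits(base, "mrf_patterns"))
  rows <- lapply(n_range, function(n) {
    pat <- interpolate_patterns(base, n)
    starts <- tryCatch(
      allocate_event_times(n, group_duration_ms, base$readout_overhead_ms),
      mrfepi_infeasible_schedule = function(e) {
        message(sprintf("skipping n = %d: %s", n, conditionMessage(e)))
        NULL
      })
    if (is.null(starts)) return(NULL)
    tl <- slice_timeline(starts, pat$te_ms, pat$flip_deg,
                         timeline_id = sprintf("sweep-n%d", n))
    na <- colMeans(t(vapply(seq_len(nrow(eval_set)), function(i) {
      j <- fingerprint_jacobian(tl, tissue_params(eval_set$t1_ms[i],
                                                  eval_set$t2star_ms[i]))
      tryCatch(unlist(noise_amplification(j)),
               mrfepi_unidentifiable_design = function(e) rep(NA_real_, 3))
    }, numeric(3))))
    row <- data.frame(n_images = n, na_t1 = na[[1]], na_t2star = na[[2]],
                      na_combined = na[[3]])
    if (n_draws > 0) {
      dict <- build_dictionary(grid, tl)
      mc <- monte_carlo_precision(tl, eval_set, dict, sigma = sigma,
                                  n_draws = n_draws, seed = seed + n)
      row$mc_t1 <- mc$precision_t1
      row$mc_t2star <- mc$precision_t2star
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "sigma") <- sigma
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("mrf_design_curve", class(out))
  out
}

#' Compare randomized and sequential slice orderings
#'
#' Builds a slice-group schedule under the chosen ordering scheme, runs the
#' Monte-Carlo precision analysis for each slice's timeline (with its own
#' dictionary), and reports per-slice precision together with the across-slice
#' dispersion (standard deviation). Randomization aims to make precision
#' homogeneous across the slices of a group.
#'
#' @param base `mrf_patterns` base trains.
#' @param n_slices Slices per group (default 4).
#' @param scheme `"randomized"` or `"sequential"`.
#' @param eval_set Evaluation pairs (default [evaluation_set()]).
#' @param sigma Relative noise level (default 0.05).
#' @param n_draws Monte-Carlo repetitions (default 1000).
#' @param seed RNG seed (also used for the slice ordering).
#' @param images_per_slice Baseline images per slice (default 40).
#' @param group_duration_ms Group time in ms (default 17000).
#' @param grid Dictionary grid (default: standard grids at nominal B1).
#' @return data.frame with one row per slice (`slice`, `precision_t1`,
#'   `precision_t2star`); attribute `dispersion` holds the across-slice
#'   standard deviations.
#' @export
compare_slice_orderings <- function(base = default_patterns(), n_slices = 4,
                                    scheme = c("randomized", "sequential"),
                                    eval_set = evaluation_set(), sigma = 0.05,
                                    n_draws = 1000, seed = 1L,
                                    images_per_slice = 40,
                                    group_duration_ms = 17000,
                                    grid = parameter_grid(b1 = 1)) {
  scheme <- match.arg(scheme)
  grp <- build_group_schedule(base, n_slices, images_per_slice,
                              group_duration_ms, seed = seed, ordering = scheme)
  res <- t(vapply(grp$timelines, function(tl) {
    dict <- build_dictionary(grid, tl)
    mc <- monte_carlo_precision(tl, eval_set, dict, sigma = sigma,
                                n_draws = n_draws,
                                seed = seed + tl$slice_index)
    c(mc$precision_t1, mc$precision_t2star)
  }, numeric(2)))
  out <- data.frame(slice = seq_len(n_slices),
                    precision_t1 = res[, 1], precision_t2star = res[, 2])
  attr(out, "dispersion") <- c(t1 = stats::sd(res[, 1]),
                               t2star = stats::sd(res[, 2]))
  attr(out, "scheme") <- scheme
  out
}
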