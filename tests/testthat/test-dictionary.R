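test_that("default grids enumerate to the documented sizes", {
  # independent enumeration of the printed ranges, step by step
  t1_brute <- c()
  for (v in seq(20, 2000, by = 10)) t1_brute <- c(t1_brute, v)
  for (v in seq(2000, 6000, by = 500)) t1_brute <- c(t1_brute, v)
  t1_brute <- sort(unique(t1_brute))
  expect_equal(default_t1_grid(), t1_brute)
  expect_length(default_t1_grid(), 207)

  t2_brute <- sort(unique(c(seq(10, 100, by = 2), seq(100, 300, by = 5))))
  expect_equal(default_t2star_grid(), t2_brute)
  expect_length(default_t2star_grid(), 86)

  expect_equal(default_b1_grid(), seq(0.6, 1.4, by = 0.1), tolerance = 1e-12)
  expect_length(default_b1_grid(), 9)
})

test_that("dictionary enumeration matches a brute-force pair count", {
  grid <- parameter_grid()
  brute <- 0L
  for (t1 in grid$t1_ms) for (t2 in grid$t2star_ms) if (t1 >= t2) brute <- brute + 1L
  brute <- brute * length(grid$b1)
  expect_equal(count_dictionary_entries(grid), brute)
  expect_equal(brute, 151938L)

  cg <- coarse_grid()
  dict <- build_dictionary(cg, uniform_timeline(16))
  brute_c <- 0L
  for (t1 in cg$t1_ms) for (t2 in cg$t2star_ms) for (b in cg$b1) {
    if (t1 >= t2) brute_c <- brute_c + 1L
  }
  expect_equal(nrow(dict$params), brute_c)
  expect_equal(count_dictionary_entries(cg), brute_c)
})

test_that("dictionaries discard t1 < t2star, are unit-norm and deduplicated", {
  dict <- build_dictionary(coarse_grid(), uniform_timeline(16))
  expect_false(any(dict$params$t1_ms < dict$params$t2star_ms))
  # the unphysical triple (T1 50, T2* 60) can never appear
  g2 <- parameter_grid(t1_ms = c(50, 500), t2star_ms = c(40, 60), b1 = 1)
  d2 <- build_dictionary(g2, uniform_timeline(16))
  expect_false(any(d2$params$t1_ms == 50 & d2$params$t2star_ms == 60))

  expect_equal(sqrt(rowSums(dict$entries^2)), rep(1, nrow(dict$params)),
               tolerance = 1e-12)
  expect_false(any(duplicated(dict$params)))
  # lexicographic (b1, t1, t2star) ordering
  o <- order(dict$params$b1_scale, dict$params$t1_ms, dict$params$t2star_ms)
  expect_equal(o, seq_len(nrow(dict$params)))

  zero_tl <- slice_timeline(c(100, 200), c(20, 20), c(0, 0))
  expect_error(build_dictionary(coarse_grid(), zero_tl),
               class = "mrfepi_degenerate_entry")
})

test_that("noiseless matching recovers every grid triple exactly", {
  tl <- uniform_timeline(24)
  grid <- coarse_grid()
  dict <- build_dictionary(grid, tl)
  for (i in seq_len(nrow(dict$params))) {
    p <- dict$params[i, ]
    fp <- simulate_fingerprint(tl, tissue_params(p$t1_ms, p$t2star_ms,
                                                 b1_scale = p$b1_scale))
    m <- match_fingerprint(fp, dict)
    expect_identical(c(m$t1_ms, m$t2star_ms, m$b1_scale),
                     c(p$t1_ms, p$t2star_ms, p$b1_scale))
    expect_equal(m$score, 1, tolerance = 1e-10)
    expect_equal(m$m0, 1, tolerance = 1e-10)
  }
})

test_that("matched triples are scale invariant and M0 is equivariant", {
  tl <- uniform_timeline(24)
  dict <- build_dictionary(coarse_grid(), tl)
  fp <- simulate_fingerprint(tl, tissue_params(1000, 60, b1_scale = 1.2))
  ref <- match_fingerprint(fp, dict)
  for (c_scale in c(0.01, 3, 1e4)) {
    m <- match_fingerprint(c_scale * fp, dict)
    expect_identical(m$entry_index, ref$entry_index)
    expect_equal(m$m0, c_scale * ref$m0, tolerance = 1e-9)
    expect_equal(m$score, ref$score)
  }
})

test_that("the matcher equals a brute-force inner-product loop", {
  tl <- uniform_timeline(20)
  grid <- parameter_grid(t1_ms = seq(100, 2500, by = 100),
                         t2star_ms = seq(15, 115, by = 5), b1 = 1)
  dict <- build_dictionary(grid, tl)
  expect_gte(nrow(dict$params), 500)
  for (seed in 1:10) {
    sig <- withr::with_seed(seed, abs(rnorm(20)))
    m <- match_fingerprint(sig, dict)
    brute_scores <- numeric(nrow(dict$params))
    for (i in seq_len(nrow(dict$params))) {
      brute_scores[i] <- sum(sig * dict$entries[i, ])
    }
    expect_identical(m$entry_index, which.max(brute_scores))
    expect_equal(m$score, max(brute_scores) / sqrt(sum(sig^2)))
  }
})

test_that("equal scores break ties toward the lowest entry index", {
  tl <- uniform_timeline(16)
  dict <- build_dictionary(coarse_grid(), tl)
  dup <- dict
  dup$entries[40, ] <- dup$entries[7, ]   # force an exact tie
  dup$norms[40] <- dup$norms[7]
  sig <- dup$entries[7, ]
  expect_identical(match_fingerprint(sig, dup)$entry_index, 7L)
})

test_that("degenerate matching inputs raise classed errors", {
  dict <- build_dictionary(coarse_grid(), uniform_timeline(16))
  expect_error(match_fingerprint(rep(0, 16), dict), class = "mrfepi_no_match")
  expect_error(match_fingerprint(rep(1, 15), dict),
               class = "mrfepi_invalid_argument")
})

test_that("closed-form M0 reproduces hand-computed identities", {
  f <- withr::with_seed(1, abs(rnorm(25)))
  f <- f / sqrt(sum(f^2))
  expect_equal(compute_m0(f, f), 1)
  expect_equal(compute_m0(3 * f, f), 3)

  # k = f + orthogonal e: |k'k|/|k'f| = 1 + ||e||^2 (disjoint supports keep
  # the orthogonality exact in floating point)
  f2 <- c(1, 2, 2, 0, 0, 0) / 3
  e <- c(0, 0, 0, 0.3, -0.4, 1.2)
  expect_equal(compute_m0(f2 + e, f2), 1 + sum(e^2))
  expect_error(compute_m0(e, f2), class = "mrfepi_no_match")
  expect_error(compute_m0(f, f[-1]), class = "mrfepi_invalid_argument")
})

test_that("off-grid tissues match within one grid step (noiseless)", {
  tl <- uniform_timeline(24)
  grid <- coarse_grid()
  dict <- build_dictionary(grid, tl)
  cases <- withr::with_seed(7, data.frame(t1 = runif(8, 300, 1900),
                                          t2s = runif(8, 30, 110)))
  for (i in seq_len(nrow(cases))) {
    t1 <- cases$t1[i]; t2s <- min(cases$t2s[i], cases$t1[i])
    m <- match_fingerprint(simulate_fingerprint(tl, tissue_params(t1, t2s)), dict)
    expect_lte(abs(m$t1_ms - t1), 200)
    expect_lte(abs(m$t2star_ms - t2s), 20)
  }
})

test_that("the four per-slice dictionaries of a group are pairwise distinct", {
  grp <- build_group_schedule(default_patterns(), 4, 12, 6000, seed = 3)
  dicts <- lapply(grp$timelines, function(tl) build_dictionary(coarse_grid(), tl))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(isTRUE(all.equal(dicts[[i]]$entries, dicts[[j]]$entries)))
  }
})

test_that("dictionaries survive a save/load round trip", {
  dict <- build_dictionary(coarse_grid(), uniform_timeline(16))
  path <- withr::local_tempfile(fileext = ".rds")
  save_dictionary(dict, path)
  expect_identical(load_dictionary(path), dict)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, bad)
  expect_error(load_dictionary(bad), class = "mrfepi_invalid_argument")
})
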