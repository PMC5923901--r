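test_that("map reconstruction equals per-voxel matching and is exact when noiseless", {
  ph <- grid_valued_brain(c(24, 24), seed = 2)
  proto <- build_protocol(4, 4, images_per_slice = 24, seed = 4)
  study <- render_baseline_series(ph, proto, seed = 6)
  grid <- parameter_grid(t1_ms = c(750, 1200, 1290, 2000, 4000),
                         t2star_ms = c(40, 52, 56, 96, 200),
                         b1 = default_b1_grid())
  dict <- build_dictionary(grid, protocol_timeline(proto, 1))
  maps <- reconstruct_maps(study$series[[1]], dict)

  truth <- study$truth[[1]]
  expect_equal(maps$t1_ms, truth$t1_ms)
  expect_equal(maps$t2star_ms, truth$t2star_ms)
  expect_equal(maps$b1_scale, truth$b1_scale)
  expect_equal(maps$m0, truth$m0, tolerance = 1e-8)
  expect_true(all(is.na(maps$t1_ms[!truth$mask])))
  expect_false(any(maps$t1_ms[maps$mask] < maps$t2star_ms[maps$mask], na.rm = TRUE))

  # vectorized matching agrees with a scalar per-voxel loop
  idx <- which(maps$mask)[c(1, 25, 100, 200)]
  for (v in idx) {
    trace <- study$series[[1]]$data[arrayInd(v, dim(maps$t1_ms))[1],
                                    arrayInd(v, dim(maps$t1_ms))[2], ]
    m <- match_fingerprint(trace, dict)
    expect_equal(maps$t1_ms[v], m$t1_ms)
    expect_equal(maps$m0[v], m$m0)
  }

  wrong <- study$series[[1]]
  wrong$timeline_id <- "other"
  expect_error(reconstruct_maps(wrong, dict), class = "mrfepi_invalid_argument")
})

test_that("bias-field estimation recovers a known smooth field", {
  nr <- 96; vox <- 2.5
  x <- matrix(seq(-1, 1, length.out = nr), nr, nr); y <- t(x)
  mask <- x^2 + y^2 < 0.95
  truth <- exp(0.3 * x + 0.2 * y + 0.1 * x * y)
  truth <- truth / exp(mean(log(truth[mask])))
  m0 <- 50 * truth; m0[!mask] <- NA

  est <- estimate_bias_field(m0, mask, fwhm_mm = 60, voxel_mm = vox)
  interior <- x^2 + y^2 < 0.5
  rel <- (est$s[interior] - truth[interior]) / truth[interior]
  expect_lt(sqrt(mean(rel^2)), 0.02)

  # uniform map -> unit field
  flat <- matrix(7, 32, 32)
  u <- estimate_bias_field(flat, matrix(TRUE, 32, 32), 60, 2.5)
  expect_equal(u$s, matrix(1, 32, 32), tolerance = 1e-10)

  # global intensity scale is absorbed by the geometric-mean normalization
  est2 <- estimate_bias_field(m0 * 13, mask, 60, vox)
  expect_equal(est2$s, est$s, tolerance = 1e-12)

  expect_error(estimate_bias_field(m0, mask & FALSE, 60, vox),
               class = "mrfepi_invalid_argument")
})

test_that("CSF normalization pins the reference region to 100 pu and is linear", {
  nr <- 40
  s <- matrix(exp(seq(-0.2, 0.2, length.out = nr)), nr, nr)
  bias <- structure(list(s = s, fwhm_mm = 60, voxel_mm = 1),
                    class = "mrf_bias_field")
  csf <- matrix(FALSE, nr, nr); csf[5:10, 5:10] <- TRUE
  half <- matrix(FALSE, nr, nr); half[25:30, 25:30] <- TRUE
  m0 <- s * 80
  m0[half] <- s[half] * 40            # half the bias-corrected amplitude of CSF
  pd <- normalize_pd(m0, bias, csf)
  expect_equal(mean(pd[csf]), 100)
  expect_equal(pd[half], rep(50, sum(half)))
  expect_error(normalize_pd(m0, bias, csf & FALSE),
               class = "mrfepi_invalid_argument")
})

test_that("the phantom PD reference formula inverts decay and stays linear", {
  nr <- 16
  ones <- matrix(1, nr, nr)
  roi <- matrix(FALSE, nr, nr); roi[2:5, 2:5] <- TRUE
  inten <- matrix(seq(1, 4, length.out = nr * nr), nr, nr)

  # TE = 0, B1 = S = 1: output proportional to intensity
  pd0 <- phantom_pd_reference(inten, ones, ones, 0, 50 * ones, roi)
  expect_equal(pd0 / inten, matrix(100 / mean(inten[roi]), nr, nr))

  # pre-multiplying the intensity by the decay is exactly undone
  t2s <- matrix(seq(30, 90, length.out = nr * nr), nr, nr)
  pd1 <- phantom_pd_reference(inten * exp(-20 / t2s), ones, ones, 20, t2s, roi)
  expect_equal(pd1, pd0)

  # two-compartment linearity: intensity ratio 0.6 -> PD ratio 0.6
  duo <- ones; duo[9:16, ] <- 0.6
  roi_top <- matrix(FALSE, nr, nr); roi_top[1:8, ] <- TRUE
  pd2 <- phantom_pd_reference(duo, ones, ones, 0, 60 * ones, roi_top)
  expect_equal(mean(pd2[9:16, ]) / mean(pd2[1:8, ]), 0.6)
  expect_error(phantom_pd_reference(duo, ones, ones, 0, -60 * ones, roi_top),
               class = "mrfepi_invalid_argument")
})

test_that("inversion-recovery T1 fit recovers synthetic truth to 0.1%", {
  ti <- c(50, 200, 600, 1200, 2400, 4000)
  cases <- expand.grid(A = c(400, 1000), t1 = c(300, 800, 1800))
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; t1 <- cases$t1[i]
    sig <- A * abs(1 - 2 * exp(-ti / t1))
    fit <- fit_ir_t1(sig, ti)
    expect_equal(fit$t1_ms, t1, tolerance = 1e-3)
    expect_equal(fit$amplitude, A, tolerance = 1e-3)
    # scale equivariance
    fit2 <- fit_ir_t1(2 * sig, ti)
    expect_equal(fit2$amplitude, 2 * fit$amplitude, tolerance = 1e-6)
    expect_equal(fit2$t1_ms, fit$t1_ms, tolerance = 1e-6)
  }
  # the model respects the null point at TI = T1 ln 2
  expect_equal(1000 * abs(1 - 2 * exp(-800 * log(2) / 800)), 0)
  expect_error(fit_ir_t1(c(1, 2), c(10, 20)), class = "mrfepi_invalid_argument")
})

test_that("multi-echo T2* fit recovers truth and matches a log-linear oracle", {
  te <- c(5, 20, 60, 120, 200, 300)
  fit <- fit_gre_t2star(500 * exp(-te / 60) + 10, te)
  expect_equal(fit$s0, 500, tolerance = 1e-3)
  expect_equal(fit$t2star_ms, 60, tolerance = 1e-3)
  expect_equal(fit$offset, 10, tolerance = 1e-2)

  # offset-free data: closed-form log-domain regression is an oracle
  sig <- 320 * exp(-te / 45)
  lf <- lm(log(sig) ~ te)
  fit0 <- fit_gre_t2star(sig, te)
  expect_equal(fit0$t2star_ms, unname(-1 / coef(lf)[2]), tolerance = 1e-3)
  expect_equal(fit0$s0, unname(exp(coef(lf)[1])), tolerance = 1e-3)

  expect_error(fit_gre_t2star(rep(5, 6), te), class = "mrfepi_fit_failure")
})

test_that("double-angle B1 mapping inverts the cosine ratio", {
  i1 <- matrix(100, 3, 3)
  expect_equal(double_angle_b1(i1, 2 * i1 * cos(45 * pi / 180), 45),
               matrix(1, 3, 3))
  expect_equal(double_angle_b1(i1, 2 * i1 * cos(36 * pi / 180), 45),
               matrix(0.8, 3, 3))
  expect_equal(double_angle_b1(i1, 0 * i1, 45), matrix(2, 3, 3))
  expect_warning(double_angle_b1(i1, 2.5 * i1, 45), "clamped")
  expect_error(double_angle_b1(-i1, i1, 45), class = "mrfepi_invalid_argument")
})
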