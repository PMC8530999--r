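test_that("framewise displacement follows the differenced six-parameter formula", {
  m <- matrix(0.3, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  m <- matrix(0, 10, 6)
  m[6:10, 1] <- 0.6                       # translation step between frames 5 and 6
  fd <- framewise_displacement(m)
  expect_equal(fd[6], 0.6)
  expect_equal(fd[-6], rep(0, 9))

  m <- matrix(0, 10, 6)
  m[4:10, 5] <- 0.01                      # rotation step on one axis
  fd <- framewise_displacement(m)
  expect_equal(fd[4], 0.5)                # 50 mm * 0.01 rad
  expect_equal(sum(fd), 0.5)

  expect_error(framewise_displacement(matrix(0, 1, 6)), "2 frames")
  expect_error(framewise_displacement(matrix(NA_real_, 5, 6)), "finite")
})

test_that("literal FD mode sums absolute parameter values without differencing", {
  m <- matrix(0, 4, 6)
  m[, 1] <- c(0.1, 0.1, 0.2, 0.2)
  expect_equal(framewise_displacement(m, literal = TRUE), c(0.1, 0.1, 0.2, 0.2))
})

test_that("scrubbing removes the excursion plus its padding window", {
  expect_true(all(scrub_mask(rep(0.4, 10))))
  fd <- rep(0, 10); fd[6] <- 0.6
  expect_equal(which(!scrub_mask(fd)), 5:8)   # 1 before, excursion, 2 after
  fd0 <- rep(0, 10); fd0[1] <- 0.9
  expect_equal(which(!scrub_mask(fd0)), 1:3)  # clipped at the run start
  fdE <- rep(0, 10); fdE[10] <- 0.9
  expect_equal(which(!scrub_mask(fdE)), 9:10) # clipped at the run end
  # threshold comparison is strictly greater
  expect_true(all(scrub_mask(rep(0.5, 10))))
})

test_that("scrubbing matches brute-force window expansion on random patterns", {
  set.seed(42)
  for (i in 1:50) {
    fd <- sample(c(0.4, 0.6), 12, replace = TRUE)
    expect_identical(scrub_mask(fd), brute_scrub(fd))
  }
})

test_that("the minimum-duration gate uses an inclusive comparison", {
  expect_true(min_duration_ok(rep(TRUE, 130), TR = 2))
  expect_false(min_duration_ok(rep(TRUE, 119), TR = 2))
  expect_true(min_duration_ok(rep(TRUE, 120), TR = 2))   # exactly 240 s
})

test_that("nuisance regression yields residuals orthogonal to the design", {
  set.seed(1)
  data <- matrix(rnorm(200 * 8), 200, 8)
  reg <- matrix(rnorm(200 * 5), 200, 5)
  res <- nuisance_regress(data, reg)
  expect_lt(max(abs(crossprod(cbind(1, reg), res))), 1e-8)
  # brute-force normal-equations oracle
  X <- cbind(1, reg)
  beta <- solve(t(X) %*% X, t(X) %*% data)
  expect_equal(res, data - X %*% beta, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("self-regression leaves ~zero residuals; rank deficiency is named", {
  set.seed(2)
  v <- matrix(rnorm(100), 100, 1)
  expect_lt(max(abs(nuisance_regress(v, v))), 1e-10)
  reg <- cbind(a = rnorm(50), b = 1)  # collinear with the intercept
  expect_error(nuisance_regress(matrix(rnorm(50), 50, 1), reg), "rank deficient")
})

test_that("the ideal band-pass keeps in-band tones and kills the rest", {
  t <- seq(0, by = 2, length.out = 300)
  s_in <- sin(2 * pi * 0.05 * t)
  out <- bandpass_filter(s_in, TR = 2)
  expect_equal(popsd(out), 1 / sqrt(2), tolerance = 0.02)
  expect_lt(max(abs(bandpass_filter(sin(2 * pi * 0.2 * t), TR = 2))), 1e-6)
  expect_equal(bandpass_filter(rep(3, 100), TR = 2), rep(0, 100))
  expect_error(bandpass_filter(rnorm(100), TR = 2, f_hi = 0.3), "Nyquist")
})

test_that("variability SD uses the population denominator over kept frames", {
  expect_equal(variability_sd(matrix(c(1, 2, 3, 4, 5))), sqrt(2))
  expect_equal(variability_sd(matrix(rep(7, 10))), 0)
  x <- matrix(c(1, 2, 100, 3, 4), ncol = 1)
  expect_equal(variability_sd(x, keep = c(TRUE, TRUE, FALSE, TRUE, TRUE)),
               variability_sd(matrix(c(1, 2, 3, 4))))
  expect_error(variability_sd(matrix(1:5, ncol = 1), keep = c(TRUE, rep(FALSE, 4))),
               "2 kept frames")
  # scale equivariance
  set.seed(3)
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(variability_sd(3.7 * m), 3.7 * variability_sd(m))
})

test_that("ALFF equals the SD of the band-passed series and a direct DFT sum", {
  set.seed(4)
  x <- matrix(rnorm(200 * 6), 200, 6)
  bp <- bandpass_filter(x, TR = 2)
  expect_equal(alff(x, TR = 2), variability_sd(bp), tolerance = 1e-8)
  expect_equal(alff(bp, TR = 2), variability_sd(bp), tolerance = 1e-8)
  # brute-force periodogram: sum |X_k|^2 over band bins computed by direct DFT
  v <- x[, 1]; T <- length(v)
  k <- 0:(T - 1)
  f <- pmin(k, T - k) / (T * 2)
  band <- which(f >= 0.01 & f <= 0.10 & k != 0)
  dft <- vapply(band - 1, function(kk) {
    abs(sum(v * exp(-2i * pi * kk * (0:(T - 1)) / T)))^2
  }, numeric(1))
  expect_equal(alff(v, TR = 2), sqrt(sum(dft)) / T, tolerance = 1e-8)
  # pure out-of-band tone
  t <- seq(0, by = 2, length.out = 200)
  expect_lt(alff(sin(2 * pi * 0.2 * t), TR = 2), 1e-8)
})

test_that("MSSD averages squared differences across consecutive kept pairs", {
  expect_equal(mssd(matrix(rep(2, 10))), 0)
  expect_equal(mssd(matrix(c(0, 1, 0, 1))), 1)
  # a scrubbed gap contributes no pair
  x <- matrix(c(0, 1, 50, 1, 0), ncol = 1)
  expect_equal(mssd(x, keep = c(TRUE, TRUE, FALSE, TRUE, TRUE)),
               mean(c(1, 1)))
  expect_error(mssd(matrix(1:4, ncol = 1), keep = c(TRUE, FALSE, TRUE, FALSE)),
               "consecutive")
  # association with SD across simulated voxels
  set.seed(5)
  m <- matrix(rnorm(200 * 100), 200, 100)
  m <- sweep(m, 2, runif(100, 0.2, 3), "*")
  expect_gt(cor(mssd(m), variability_sd(m), method = "spearman"), 0.8)
})

test_that("z-scoring is exact, idempotent, and rejects degenerate masks", {
  z <- zscore_map(c(1, 2, 3))
  expect_equal(z$values, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)
  expect_equal(zscore_map(z$values)$values, z$values, tolerance = 1e-12)
  mask1 <- structure(list(include = c(TRUE, FALSE, FALSE), source = "one"),
                     class = "analysis_mask")
  expect_error(zscore_map(c(1, 2, 3), mask1), "zero")
  # out-of-mask voxels become NA; map is invariant to global scaling
  mask <- build_analysis_mask(c(0.9, 0.9, 0.9, 0.2), gm_threshold = 0.5)
  a <- zscore_map(c(1, 2, 3, 99), mask)
  b <- zscore_map(c(1, 2, 3, 99) * 5, mask)
  expect_true(is.na(a$values[4]))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("analysis mask combines the GM threshold and exclusion correctly", {
  m <- build_analysis_mask(c(0.4, 0.5, 0.9))
  expect_equal(m$include, c(FALSE, TRUE, TRUE))     # >= comparison
  m2 <- build_analysis_mask(c(0.4, 0.5, 0.9), exclusion = c(FALSE, FALSE, TRUE))
  expect_equal(m2$include, c(FALSE, TRUE, FALSE))
  expect_error(build_analysis_mask(c(0.9, 0.9), exclusion = c(TRUE, TRUE)), "empty")
  expect_error(build_analysis_mask(c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("end-to-end extraction composes the stages in pipeline order", {
  tsd <- runif(50, 0.5, 2)
  run <- generate_bold_run(600, 50, TR = 2, target_sd = tsd, seed = 12)
  res <- extract_variability(run)
  expect_identical(res$verdict, "included")
  expect_equal(mean(res$map$values), 0, tolerance = 1e-9)
  expect_equal(popsd(res$map$values), 1, tolerance = 1e-9)
  expect_gt(cor(res$map$values, tsd, method = "spearman"), 0.9)
})

test_that("filtering before scrubbing differs from scrubbing before filtering", {
  # the pipeline filters the full series and drops scrubbed frames only for
  # the SD; the reverse order (filter the censored series) gives different
  # maps, so the order is pinned down here
  run <- generate_bold_run(400, 20, TR = 2, target_sd = runif(20, 0.5, 2),
                           spike_frames = c(100, 250), seed = 14)
  filt <- bandpass_filter(run$data, run$TR)
  fd <- framewise_displacement(run$motion)
  keep <- scrub_mask(fd)
  pipeline_order <- variability_sd(filt, keep)
  reverse_order <- variability_sd(bandpass_filter(run$data[keep, ], run$TR))
  expect_gt(max(abs(pipeline_order - reverse_order)), 1e-6)
  # and extract_variability follows the pipeline order
  res <- extract_variability(run)
  manual <- zscore_map(variability_sd(
    bandpass_filter(nuisance_regress(run$data, run$motion), run$TR), keep))
  expect_equal(res$map$values, manual$values, tolerance = 1e-12)
})

test_that("a heavily scrubbed run is excluded with its retained time reported", {
  run <- generate_bold_run(120, 5, TR = 2, target_sd = rep(1, 5),
                           spike_frames = seq(2, 118, by = 4), seed = 13)
  res <- extract_variability(run)
  expect_identical(res$verdict, "excluded")
  expect_lt(res$retained_seconds, 240)
  expect_null(res$map)
})
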