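# helper: one Gaussian on a uniform grid
gauss_profile <- function(center, height, fwhm, from, to, step) {
  mz <- seq(from, to, by = step)
  list(mz = mz,
       intensity = height * exp(-4 * log(2) * ((mz - center) / fwhm)^2))
}

test_that("peak picking honors threshold, distance and centroid accuracy", {
  params <- picking_params()
  # all-zero spectrum
  expect_equal(nrow(find_spectrum_peaks(seq(400, 401, 0.001),
                                        rep(0, 1001), params)), 0)
  # single Gaussian above threshold: one peak, centroid within 0.2 steps
  g <- gauss_profile(400.00137, 5e5, 0.0013, 399.99, 400.01, 0.0002)
  pk <- find_spectrum_peaks(g$mz, g$intensity, params)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 400.00137), 0.2 * 0.0002)
  # just below threshold: nothing
  g2 <- gauss_profile(400.001, 1.99e5, 0.0013, 399.99, 400.01, 0.0002)
  expect_equal(nrow(find_spectrum_peaks(g2$mz, g2$intensity, params)), 0)
})

test_that("close maxima are resolved by the distance rule, taller first", {
  # two apexes 3 points apart, both above threshold
  y <- c(0, 0, 3e5, 0, 0, 5e5, 0, 0)
  mz <- 400 + seq_along(y) * 0.001
  pk <- find_spectrum_peaks(mz, y, picking_params(min_distance = 5))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$intensity, 5e5)
  # same input with distance 1 keeps both (brute-force enumeration: the two
  # local maxima above threshold)
  pk2 <- find_spectrum_peaks(mz, y, picking_params(min_distance = 1))
  expect_equal(nrow(pk2), 2)
})

test_that("prominence filtering removes shoulders on larger peaks", {
  # a shoulder: small bump riding on the flank of a big peak
  mz <- seq(400, 400.04, by = 0.0005)
  big <- 1e6 * exp(-4 * log(2) * ((mz - 400.02) / 0.004)^2)
  bump <- 2.5e5 * exp(-4 * log(2) * ((mz - 400.008) / 0.0008)^2)
  y <- big + bump
  no_prom <- find_spectrum_peaks(mz, y, picking_params(prominence = 0))
  with_prom <- find_spectrum_peaks(mz, y, picking_params(prominence = 3e5))
  expect_gt(nrow(no_prom), nrow(with_prom))
  expect_equal(nrow(with_prom), 1)
})

test_that("noiseless planted spectra are recovered exactly by picking", {
  instr <- instrument_model(sigma_ppm = 0, noise_cv = 0)
  ions <- tibble::tibble(
    species = c("a", "b", "c", "d"), adduct = "[M+H]+", k = 0L,
    mz = c(300.1, 550.25, 800.4, 1100.55),
    height = c(5e5, 2e5, 1.9e5, 1e9)
  )
  sp <- simulate_pixel_spectrum(ions, instr, NULL)
  pk <- find_spectrum_peaks(sp$mz, sp$intensity, picking_params())
  # peaks at or above 200,000 counts recovered, none below
  expect_equal(nrow(pk), 3)
  matched <- vapply(c(300.1, 550.25, 1100.55), function(m) {
    any(abs(ppm_error(pk$mz, m)) < 1)
  }, logical(1))
  expect_true(all(matched))
  expect_false(any(abs(ppm_error(pk$mz, 800.4)) < 10))
})

test_that("recalibration recovers constructed ppm distortions", {
  refs <- c(300.2, 500.4, 700.6, 900.8)
  peaks <- tibble::tibble(x = 0L, y = 0L, mz = refs, intensity = 1e6)
  # already exact: a = b = 0 and unchanged m/z
  out0 <- recalibrate_peaks(peaks, refs)
  model0 <- attr(out0, "recal")
  expect_equal(model0$a, 0, tolerance = 1e-8)
  expect_equal(model0$b, 0, tolerance = 1e-10)
  expect_equal(out0$mz, refs, tolerance = 1e-10)

  # uniform +2 ppm shift: intercept ~2, residual ~0, intensities untouched
  shifted <- peaks
  shifted$mz <- refs * (1 + 2e-6)
  out2 <- recalibrate_peaks(shifted, refs)
  model2 <- attr(out2, "recal")
  expect_equal(model2$a, 2, tolerance = 1e-3)
  expect_lt(model2$rms_ppm, 1e-6)
  expect_equal(out2$mz, refs, tolerance = 1e-9)
  expect_identical(out2$intensity, shifted$intensity)
  expect_equal(tidy(model2)$estimate[1], model2$a)
  expect_equal(glance(model2)$status, "ok")

  # mass-dependent drift a + b m is recovered too
  drift <- peaks
  drift$mz <- refs * (1 + (1 + 0.002 * refs) * 1e-6)
  outd <- recalibrate_peaks(drift, refs)
  modeld <- attr(outd, "recal")
  expect_equal(modeld$a, 1, tolerance = 0.05)
  expect_equal(modeld$b, 0.002, tolerance = 1e-4)
  expect_equal(outd$mz, refs, tolerance = 1e-7)

  # no references in range: warning, unchanged output
  expect_warning(outn <- recalibrate_peaks(peaks, c(1200.5)), "skipped")
  expect_equal(outn$mz, peaks$mz)
  expect_equal(attr(outn, "recal")$status, "no-op")
})

test_that("alignment bins centroids deterministically and conserves TIC", {
  # one pixel: one bin per peak
  p1 <- tibble::tibble(x = 0L, y = 0L, mz = c(400.1, 500.2, 600.3),
                       intensity = c(1, 2, 3))
  class(p1) <- c("centroid_peaks", class(p1))
  a1 <- align_peaks(p1, 3)
  expect_equal(nrow(a1$bins), 3)

  # two pixels within 1 ppm merge into one bin with two entries
  p2 <- tibble::tibble(x = c(0L, 1L), y = 0L,
                       mz = c(500, 500 * (1 + 1e-6)), intensity = c(2, 4))
  class(p2) <- c("centroid_peaks", class(p2))
  a2 <- align_peaks(p2, 3)
  expect_equal(nrow(a2$bins), 1)
  expect_equal(nrow(a2$intensities), 2)
  # intensity-weighted representative m/z
  expect_equal(a2$bins$mz, (500 * 2 + 500 * (1 + 1e-6) * 4) / 6,
               tolerance = 1e-10)

  # permutation invariance in pixel order
  p3 <- p2[2:1, ]
  class(p3) <- c("centroid_peaks", class(p3))
  a3 <- align_peaks(p3, 3)
  expect_equal(a3$bins, a2$bins)

  # bin count is non-increasing in tolerance
  set.seed(2)
  mzs <- sort(runif(300, 400, 410))
  pr <- tibble::tibble(x = 0L, y = 0L, mz = mzs, intensity = 1)
  class(pr) <- c("centroid_peaks", class(pr))
  n_bins <- vapply(c(0.5, 1, 3, 10, 50), function(tol) {
    nrow(align_peaks(pr, tol)$bins)
  }, numeric(1))
  expect_true(all(diff(n_bins) <= 0))

  # same-pixel members in one bin are summed (TIC conserved)
  p4 <- tibble::tibble(x = 0L, y = 0L, mz = c(500, 500 + 1e-4),
                       intensity = c(2, 3))
  class(p4) <- c("centroid_peaks", class(p4))
  a4 <- align_peaks(p4, 3)
  expect_equal(nrow(a4$intensities), 1)
  expect_equal(a4$intensities$intensity, 5)
})

test_that("aligned bins recover the planted ion species of a phantom", {
  sim <- small_sim()
  peaks <- pick_peaks(sim$dataset)
  aligned <- align_peaks(peaks, 3)
  planted <- unique(round(c(sim$ions$mz, sim$matrix_ions$mz), 6))
  hits <- vapply(planted, function(m) {
    any(abs(ppm_error(aligned$bins$mz, m)) <= 3)
  }, logical(1))
  expect_true(all(hits))
  # number of bins overlapping ground truth equals the planted ion count
  n_overlap <- sum(vapply(seq_len(nrow(aligned$bins)), function(i) {
    any(abs(ppm_error(aligned$bins$mz[i], planted)) <= 3)
  }, logical(1)))
  expect_equal(n_overlap, length(planted))
})

test_that("TIC and mean spectrum summarize datasets consistently", {
  sim <- small_sim()
  tic <- pixel_tic(sim$dataset)
  expect_equal(nrow(tic), nrow(sim$dataset))
  expect_equal(tic$tic[5], sum(sim$dataset$intensity[[5]]))

  # over the matrix-only background pixels, the mean spectrum is dominated
  # by the matrix cluster ions
  bg <- sim$dataset[sim$dataset$region == "background", ]
  class(bg) <- c("msi_dataset", class(bg))
  aligned_bg <- align_peaks(pick_peaks(bg), 3)
  ms <- mean_spectrum(aligned_bg)
  top6 <- ms$mz[order(ms$mean_intensity, decreasing = TRUE)][1:6]
  is_matrix <- vapply(top6, function(m) {
    any(abs(ppm_error(m, sim$matrix_ions$mz)) <= 3)
  }, logical(1))
  expect_true(all(is_matrix))
  peaks <- pick_peaks(sim$dataset)
  aligned <- align_peaks(peaks, 3)
  # binned TIC of all pixels >= TIC restricted to any subset of bins
  tic_all <- sum(aligned$bins$total_intensity)
  subset_tic <- sum(aligned$bins$total_intensity[1:10])
  expect_gte(tic_all, subset_tic)
})
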