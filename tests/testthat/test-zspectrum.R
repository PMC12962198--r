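test_that("frequency axis sorts offsets and validates the reference", {
  ax <- frequency_axis(c(2, -2, 0), reference_offset = -1560)
  expect_equal(ax$offsets, c(-2, 0, 2))
  expect_equal(ax$offsets[order(ax$sort_index)], c(2, -2, 0))
  expect_error(frequency_axis(c(0, 0, 1)), "distinct")
  expect_error(frequency_axis(c(-6, 6), reference_offset = 50), "far off-resonance")
  expect_length(default_axis()$offsets, 23)
  expect_equal(range(default_axis()$offsets), c(-6, 6))
})

test_that("series loading re-sorts acquisition order and rejects mismatches", {
  dir <- withr::local_tempdir()
  # acquisition order deliberately scrambled
  acq <- c(0, -6, 6, -3, 3, seq(-5, 5, length.out = 18))
  ax <- frequency_axis(acq)
  d <- c(6, 5, 3)
  set.seed(1)
  data_sorted <- array(runif(prod(d) * 23, 500, 1000), c(d, 23))
  ref <- array(1000, d)
  series <- cest_series(data_sorted, ref, ax)
  write_cest_series(series, file.path(dir, "s"))
  back <- load_cest_series(file.path(dir, "s_series.nii.gz"),
                           file.path(dir, "s_series.json"))
  expect_equal(back$axis$offsets, sort(acq))
  # spot voxel: volume at a given ppm survives the permutation round trip
  for (ppm in c(-6, 0, 3)) {
    expect_equal(back$data[2, 3, 1, which(back$axis$offsets == ppm)],
                 data_sorted[2, 3, 1, which(ax$offsets == ppm)],
                 tolerance = 1e-6)
  }
  # sidecar offset count mismatch
  side <- jsonlite::read_json(file.path(dir, "s_series.json"), simplifyVector = TRUE)
  side$offsets_ppm <- side$offsets_ppm[-1]
  jsonlite::write_json(side, file.path(dir, "bad.json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_cest_series(file.path(dir, "s_series.nii.gz"),
                                file.path(dir, "bad.json")), "mismatch")
  side$offsets_ppm <- NULL
  jsonlite::write_json(side, file.path(dir, "bad2.json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_cest_series(file.path(dir, "s_series.nii.gz"),
                                file.path(dir, "bad2.json")), "offsets_ppm")
})

test_that("normalization divides by S0, guards invalid voxels and is scale invariant", {
  ax <- frequency_axis(c(-1, 0, 1))
  data <- array(0.8, c(2, 2, 1, 3))
  ref <- array(1, c(2, 2, 1))
  ref[1, 1, 1] <- 0                      # dead voxel
  data[2, 2, 1, ] <- 10                  # blow-up voxel, Z clipped at 2
  series <- cest_series(data, ref, ax)
  zv <- normalize_series(series, s0_floor = 0.1)
  expect_equal(zv$z[2, 1, 1, 1], 0.8)
  expect_false(zv$valid[1, 1, 1])
  expect_true(all(is.na(zv$z[1, 1, 1, ])))
  expect_equal(zv$z[2, 2, 1, 2], 2)
  expect_error(normalize_series(cest_series(data, array(0, c(2, 2, 1)), ax)),
               "identically zero")
  # scale invariance: multiplying S and S0 by the same constant leaves Z unchanged
  scaled <- cest_series(data * 37.5, ref * 37.5, ax)
  expect_equal(normalize_series(scaled)$z, zv$z)
})

test_that("noise-free phantom Z-volumes match the ground-truth forward spectra", {
  spec <- small_spec(noise_sigma = 0, b0_amplitude = 0)
  subj <- generate_subject(spec, "CN", seed = 4)
  zvol <- normalize_series(subj$series)
  truth <- forward_zspectrum(cestquant:::gm_pools(), spec$axis)$z
  vox <- which(subj$labels$labels == 3L & zvol$valid)
  nv <- prod(dim(zvol$valid))
  for (j in c(1, 12, 23)) {
    expect_lt(max(abs(zvol$z[vox + (j - 1) * nv] - truth[j])), 1e-10)
  }
})

test_that("spline interpolation is exact at knots and reproduces polynomials", {
  # a 0.5-ppm axis puts every knot exactly on the 0.01-ppm dense grid
  ax <- frequency_axis(seq(-6, 6, by = 0.5))
  offs <- ax$offsets
  z <- forward_zspectrum(default_pool_set(), ax)
  dense <- interpolate_zspectrum(z, grid_step = 0.01)
  at_knots <- sapply(offs, function(o) dense$z[which.min(abs(dense$offsets - o))])
  expect_equal(at_knots, z$z, tolerance = 1e-9)
  lin <- zspectrum(0.5 + 0.02 * offs, offs, reference_offset = -1560)
  dl <- interpolate_zspectrum(lin, 0.01)
  expect_equal(dl$z, 0.5 + 0.02 * dl$offsets, tolerance = 1e-9)
  # dense minimum of a sampled Lorentzian lies near the analytic center
  lor <- forward_zspectrum(pool_set("water", 0.8, 0.2, 3), default_axis())
  dmin <- interpolate_zspectrum(lor, 0.01)
  expect_lt(abs(dmin$offsets[which.min(dmin$z)] - 0.2), 0.03)
  expect_error(interpolate_zspectrum(zspectrum(c(1, 1, 1), c(-1, 0, 1))), "at least 5")
})

test_that("B0 estimation finds known shifts and flags flat spectra", {
  ax <- default_axis()
  for (sh in c(0.3, -0.55, 0)) {
    s <- forward_zspectrum(pool_set("water", 0.8, 0, 3), ax, b0_shift = sh)
    est <- estimate_b0_shift(interpolate_zspectrum(s), window = 1.5)
    expect_lte(abs(est - sh), 0.01 + 1e-9)
  }
  flat <- zspectrum(rep(0.9, 23), ax$offsets)
  dense_flat <- interpolate_zspectrum(flat)
  expect_warning(est <- estimate_b0_shift(dense_flat), "flat")
  expect_equal(as.numeric(est), 0)
  narrow <- interpolate_zspectrum(forward_zspectrum(pool_set("water", 0.8, 0, 3),
                                                    frequency_axis(seq(-1, 1, 0.25))))
  expect_error(estimate_b0_shift(narrow, window = 1.5), "window")
})

test_that("estimate-then-correct round-trips noise-free spectra", {
  # dense sampling isolates the estimator from spline error; the corrected
  # spectrum must match the unshifted one up to sampling tolerance
  ax_fine <- frequency_axis(seq(-6, 6, by = 0.1))
  set.seed(13)
  for (k in 1:100) {
    A <- runif(1, 0.6, 0.9); G <- runif(1, 1.5, 4)
    sh <- runif(1, -0.6, 0.6)
    pools <- pool_set("water", A, 0, G)
    d0 <- interpolate_zspectrum(forward_zspectrum(pools, ax_fine), 0.01)
    d1 <- interpolate_zspectrum(forward_zspectrum(pools, ax_fine, b0_shift = sh), 0.01)
    est <- estimate_b0_shift(d1)
    expect_lte(abs(est - sh), 0.01 + 1e-9)
    cor <- correct_b0(d1, est)
    keep <- !is.na(cor$z)
    expect_lt(max(abs(cor$z[keep] - d0$z[keep])), 0.01)
    # the corrected minimum sits at 0 within one grid step
    expect_lte(abs(cor$offsets[which.min(cor$z)]), 0.02 + 1e-9)
  }
  d <- interpolate_zspectrum(forward_zspectrum(pool_set("water", 0.8, 0, 3),
                                               default_axis()), 0.01)
  expect_equal(correct_b0(d, 0)$z, d$z)
  expect_error(correct_b0(d, 7), "span")
})

test_that("voxel-wise B0 maps track the ground-truth field", {
  spec <- small_spec(noise_sigma = 0.005, b0_amplitude = 0.3)
  subj <- generate_subject(spec, "CN", seed = 9)
  zvol <- normalize_series(subj$series)
  b0 <- compute_b0_map(zvol)
  err <- abs(b0$shift - subj$truth$b0)[b0$valid]
  expect_lt(mean(err), 0.05)
  # invalid voxels flagged, not zero-filled
  expect_true(all(is.na(b0$shift[!b0$valid])))
  # symmetric phantom, zero field, zero noise: map is zero within a grid step
  sym <- generate_subject(symmetric_spec(), "CN", seed = 2)
  b0s <- compute_b0_map(normalize_series(sym$series))
  expect_lte(max(abs(b0s$shift[b0s$valid])), 0.01 + 1e-9)
})
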