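test_that("saturation scheme validates its duration invariant", {
  sch <- saturation_scheme()
  expect_equal(sch$pulse_count * sch$pulse_duration, sch$total_duration)
  expect_equal(sch$total_duration, 2)
  expect_error(saturation_scheme(40, 0.05, 1.2, total_duration = 3), "equal")
  expect_error(saturation_scheme(pulse_count = -1), "positive")
})

test_that("label volumes are deterministic, label-closed and correctly counted", {
  spec <- small_spec()
  a <- generate_label_volume(spec, seed = 7)
  b <- generate_label_volume(spec, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_setequal(setdiff(unique(as.vector(a$labels)), 0L), c(3L, 42L, 4L, 43L))
  # brute-force voxel scan equals the per-class region sizes
  per_class <- vapply(c(3L, 42L, 4L, 43L), function(id) sum(a$labels == id),
                      integer(1))
  expect_equal(sum(a$labels > 0), sum(per_class))
  # bilateral pairs annotated for merging
  expect_setequal(a$lut$hemisphere, c("left", "right"))
  expect_error(generate_label_volume(phantom_spec(grid_shape = c(4, 4, 2),
                                                  tissue_classes = small_classes())),
               "too small")
  expect_error(generate_label_volume(
    phantom_spec(tissue_classes = small_classes()[1])), "two tissue classes")
})

test_that("forward model obeys closed forms and the shift identity", {
  ax <- default_axis()
  one <- pool_set("water", 0.5, 0, 2)
  s <- forward_zspectrum(one, frequency_axis(c(-1, 0, 1)))
  expect_equal(s$z, c(0.75, 0.5, 0.75))
  # b0 shift: spectrum equals the unshifted spectrum evaluated at x - shift
  shifted <- forward_zspectrum(default_pool_set(), ax, b0_shift = 0.3)
  expect_equal(shifted$z, model_zspectrum(default_pool_set(), ax$offsets - 0.3))
  too_much <- pool_set(c("water", "MT"), c(0.9, 0.5), c(0, -2.4), c(3, 25))
  expect_error(forward_zspectrum(too_much, ax), "Z < 0")
})

test_that("Rician noise has the large-SNR and Rayleigh-floor moments", {
  ax <- frequency_axis(c(-3, 0, 3))
  d <- c(50, 50, 4)
  ref <- array(1000, d)
  data <- array(1000, c(d, 3))
  data[, , 1:2, ] <- 0    # half the volume is empty background
  series <- cest_series(data, ref, ax)
  expect_identical(add_noise(series, 0, seed = 1), series)
  noisy <- add_noise(series, 0.01, seed = 1)
  sig <- noisy$data[, , 3:4, ]
  bg <- noisy$data[, , 1:2, ]
  # large-signal voxels: sample sd within 5% of noise_sigma * S0
  expect_lt(abs(stats::sd(sig) - 10) / 10, 0.05)
  # zero-signal voxels acquire the Rayleigh mean sigma * sqrt(pi/2)
  expect_lt(abs(mean(bg) - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.05)
})

test_that("subjects are seeded-deterministic and honor the group effect", {
  spec <- small_spec(noise_sigma = 0.005)
  s1 <- generate_subject(spec, "CI", seed = 11)
  s2 <- generate_subject(spec, "CI", seed = 11)
  expect_identical(s1$series$data, s2$series$data)
  expect_identical(s1$truth$b0, s2$truth$b0)
  # CI amplitude = (1 + effect) * CN amplitude, per pool
  cn <- generate_subject(spec, "CN", seed = 11)
  tci <- s1$truth$classes[["Cerebral-Cortex"]]
  tcn <- cn$truth$classes[["Cerebral-Cortex"]]
  expect_equal(tci$amplitude[tci$name == "amide"],
               0.8 * tcn$amplitude[tcn$name == "amide"])
  expect_equal(tci$amplitude[tci$name == "hydroxyl"],
               1.2 * tcn$amplitude[tcn$name == "hydroxyl"])
  # noise-free, field-free subject: voxel Z equals the forward model exactly
  clean <- generate_subject(small_spec(noise_sigma = 0, b0_amplitude = 0), "CN", seed = 2)
  vox <- which(clean$labels$labels == 3L)[1]
  zvox <- sapply(seq_along(spec$axis$offsets), function(j) {
    clean$series$data[, , , j][vox] / clean$series$reference[vox]
  })
  expect_equal(zvox, forward_zspectrum(cestquant:::gm_pools(), spec$axis)$z,
               tolerance = 1e-12)
})

test_that("cohorts have the right size, labels and within-group structure", {
  spec <- small_spec()
  cohort <- generate_cohort(spec, n_per_group = 4, seed = 5)
  expect_length(cohort, 8)
  groups <- vapply(cohort, function(s) s$truth$group, character(1))
  expect_equal(sum(groups == "CI"), 4)
  expect_length(generate_cohort(spec, 1, seed = 1), 2)
  # same class truth within group, different noise realizations
  expect_equal(cohort[[1]]$truth$classes, cohort[[2]]$truth$classes)
  expect_false(identical(cohort[[1]]$series$data, cohort[[2]]$series$data))
  expect_error(generate_cohort(spec, 0), "at least 1")
})

test_that("phantom output round-trips through NIfTI and is reproducible on disk", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- small_spec()
  s <- generate_subject(spec, "CI", seed = 3, subject_id = "sub-01")
  write_phantom(s, dir1)
  write_phantom(generate_subject(spec, "CI", seed = 3, subject_id = "sub-01"), dir2)
  loaded <- load_cest_series(file.path(dir1, "sub-01_series.nii.gz"),
                             file.path(dir1, "sub-01_series.json"))
  expect_equal(unclass(loaded$data), unclass(s$series$data), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(loaded$axis$offsets, s$series$axis$offsets)
  again <- load_cest_series(file.path(dir2, "sub-01_series.nii.gz"),
                            file.path(dir2, "sub-01_series.json"))
  expect_identical(unclass(loaded$data), unclass(again$data))
  labs <- read_label_volume(file.path(dir1, "sub-01_labels.nii.gz"),
                            file.path(dir1, "sub-01_lut.tsv"))
  expect_identical(labs$labels, s$labels$labels)
  expect_equal(labs$lut$name, s$labels$lut$name)
})

test_that("two-pool Bloch-McConnell model matches closed forms and an ODE oracle", {
  skip_if_not_installed("deSolve")
  ax <- default_axis()
  scheme <- saturation_scheme()
  r1a <- 1 / 1.3; r2a <- 1 / 0.075
  # solute fraction 0 degenerates to the single-pool CW saturation closed form
  z0 <- forward_zspectrum_bm(r1a, r2a, solute = list(rate = 50, fraction = 0,
                                                     offset_ppm = 3.5),
                             scheme = scheme, axis = ax)
  w1 <- 2 * pi * 42.577478518 * scheme$b1rms
  delta <- 2 * pi * 127.74 * ax$offsets
  closed <- r1a * (r2a^2 + delta^2) / (r1a * (r2a^2 + delta^2) + w1^2 * r2a)
  expect_equal(z0$z, closed, tolerance = 1e-9)
  # far off-resonance limit: Z -> 1
  zref <- cestquant:::bm_steady_state_z(-1560, w1, r1a, r2a, 1, 30,
                                        0.001 * 50, 50, 0.001, 3.5, 127.74)
  expect_lt(abs(zref - 1), 1e-3)
  # time propagation of the same equations (independent ODE integration);
  # representative offsets keep the stiff oscillatory integration affordable
  sol <- list(rate = 100, fraction = 0.002, offset_ppm = 3.5, r1 = 1, r2 = 30)
  probe <- ax$offsets[c(1, 5, 9, 12, 15, 19, 23)]
  zss <- forward_zspectrum_bm(r1a, r2a, sol, scheme, frequency_axis(probe))
  ode_z <- vapply(probe, function(off) {
    da <- 2 * pi * 127.74 * (0 - off)
    db <- 2 * pi * 127.74 * (sol$offset_ppm - off)
    ka <- sol$fraction * sol$rate; kb <- sol$rate
    deriv <- function(t, M, parms) {
      list(c(
        -(r2a + ka) * M[1] + da * M[2] + kb * M[4],
        -da * M[1] - (r2a + ka) * M[2] + w1 * M[3] + kb * M[5],
        -w1 * M[2] - (r1a + ka) * M[3] + kb * M[6] + r1a,
        ka * M[1] - (sol$r2 + kb) * M[4] + db * M[5],
        ka * M[2] - db * M[4] - (sol$r2 + kb) * M[5] + w1 * M[6],
        ka * M[3] - w1 * M[5] - (sol$r1 + kb) * M[6] + sol$r1 * sol$fraction
      ))
    }
    out <- deSolve::lsoda(c(0, 0, 1, 0, 0, sol$fraction), c(0, 12), deriv, NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 1e6)
    out[2, 4]
  }, numeric(1))
  expect_lt(max(abs(zss$z - ode_z) / pmax(ode_z, 0.05)), 0.01)
  # non-Lorentzian oracle: the 6-pool fit still describes BM spectra well
  zbm <- forward_zspectrum_bm(r1a, r2a, sol, scheme, ax)
  zbm$b0_shift <- 0
  expect_lt(fit_multipool(zbm)$rmse, 0.02)
  expect_error(forward_zspectrum_bm(r1a, r2a, list(rate = -5, fraction = 0.1,
                                                   offset_ppm = 3.5)), "positive")
})
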