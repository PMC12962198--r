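demo_lut <- function() {
  data.frame(
    label_id = c(3L, 42L, 17L, 53L, 4L, 43L, 10L, 1025L, 2025L, 1023L, 2023L),
    name = c("Left-Cerebral-Cortex", "Right-Cerebral-Cortex",
             "Left-Hippocampus", "Right-Hippocampus",
             "Left-Lateral-Ventricle", "Right-Lateral-Ventricle",
             "Left-Thalamus",
             "ctx-lh-precuneus", "ctx-rh-precuneus",
             "ctx-lh-posteriorcingulate", "ctx-rh-posteriorcingulate"),
    hemisphere = c("left", "right", "left", "right", "left", "right", "left",
                   "left", "right", "left", "right"),
    stringsAsFactors = FALSE
  )
}

test_that("bilateral merging pools left/right label sets and keeps singletons", {
  lut <- demo_lut()
  rs <- merge_bilateral(roiset_from_lut(lut), lut)
  expect_true(all(c("Cerebral-Cortex", "Hippocampus", "ctx-precuneus") %in%
                    names(rs$definitions)))
  expect_setequal(rs$definitions[["ctx-precuneus"]], c(1025L, 2025L))
  expect_equal(rs$definitions[["Left-Thalamus"]], 10L)
  expect_equal(unname(rs$provenance[["Cerebral-Cortex"]]), "bilateral-merged")
  # missing hemisphere annotation for a paired name is a config error
  bad <- lut; bad$hemisphere[bad$label_id == 42L] <- "none"
  expect_error(merge_bilateral(roiset_from_lut(bad), bad), "hemisphere")
  # merged voxel count = left + right (brute force)
  labels <- generate_label_volume(small_spec(), seed = 1)
  rs2 <- roi_voxel_counts(merge_bilateral(roiset_from_lut(labels$lut), labels$lut),
                          labels)
  expect_equal(unname(rs2$n_voxels[["Cerebral-Cortex"]]),
               sum(labels$labels == 3L) + sum(labels$labels == 42L))
})

test_that("composites are set unions with configurable membership", {
  lut <- demo_lut()
  rs <- merge_bilateral(roiset_from_lut(lut), lut)
  comp <- build_composites(rs, list("medial-parietal-lobe" =
                                      c("ctx-precuneus", "ctx-posteriorcingulate")))
  expect_setequal(comp$definitions[["medial-parietal-lobe"]],
                  c(1025L, 2025L, 1023L, 2023L))
  expect_true("ctx-precuneus" %in% names(comp$definitions))  # constituents retained
  # union counts overlaps once
  over <- roi_set(list(a = c(1L, 2L), b = c(2L, 3L)))
  u <- build_composites(over, list(ab = c("a", "b")))
  expect_equal(sort(u$definitions$ab), c(1L, 2L, 3L))
  expect_error(build_composites(rs, list(x = c("ctx-precuneus", "nope"))), "missing")
  expect_identical(build_composites(rs, list()), rs)
  # the default composite table covers the four AD regions
  expect_setequal(names(default_composites()),
                  c("medial-temporal-lobe", "lateral-temporal-lobe",
                    "lateral-parietal-lobe", "medial-parietal-lobe"))
})

test_that("exclusion removes ventricular ROIs and ignores unknowns", {
  lut <- demo_lut()
  rs <- merge_bilateral(roiset_from_lut(lut), lut)
  before <- length(rs$definitions)
  out <- exclude_rois(rs)
  expect_false("Lateral-Ventricle" %in% names(out$definitions))
  expect_equal(length(out$definitions), before - 1)
  expect_identical(exclude_rois(rs, character(0)), rs)
})

test_that("common-ROI intersection respects names and minimum sizes", {
  a <- roi_set(list(x = 1L, y = 2L, z = 3L)); a$n_voxels <- c(x = 10, y = 5, z = 2)
  b <- roi_set(list(x = 1L, z = 3L)); b$n_voxels <- c(x = 8, z = 0)
  common <- common_rois(list(a, b))
  expect_setequal(names(common$definitions), "x")   # y absent in b, z empty in b
  expect_identical(names(common_rois(list(a, a))$definitions), names(a$definitions))
  expect_error(common_rois(list(a, roi_set(list(q = 9L)))), "common")
})

test_that("ROI map means equal brute-force mask averages", {
  labels <- generate_label_volume(small_spec(), seed = 2)
  d <- dim(labels$labels)
  set.seed(9)
  map <- list(map = array(rnorm(prod(d)), d), valid = array(TRUE, d),
              offset = 3.5)
  rs <- roi_voxel_counts(merge_bilateral(roiset_from_lut(labels$lut), labels$lut),
                         labels)
  rows <- roi_mean_map(map, rs, labels, subject_id = "s1", group = "CN",
                       metric_name = "mtrasym_3.5")
  for (i in seq_len(nrow(rows))) {
    sel <- labels$labels %in% rs$definitions[[rows$roi_name[i]]]
    expect_equal(rows$value[i], mean(map$map[sel]))
    expect_equal(rows$n_voxels[i], sum(sel))
  }
  # pooled mean equals the voxel-count-weighted mean of hemisphere means
  left <- labels$labels == 3L; right <- labels$labels == 42L
  pooled <- rows$value[rows$roi_name == "Cerebral-Cortex"]
  weighted <- (sum(left) * mean(map$map[left]) + sum(right) * mean(map$map[right])) /
    (sum(left) + sum(right))
  expect_equal(pooled, weighted)
  # constant map: every mean equals the constant
  cmap <- list(map = array(0.42, d), valid = array(TRUE, d), offset = 2)
  crows <- roi_mean_map(cmap, rs, labels)
  expect_true(all(crows$value == 0.42))
})

test_that("ROI-averaged spectra are offset-wise voxel means", {
  spec <- small_spec(noise_sigma = 0, b0_amplitude = 0)
  subj <- generate_subject(spec, "CN", seed = 5)
  zvol <- normalize_series(subj$series)
  b0 <- compute_b0_map(zvol)
  rs <- roi_set(list(ctx = c(3L, 42L)))
  sp <- roi_mean_zspectrum(zvol, rs, subj$labels, b0)
  # all voxels in the class share one spectrum, so the mean equals it
  nv <- prod(dim(zvol$valid))
  vox <- which(subj$labels$labels == 3L & zvol$valid)[1]
  voxel_z <- zvol$z[vox + (seq_len(23) - 1) * nv]
  shift_steps <- round(b0$shift[vox] / b0$grid_step)
  expect_equal(attr(sp$ctx, "n_voxels"),
               sum(subj$labels$labels %in% c(3L, 42L) & zvol$valid))
  # with zero field every voxel gets the same correction; compare at 0 ppm
  # (grid-aligned sample) where the corrected value is read off the spline
  mid <- which(sp$ctx$offsets == 0)
  dense <- interpolate_zspectrum(zspectrum(voxel_z, zvol$axis$offsets), 0.01)
  expect_equal(sp$ctx$z[mid],
               dense$z[which.min(abs(dense$offsets - b0$shift[vox]))],
               tolerance = 1e-9)
  # two-voxel hand check of the averaging itself
  zv2 <- zvol
  expect_warning(roi_mean_zspectrum(zvol, roi_set(list(empty = 999L)),
                                    subj$labels, b0), "omitted")
})

test_that("ROI averaging attains the expected sqrt(N) standard-error scaling", {
  spec <- small_spec(noise_sigma = 0.005, b0_amplitude = 0)
  n_rep <- 30
  mids <- sapply(seq_len(n_rep), function(k) {
    subj <- generate_subject(spec, "CN", seed = 3000 + k)
    zvol <- normalize_series(subj$series)
    rs <- roi_set(list(ctx = c(3L, 42L)))
    b0 <- compute_b0_map(zvol)
    sp <- roi_mean_zspectrum(zvol, rs, subj$labels, b0)$ctx
    c(n = attr(sp, "n_voxels"), z = sp$z[which(sp$offsets == 0)])
  })
  n_vox <- mids["n", 1]
  se <- stats::sd(mids["z", ])
  # per-offset standard error ~ voxel noise / sqrt(N) within a factor 1.5;
  # the Z value near the water dip is ~0.1 so voxel noise in Z ~ sigma
  expected <- 0.005 / sqrt(n_vox)
  expect_gt(se, expected / 1.5)
  expect_lt(se, expected * 1.5)
})

test_that("label volumes survive a TSV lookup round trip and reject unknown labels", {
  labels <- generate_label_volume(small_spec(), seed = 1)
  expect_error(label_volume(array(99L, c(2, 2, 2)), labels$lut), "missing")
  path_n <- withr::local_tempfile(fileext = ".nii.gz")
  path_l <- withr::local_tempfile(fileext = ".tsv")
  write_label_volume(labels, path_n, path_l)
  back <- read_label_volume(path_n, path_l)
  expect_identical(back$labels, labels$labels)
  expect_equal(back$lut, labels$lut)
})
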