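# Seeded synthetic CEST phantom: geometric "anatomy" with FreeSurfer-style
# labels, per-tissue multi-pool ground truth, a smooth B0 field, Rician noise
# and optional per-offset rigid motion. Stands in for patient data so that
# every pipeline stage is testable against known truth.

#' Run code under a temporary RNG seed, restoring the caller's RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' RF saturation scheme summary
#'
#' Summary statistics of the pulsed saturation train. The default mirrors a
#' clinical 3 T protocol: 40 pulses of 50 ms (2 s total saturation) at a
#' root-mean-square B1 of 1.2 microtesla.
#'
#' @param pulse_count number of saturation pulses.
#' @param pulse_duration single pulse duration in seconds.
#' @param b1rms root-mean-square B1 amplitude in microtesla.
#' @param total_duration total saturation duration in seconds.
#' @return object of class `saturation_scheme`.
#' @export
saturation_scheme <- function(pulse_count = 40, pulse_duration = 0.05,
                              b1rms = 1.2,
                              total_duration = pulse_count * pulse_duration) {
  if (any(c(pulse_count, pulse_duration, b1rms, total_duration) <= 0)) {
    stop("all saturation scheme fields must be positive")
  }
  if (abs(pulse_count * pulse_duration - total_duration) > 1e-9) {
    stop("pulse_count * pulse_duration must equal total_duration")
  }
  structure(list(pulse_count = pulse_count, pulse_duration = pulse_duration,
                 b1rms = b1rms, total_duration = total_duration),
            class = "saturation_scheme")
}

#' Tissue class specification for the phantom
#'
#' A tissue class carries its label id(s), a geometric placement (ellipsoid in
#' fractional grid coordinates; bilateral classes are mirrored about the
#' midline), the ground-truth pool parameters, and an optional multiplicative
#' group effect: signed fractional amplitude change per pool applied to CI
#' subjects.
#'
#' @param name base anatomical name (FreeSurfer style, without hemisphere).
#' @param label_id integer label (left label for bilateral classes).
#' @param label_id_right right-hemisphere label, or NA for midline classes.
#' @param pools a `pool_set` of ground-truth parameters.
#' @param group_effect named numeric vector of fractional amplitude changes
#'   for the CI group (e.g. `c(amide = -0.2)`), or NULL.
#' @param center fractional grid coordinates of the (left) ellipsoid center.
#' @param radius fractional ellipsoid radii.
#' @param s0_scale relative proton-density weight of the class in the
#'   reference volume (CSF brightest); gives the S0 image realistic tissue
#'   contrast without touching Z (both S and S0 scale together).
#' @return object of class `tissue_class`.
#' @export
tissue_class <- function(name, label_id, label_id_right = NA_integer_, pools,
                         group_effect = NULL,
                         center = c(0.3, 0.5, 0.5), radius = c(0.15, 0.3, 0.35),
                         s0_scale = 1) {
  if (label_id <= 0) stop("label_id must be a positive integer")
  if (!is.null(group_effect)) {
    unknown <- setdiff(names(group_effect), pools$name)
    if (length(unknown)) stop("group_effect names unknown: ", paste(unknown, collapse = ", "))
    eff <- apply_group_effect(pools, group_effect)
    if (any(eff$amplitude < 0 | eff$amplitude >= 1)) {
      stop("amplitudes after applying group_effect must remain in [0, 1)")
    }
  }
  structure(list(name = name, label_id = as.integer(label_id),
                 label_id_right = as.integer(label_id_right), pools = pools,
                 group_effect = group_effect, center = center, radius = radius,
                 s0_scale = s0_scale),
            class = "tissue_class")
}

apply_group_effect <- function(pools, group_effect) {
  if (is.null(group_effect)) return(pools)
  out <- pools
  for (nm in names(group_effect)) {
    i <- which(out$name == nm)
    out$amplitude[i] <- out$amplitude[i] * (1 + group_effect[[nm]])
  }
  out
}

gm_pools <- function() default_pool_set()

wm_pools <- function() {
  pool_set(
    name      = c("water", "hydroxyl", "amine", "amide", "rNOE", "MT"),
    amplitude = c(0.72,    0.025,      0.030,   0.045,   0.070,  0.16),
    center    = c(0.0,     1.0,        2.0,     3.5,     -3.5,   -2.4),
    width     = c(3.2,     1.2,        1.8,     2.2,     3.5,    28)
  )
}

csf_pools <- function() {
  pool_set(
    name      = c("water", "hydroxyl", "amine", "amide", "rNOE", "MT"),
    amplitude = c(0.90,    0.005,      0.005,   0.005,   0.005,  0.01),
    center    = c(0.0,     1.0,        2.0,     3.5,     -3.5,   -2.4),
    width     = c(1.4,     1.2,        1.8,     2.2,     3.5,    25)
  )
}

#' Default CI group effect: amplitudes lower at the 2 ppm (amine) and 3.5 ppm
#' (amide) pools and higher at the 1 ppm (hydroxyl) pool.
#' @export
default_group_effect <- function() c(hydroxyl = 0.20, amine = -0.20, amide = -0.20)

#' Default phantom tissue classes
#'
#' Four simple geometric classes with FreeSurfer color-table ids: bilateral
#' cortical shells (3/42), bilateral white-matter cores (2/41), bilateral
#' hippocampi (17/53), and bilateral lateral ventricles (4/43, CSF-like, no
#' group effect; excluded from analysis by the default ventricular exclusion
#' list).
#' @return list of `tissue_class` objects.
#' @export
default_tissue_classes <- function() {
  eff <- default_group_effect()
  list(
    tissue_class("Cerebral-Cortex", 3L, 42L, gm_pools(), eff,
                 center = c(0.28, 0.50, 0.50), radius = c(0.23, 0.40, 0.44),
                 s0_scale = 0.85),
    tissue_class("Cerebral-White-Matter", 2L, 41L, wm_pools(), eff,
                 center = c(0.28, 0.50, 0.50), radius = c(0.13, 0.26, 0.30),
                 s0_scale = 0.70),
    tissue_class("Hippocampus", 17L, 53L, gm_pools(), eff,
                 center = c(0.28, 0.66, 0.42), radius = c(0.08, 0.10, 0.18),
                 s0_scale = 0.85),
    tissue_class("Lateral-Ventricle", 4L, 43L, csf_pools(), NULL,
                 center = c(0.40, 0.40, 0.55), radius = c(0.06, 0.12, 0.20),
                 s0_scale = 1.0)
  )
}

#' Phantom specification
#'
#' Defines the synthetic acquisition: grid and voxel geometry (defaults mirror
#' the emulated protocol: 2 x 2 mm in-plane, 5 mm slices, 10 slices), the
#' saturation axis (23 equally spaced offsets on \[-6, +6\] ppm plus the
#' -1560 ppm reference), tissue classes with ground truth, the B0 field model
#' (smooth low-order polynomial plus Gaussian-filtered random field, bounded
#' by `b0_amplitude`), the Rician noise level as a fraction of S0, and an
#' optional per-offset rigid motion schedule.
#'
#' @param grid_shape integer vector (x, y, z) of voxels.
#' @param voxel_size mm, length 3.
#' @param axis a [frequency_axis()].
#' @param tissue_classes list of [tissue_class()] objects.
#' @param b0_amplitude maximum |B0| shift in ppm (default 0.3).
#' @param b0_smoothness Gaussian smoothing scale of the random field component
#'   in voxels (default 4).
#' @param noise_sigma Rician noise standard deviation as a fraction of S0
#'   (default 0.005).
#' @param motion_schedule NULL, or a list of [rigid_transform()] objects, one
#'   per offset (in sorted-offset order).
#' @param s0 reference-volume tissue intensity in arbitrary units.
#' @param s0_texture amplitude of the smooth within-class proton-density
#'   heterogeneity field (fraction of the class S0, default 0.1); real tissue
#'   is not piecewise constant, and this texture is what makes saturated
#'   volumes registerable.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 10), voxel_size = c(2, 2, 5),
                         axis = default_axis(),
                         tissue_classes = default_tissue_classes(),
                         b0_amplitude = 0.3, b0_smoothness = 4,
                         noise_sigma = 0.005, motion_schedule = NULL,
                         s0 = 1000, s0_texture = 0.1) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (b0_amplitude < 0) stop("b0_amplitude must be non-negative")
  ids <- unlist(lapply(tissue_classes, function(cl) {
    c(cl$label_id, if (!is.na(cl$label_id_right)) cl$label_id_right)
  }))
  if (anyDuplicated(ids)) stop("label ids must be unique across tissue classes")
  if (!is.null(motion_schedule) && length(motion_schedule) != length(axis$offsets)) {
    stop("motion_schedule must have one transform per offset")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 axis = axis, tissue_classes = tissue_classes,
                 b0_amplitude = b0_amplitude, b0_smoothness = b0_smoothness,
                 noise_sigma = noise_sigma, motion_schedule = motion_schedule,
                 s0 = s0, s0_texture = s0_texture),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid_shape, center_frac, radius_frac) {
  cx <- center_frac * (grid_shape - 1) + 1
  r <- radius_frac * grid_shape
  if (any(r < 1)) stop("grid too small to place all tissue classes")
  x <- ((seq_len(grid_shape[1]) - cx[1]) / r[1])^2
  y <- ((seq_len(grid_shape[2]) - cx[2]) / r[2])^2
  z <- ((seq_len(grid_shape[3]) - cx[3]) / r[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

#' Generate the phantom label volume
#'
#' Places each tissue class as one ellipsoid (or a mirrored left/right pair
#' for bilateral classes) on the grid; later classes overwrite earlier ones,
#' so listing coarse structures first yields nested anatomy (e.g. a
#' white-matter core carved out of a cortical shell). Deterministic given the
#' spec and seed.
#'
#' @param spec a `phantom_spec` with at least two tissue classes.
#' @param seed integer seed.
#' @return object of class `label_volume` (see [label_volume()]).
#' @export
generate_label_volume <- function(spec, seed = 1L) {
  if (length(spec$tissue_classes) < 2L) stop("need at least two tissue classes")
  labels <- array(0L, spec$grid_shape)
  lut <- list()
  for (cl in spec$tissue_classes) {
    left <- ellipsoid_mask(spec$grid_shape, cl$center, cl$radius)
    if (!is.na(cl$label_id_right)) {
      rc <- cl$center; rc[1] <- 1 - rc[1]
      right <- ellipsoid_mask(spec$grid_shape, rc, cl$radius)
      labels[left] <- cl$label_id
      labels[right] <- cl$label_id_right
      lut[[length(lut) + 1L]] <- data.frame(
        label_id = c(cl$label_id, cl$label_id_right),
        name = paste0(c("Left-", "Right-"), cl$name),
        hemisphere = c("left", "right"), stringsAsFactors = FALSE)
    } else {
      labels[left] <- cl$label_id
      lut[[length(lut) + 1L]] <- data.frame(
        label_id = cl$label_id, name = cl$name, hemisphere = "none",
        stringsAsFactors = FALSE)
    }
  }
  label_volume(labels, do.call(rbind, lut),
               affine = diag(c(spec$voxel_size, 1)))
}

#' Forward Z-spectrum from ground-truth pools
#'
#' `Z(x) = 1 - sum_i L_i(x - b0_shift)`: the multi-pool Lorentzian model used
#' generatively, with an optional B0 shift of the whole spectrum. The signal
#' at the far off-resonance reference offset is 1 by construction.
#'
#' @param pools a `pool_set`.
#' @param axis a [frequency_axis()].
#' @param b0_shift B0 offset in ppm (default 0).
#' @return an (uncorrected) `zspectrum` on the axis offsets.
#' @export
forward_zspectrum <- function(pools, axis, b0_shift = 0) {
  z <- model_zspectrum(pools, axis$offsets - b0_shift)
  if (any(z < 0)) {
    stop("pool amplitudes produce Z < 0 on the axis; reduce amplitudes")
  }
  zspectrum(z, axis$offsets, axis$reference_offset)
}

gaussian_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = dim(ap)[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate edges
      out <- out + k[j] * m[src, , drop = FALSE]
    }
    aperm(array(out, dim(ap)), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

generate_b0_field <- function(spec) {
  # caller must have seeded the RNG
  d <- spec$grid_shape
  if (spec$b0_amplitude == 0) return(array(0, d))
  xs <- seq(-1, 1, length.out = d[1])
  ys <- seq(-1, 1, length.out = d[2])
  zs <- seq(-1, 1, length.out = d[3])
  a <- stats::runif(3, -1, 1)
  planar <- outer(outer(a[1] * xs, a[2] * ys, `+`), a[3] * zs, `+`)
  bumpy <- gaussian_smooth_3d(array(stats::rnorm(prod(d)), d), spec$b0_smoothness)
  raw <- planar / max(abs(planar)) + bumpy / max(abs(bumpy))
  raw / max(abs(raw)) * spec$b0_amplitude
}

#' Add Rician (magnitude MRI) noise to a series
#'
#' Each intensity `v` is replaced by `|(v + n1) + i n2|` with `n1`, `n2`
#' zero-mean Gaussian of standard deviation `noise_sigma * S0`, where S0 is
#' the robust maximum (99th percentile) of the reference volume. The
#' reference volume receives the same noise model. `noise_sigma = 0` is the
#' identity.
#'
#' @param series a `cest_series`.
#' @param noise_sigma noise standard deviation as a fraction of S0.
#' @param seed integer seed.
#' @return a new `cest_series`.
#' @export
add_noise <- function(series, noise_sigma, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (noise_sigma == 0) return(series)
  s0 <- as.numeric(stats::quantile(series$reference, 0.99, names = FALSE))
  sd <- noise_sigma * s0
  with_seed(seed, {
    rician <- function(v) {
      n <- length(v)
      sqrt((v + stats::rnorm(n, sd = sd))^2 + stats::rnorm(n, sd = sd)^2)
    }
    data <- array(rician(series$data), dim(series$data))
    reference <- array(rician(series$reference), dim(series$reference))
    cest_series(data, reference, series$axis, affine = series$affine,
                mask = series$mask)
  })
}

#' Generate one synthetic subject
#'
#' Per-voxel spectra follow the voxel's tissue-class ground truth (with the
#' class group effect applied for CI subjects), shifted by a smooth random B0
#' field, optionally moved per offset by the motion schedule, and degraded by
#' Rician noise.
#'
#' @param spec a `phantom_spec`.
#' @param group `"CI"` or `"CN"`.
#' @param seed integer seed; all randomness (B0 field, noise) derives from it.
#' @param subject_id optional id string.
#' @return list with `series` (a `cest_series`), `labels` (a
#'   `label_volume`), and `truth` (class ground truth after group effect, B0
#'   field, motion schedule, group, id).
#' @export
generate_subject <- function(spec, group = c("CN", "CI"), seed = 1L,
                             subject_id = NULL) {
  group <- match.arg(group)
  labels <- generate_label_volume(spec, seed)
  d <- spec$grid_shape
  offsets <- spec$axis$offsets
  b0 <- with_seed(seed, generate_b0_field(spec))
  texture <- if ((spec$s0_texture %||% 0) > 0) {
    raw <- with_seed(seed + 2L,
                     gaussian_smooth_3d(array(stats::rnorm(prod(d)), d), 2))
    1 + spec$s0_texture * raw / max(abs(raw))
  } else array(1, d)
  z4 <- array(0, c(d, length(offsets)))
  s0_map <- array(0, d)
  truth_classes <- list()
  nv <- prod(d)
  for (cl in spec$tissue_classes) {
    pools <- if (group == "CI") apply_group_effect(cl$pools, cl$group_effect) else cl$pools
    truth_classes[[cl$name]] <- pools
    ids <- c(cl$label_id, if (!is.na(cl$label_id_right)) cl$label_id_right)
    vox <- which(labels$labels %in% ids)
    if (!length(vox)) next
    s0_map[vox] <- spec$s0 * (cl$s0_scale %||% 1) * texture[vox]
    shift <- b0[vox]
    for (j in seq_along(offsets)) {
      x <- offsets[j] - shift
      zj <- rep(1, length(vox))
      for (i in seq_len(nrow(pools))) {
        zj <- zj - lorentzian_value(pools$amplitude[i], pools$center[i],
                                    pools$width[i], x)
      }
      if (any(zj < 0)) stop("pool amplitudes produce Z < 0; reduce amplitudes")
      z4[vox + (j - 1) * nv] <- zj
    }
  }
  reference <- s0_map
  data <- z4 * as.vector(s0_map)
  affine <- diag(c(spec$voxel_size, 1))
  if (!is.null(spec$motion_schedule)) {
    for (j in seq_along(offsets)) {
      t_j <- spec$motion_schedule[[j]]
      if (!is_identity_transform(t_j)) {
        data[, , , j] <- resample_volume(data[, , , j], t_j, affine = affine,
                                         interpolation = "linear")
      }
    }
  }
  series <- cest_series(data, reference, spec$axis, affine = affine)
  series <- add_noise(series, spec$noise_sigma, seed = seed + 1L)
  list(
    series = series, labels = labels,
    truth = list(classes = truth_classes, b0 = b0,
                 motion_schedule = spec$motion_schedule, group = group,
                 subject_id = subject_id %||% sprintf("sub-%s-%03d", group, seed),
                 s0 = spec$s0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a seeded cohort of synthetic subjects
#'
#' `2 * n_per_group` subjects (default 4 per group, matching a small pilot
#' design) with distinct derived seeds: subjects share the class ground truth
#' of their group and differ in B0 field and noise realization.
#'
#' @param spec a `phantom_spec`.
#' @param n_per_group subjects per group (default 4).
#' @param seed integer master seed.
#' @return list of subjects (as from [generate_subject()]), CI first.
#' @export
generate_cohort <- function(spec, n_per_group = 4, seed = 1L) {
  if (n_per_group < 1) stop("n_per_group must be at least 1")
  n <- 2L * n_per_group
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 2L, n))
  groups <- rep(c("CI", "CN"), each = n_per_group)
  lapply(seq_len(n), function(i) {
    id <- sprintf("sub-%s%02d", groups[i], ((i - 1) %% n_per_group) + 1)
    generate_subject(spec, groups[i], seed = seeds[i], subject_id = id)
  })
}

#' Write a phantom subject to disk
#'
#' Emits the 4D series + JSON sidecar + reference volume (via
#' [write_cest_series()]), the integer label volume, the TSV label lookup
#' table, the B0 ground-truth field as NIfTI, and a JSON ground-truth file
#' with the per-class pool parameters and the motion schedule.
#'
#' @param subject a subject list from [generate_subject()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject$truth$subject_id
  prefix <- file.path(dir, id)
  write_cest_series(subject$series, prefix)
  write_label_volume(subject$labels, paste0(prefix, "_labels.nii.gz"),
                     paste0(prefix, "_lut.tsv"))
  b0img <- RNifti::asNifti(subject$truth$b0)
  RNifti::pixdim(b0img) <- abs(diag(subject$series$affine)[1:3])
  RNifti::writeNifti(b0img, paste0(prefix, "_b0_truth.nii.gz"))
  truth <- list(
    subject_id = id, group = subject$truth$group, s0 = subject$truth$s0,
    classes = lapply(subject$truth$classes, function(p) as.list(as.data.frame(p))),
    motion_schedule = if (is.null(subject$truth$motion_schedule)) NULL
      else lapply(subject$truth$motion_schedule, unclass)
  )
  jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
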