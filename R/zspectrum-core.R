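#' Multi-offset CEST volume series
#'
#' Container for a 4D saturation series (x, y, z, offset) plus the
#' far off-resonance reference volume S0 used for normalization. Volumes are
#' stored with the 4th axis in sorted-offset order regardless of acquisition
#' order (the acquisition order lives in the `frequency_axis`).
#'
#' @param data 4D numeric array, 4th axis in the sorted-offset order of `axis`.
#' @param reference 3D numeric array on the same grid.
#' @param axis a [frequency_axis()].
#' @param affine 4x4 voxel-to-world matrix (mm); default scales by
#'   `voxel_size` with a zero origin.
#' @param voxel_size length-3 voxel dimensions in mm (used when `affine` is
#'   not given).
#' @param mask optional 3D logical array.
#' @return object of class `cest_series`.
#' @export
cest_series <- function(data, reference, axis, affine = NULL,
                        voxel_size = c(2, 2, 5), mask = NULL) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (!identical(dim(data)[1:3], dim(reference)[1:3])) {
    stop("data and reference must share the same 3D grid")
  }
  if (dim(data)[4] != length(axis$offsets)) {
    stop(sprintf("offset-count mismatch: %d volumes vs %d axis offsets",
                 dim(data)[4], length(axis$offsets)))
  }
  if (any(data < 0) || any(reference < 0)) stop("intensities must be non-negative")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(
    list(data = data, reference = reference, axis = axis, affine = affine,
         mask = mask),
    class = "cest_series"
  )
}

#' @export
print.cest_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_series> grid %dx%dx%d, %d offsets\n", d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Write a CEST series to NIfTI with a JSON sidecar
#'
#' The 4D series is written with volumes in acquisition order; the sidecar
#' lists the ppm value of each volume in that order, the reference offset and
#' the voxel-to-world affine. The reference volume is written as a separate
#' 3D NIfTI.
#'
#' @param series a `cest_series`.
#' @param prefix output path prefix; writes `<prefix>_series.nii.gz`,
#'   `<prefix>_series.json`, `<prefix>_ref.nii.gz`.
#' @return invisibly, the sidecar path.
#' @export
write_cest_series <- function(series, prefix) {
  acq <- order(series$axis$sort_index)   # sorted -> acquisition order
  data_acq <- series$data[, , , acq, drop = FALSE]
  vox <- abs(diag(series$affine)[1:3])
  img4 <- RNifti::asNifti(data_acq)
  RNifti::pixdim(img4) <- vox
  RNifti::writeNifti(img4, paste0(prefix, "_series.nii.gz"))
  img3 <- RNifti::asNifti(series$reference)
  RNifti::pixdim(img3) <- vox
  RNifti::writeNifti(img3, paste0(prefix, "_ref.nii.gz"))
  sidecar <- list(
    offsets_ppm = series$axis$offsets[acq],
    reference_offset_ppm = series$axis$reference_offset,
    reference_file = basename(paste0(prefix, "_ref.nii.gz")),
    affine = series$affine
  )
  jsonlite::write_json(sidecar, paste0(prefix, "_series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, "_series.json"))
}

#' Load a CEST series from NIfTI + JSON sidecar
#'
#' Offsets are re-sorted internally (ascending ppm) while preserving the data
#' correspondence; the acquisition order is retained on the axis.
#'
#' @param series_path path to the 4D NIfTI.
#' @param sidecar_path path to the JSON sidecar listing `offsets_ppm` in
#'   acquisition order, `reference_offset_ppm` and `reference_file`.
#' @param reference_path path to the 3D reference NIfTI; defaults to the
#'   sidecar's `reference_file` resolved next to the sidecar.
#' @return a `cest_series`.
#' @export
load_cest_series <- function(series_path, sidecar_path, reference_path = NULL) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$offsets_ppm)) stop("sidecar lacks offsets_ppm")
  img <- RNifti::readNifti(series_path)
  data <- unclass(img)[, , , , drop = FALSE]
  attributes(data) <- list(dim = dim(data))
  if (dim(data)[4] != length(side$offsets_ppm)) {
    stop(sprintf("offset-count mismatch: %d volumes vs %d sidecar offsets",
                 dim(data)[4], length(side$offsets_ppm)))
  }
  if (is.null(side$reference_offset_ppm)) stop("sidecar lacks the reference offset")
  if (is.null(reference_path)) {
    if (is.null(side$reference_file)) stop("no reference volume supplied")
    reference_path <- file.path(dirname(sidecar_path), side$reference_file)
  }
  ref <- RNifti::readNifti(reference_path)
  reference <- unclass(ref)[, , , drop = TRUE]
  attributes(reference) <- list(dim = dim(reference))
  axis <- frequency_axis(side$offsets_ppm, side$reference_offset_ppm)
  affine <- if (!is.null(side$affine)) matrix(unlist(side$affine), 4, 4)
            else structure(RNifti::xform(img), dimnames = NULL)
  cest_series(data[, , , axis$sort_index, drop = FALSE], reference, axis,
              affine = affine)
}

#' Normalize a series to a Z-volume
#'
#' `Z = S(offset) / S0` per voxel. Voxels whose reference intensity falls
#' below `s0_floor` times the robust maximum of S0 (99th percentile) are
#' marked invalid; Z values are clipped to `[0, 2]` to guard against division
#' blow-ups near the mask edge.
#'
#' @param series a `cest_series`.
#' @param s0_floor fraction of the robust S0 maximum below which a voxel is
#'   invalid (default 0.1).
#' @return object of class `zvolume`: list with `z` (4D, NA where invalid),
#'   `valid` (3D logical), `axis`, `affine`.
#' @export
normalize_series <- function(series, s0_floor = 0.1) {
  s0 <- series$reference
  if (all(s0 == 0)) stop("degenerate input: reference volume is identically zero")
  robmax <- as.numeric(stats::quantile(s0, 0.99, names = FALSE))
  valid <- s0 > pmax(s0_floor * robmax, 0) & s0 > 0
  if (!is.null(series$mask)) valid <- valid & series$mask
  d <- dim(series$data)
  z <- series$data / as.vector(s0)   # recycles S0 across the 4th axis
  z[z > 2] <- 2
  z[!is.finite(z)] <- NA_real_
  invalid_idx <- which(!valid)
  if (length(invalid_idx)) {
    nvol <- d[4]; nv <- prod(d[1:3])
    z[rep(invalid_idx, nvol) + rep((0:(nvol - 1)) * nv, each = length(invalid_idx))] <- NA_real_
  }
  structure(list(z = z, valid = valid, axis = series$axis, affine = series$affine),
            class = "zvolume")
}

#' @export
print.zvolume <- function(x, ...) {
  cat(sprintf("<zvolume> grid %s, %d offsets, %d valid voxels\n",
              paste(dim(x$valid), collapse = "x"), length(x$axis$offsets),
              sum(x$valid)))
  invisible(x)
}

# ---- cubic-spline machinery ------------------------------------------------

.op_cache <- new.env(parent = emptyenv())

dense_grid <- function(offsets, grid_step) {
  seq(min(offsets), max(offsets), by = grid_step)
}

# Cubic-spline interpolation is linear in the sampled values for fixed knots,
# so voxel-wise interpolation reduces to one dense-by-knots operator matrix
# applied to the whole voxel block at once.
spline_operator <- function(offsets, grid_step) {
  key <- paste0(format(grid_step, digits = 12), "|",
                paste(format(offsets, digits = 12), collapse = ","))
  op <- .op_cache[[key]]
  if (!is.null(op)) return(op)
  grid <- dense_grid(offsets, grid_step)
  n <- length(offsets)
  op <- matrix(0, length(grid), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    op[, j] <- stats::splinefun(offsets, e, method = "fmm")(grid)
  }
  attr(op, "grid") <- grid
  .op_cache[[key]] <- op
  op
}

#' Interpolate a sampled Z-spectrum onto a dense grid
#'
#' Interpolating cubic spline (no smoothing) through the sampled offsets,
#' evaluated on a uniform grid spanning the sampled range.
#'
#' @param z a `zspectrum` with at least 5 sampled offsets.
#' @param grid_step grid spacing in ppm (default 0.01).
#' @return a dense `zspectrum` on the uniform grid.
#' @export
interpolate_zspectrum <- function(z, grid_step = 0.01) {
  if (length(z$offsets) < 5L) stop("need at least 5 sampled offsets to interpolate")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (is.unsorted(z$offsets, strictly = TRUE)) stop("axis must be strictly monotone")
  grid <- dense_grid(z$offsets, grid_step)
  dense <- stats::splinefun(z$offsets, z$z, method = "fmm")(grid)
  out <- zspectrum(pmax(dense, 0), grid, z$reference_offset, z$b0_shift)
  attr(out, "grid_step") <- grid_step
  out
}

#' Estimate the B0 shift of a spectrum by the minimum-of-Z approach
#'
#' The direct water saturation dip is the deepest feature near 0 ppm, so the
#' voxel's B0 offset is read off as the location of the dense spectrum's
#' minimum within a search window around 0. Ties are broken toward the
#' smaller absolute shift. A flat spectrum within the window yields 0 with a
#' warning.
#'
#' @param dense a dense `zspectrum` (from [interpolate_zspectrum()]).
#' @param window half-width of the search window in ppm (default 1.5); the
#'   dense grid must cover `[-window, +window]`.
#' @return the estimated shift in ppm.
#' @export
estimate_b0_shift <- function(dense, window = 1.5) {
  x <- dense$offsets
  if (min(x) > -window || max(x) < window) {
    stop("dense grid does not cover the B0 search window")
  }
  sel <- which(x >= -window & x <= window)
  zz <- dense$z[sel]
  if (max(zz) - min(zz) < .Machine$double.eps * 10) {
    warning("flat spectrum within the B0 search window; returning 0")
    return(structure(0, flat = TRUE))
  }
  cand <- sel[zz == min(zz)]
  x[cand[which.min(abs(x[cand]))]]
}

#' Apply a B0 correction to a dense spectrum
#'
#' Translates the frequency axis by `-shift` and re-evaluates the spectrum on
#' the canonical grid, so that the water minimum moves to 0 ppm. Grid points
#' whose source lies outside the sampled span are marked missing (NA) rather
#' than extrapolated.
#'
#' @param dense a dense `zspectrum`.
#' @param shift B0 shift in ppm (from [estimate_b0_shift()]).
#' @return a dense `zspectrum` with `b0_shift` set and NA outside support.
#' @export
correct_b0 <- function(dense, shift) {
  span <- diff(range(dense$offsets))
  if (abs(shift) >= span / 2) stop("|shift| must be smaller than half the sampled span")
  zc <- if (shift == 0) dense$z else
    stats::approx(dense$offsets, dense$z, xout = dense$offsets + shift,
                  method = "linear", rule = 1)$y
  out <- zspectrum(zc, dense$offsets, dense$reference_offset, b0_shift = shift)
  attr(out, "grid_step") <- attr(dense, "grid_step")
  out
}

# Dense spectra for all valid voxels at once: returns list(dense = matrix
# [n_grid x n_valid], grid, idx = linear indices of the valid voxels).
dense_voxel_matrix <- function(zvol, grid_step = 0.01) {
  op <- spline_operator(zvol$axis$offsets, grid_step)
  idx <- which(zvol$valid)
  d <- dim(zvol$z)
  nv <- prod(d[1:3])
  zm <- matrix(zvol$z, nrow = nv, ncol = d[4])[idx, , drop = FALSE]
  complete <- stats::complete.cases(zm)
  idx <- idx[complete]
  dense <- op %*% t(zm[complete, , drop = FALSE])
  dense[dense < 0] <- 0
  list(dense = dense, grid = attr(op, "grid"), idx = idx)
}

#' Voxel-wise B0 map by the minimum-of-Z-spectrum approach
#'
#' Applies [estimate_b0_shift()] to every valid voxel (via a shared
#' spline-operator fast path). Invalid voxels are excluded (NA), not
#' zero-filled.
#'
#' @param zvol a `zvolume` from [normalize_series()].
#' @param window search half-window in ppm (default 1.5).
#' @param grid_step dense grid step in ppm (default 0.01).
#' @return object of class `b0_map`: list with `shift` (3D, ppm, NA where
#'   invalid), `valid` (3D logical), `window`, `grid_step`.
#' @export
compute_b0_map <- function(zvol, window = 1.5, grid_step = 0.01) {
  if (!any(zvol$valid)) stop("no valid voxels in the Z-volume")
  dm <- dense_voxel_matrix(zvol, grid_step)
  sel <- which(dm$grid >= -window & dm$grid <= window)
  if (!length(sel)) stop("dense grid does not cover the B0 search window")
  ord <- sel[order(abs(dm$grid[sel]))]       # ties resolve toward |shift| -> 0
  sub <- dm$dense[ord, , drop = FALSE]
  amin <- max.col(-t(sub), ties.method = "first")
  shifts <- dm$grid[ord[amin]]
  d3 <- dim(zvol$valid)
  shift <- array(NA_real_, d3)
  shift[dm$idx] <- shifts
  valid <- array(FALSE, d3)
  valid[dm$idx] <- TRUE
  structure(list(shift = shift, valid = valid, window = window,
                 grid_step = grid_step, affine = zvol$affine),
            class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  cat(sprintf("<b0_map> %d valid voxels, shift range [%.3f, %.3f] ppm\n",
              sum(x$valid), min(x$shift, na.rm = TRUE), max(x$shift, na.rm = TRUE)))
  invisible(x)
}
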