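# Rigid (6 degrees of freedom) motion correction of the multi-offset series:
# each saturation volume is zero-padded along z (the acquisition covers only a
# slab, so through-plane motion needs headroom), registered to the reference
# volume under a mutual-information similarity, and resampled once from the
# original data.

#' Rigid transform (6 degrees of freedom)
#'
#' Parameterized by three translations (mm), three rotations (degrees, about
#' the x/y/z world axes, applied as Rz Ry Rx), and a rotation center in world
#' coordinates. The transform maps a point `p` of the fixed space to the
#' sampling point `R (p - c) + c + t` of the moving space (pull-back
#' convention: [resample_volume()] with this transform shifts image content by
#' approximately `-t`).
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, degrees.
#' @param center length-3 numeric, world mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3, length(center) == 3)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

is_identity_transform <- function(t) {
  all(abs(c(t$translation, t$rotation)) < 1e-12)
}

euler_to_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cg <- cos(r[3]); sg <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

matrix_to_euler <- function(R) {
  beta <- asin(-R[3, 1])
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

tf_matrix <- function(t) {
  R <- euler_to_matrix(t$rotation)
  d <- t$center + t$translation - R %*% t$center
  rbind(cbind(R, d), c(0, 0, 0, 1))
}

matrix_to_tf <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  d <- M[1:3, 4]
  translation <- as.numeric(d - center + R %*% center)
  rigid_transform(translation, matrix_to_euler(R), center)
}

#' Compose and invert rigid transforms
#'
#' `tf_compose(a, b)` is the transform equivalent to applying `b` then `a`
#' (matrix product of the point maps); `tf_invert(a)` is the inverse map.
#' Both preserve the center of the first argument.
#'
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
tf_compose <- function(a, b) {
  matrix_to_tf(tf_matrix(a) %*% tf_matrix(b), center = a$center)
}

#' @rdname tf_compose
#' @export
tf_invert <- function(a) {
  matrix_to_tf(solve(tf_matrix(a)), center = a$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.2f, %.2f, %.2f) mm, r = (%.2f, %.2f, %.2f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

#' Zero-pad a volume along the slice axis
#'
#' Adds `n_slices` all-zero slices to the top and bottom of the volume so that
#' partial-coverage slabs moving through-plane can still be registered. The
#' affine origin is translated so that the original voxels keep their world
#' coordinates.
#'
#' @param vol 3D array.
#' @param n_slices slices to add at each end (default 2).
#' @param affine 4x4 voxel-to-world matrix.
#' @return list with `data` (padded array) and `affine` (adjusted).
#' @export
zero_pad_slices <- function(vol, n_slices = 2, affine = diag(4)) {
  if (n_slices < 0) stop("n_slices must be non-negative")
  if (n_slices == 0) return(list(data = vol, affine = affine))
  d <- dim(vol)
  out <- array(0, c(d[1], d[2], d[3] + 2 * n_slices))
  out[, , n_slices + seq_len(d[3])] <- vol
  affine[, 4] <- affine %*% c(0, 0, -n_slices, 1)
  list(data = out, affine = affine)
}

# world coordinate of 1-based voxel index (i,j,k): A %*% (i-1, j-1, k-1, 1)
voxel_world_coords <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1,
                               j = seq_len(dim3[2]) - 1,
                               k = seq_len(dim3[3]) - 1))
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- numeric(length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  lin <- function(i, j, k) vol[cbind(i, j, k)]
  v <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       lin(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
       lin(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
       lin(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
       lin(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
       lin(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
       lin(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
       lin(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[inside] <- v
  out
}

nearest_sample <- function(vol, coords) {
  d <- dim(vol)
  i <- round(coords[, 1]); j <- round(coords[, 2]); k <- round(coords[, 3])
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- numeric(nrow(coords))
  out[inside] <- vol[cbind(i[inside], j[inside], k[inside])]
  out
}

#' Resample a volume under a rigid transform
#'
#' Pull-back resampling on the fixed grid: the output value at each fixed
#' voxel is sampled from the moving volume at `R (p - c) + c + t`. Linear
#' interpolation for intensity volumes, nearest neighbor for label volumes
#' (which keeps the label value set closed). Points mapping outside the
#' moving volume become 0.
#'
#' @param vol 3D array (the moving volume).
#' @param transform a `rigid_transform`.
#' @param affine 4x4 voxel-to-world matrix of `vol`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fixed_dim,fixed_affine output grid (defaults: the moving grid).
#' @return 3D array on the fixed grid.
#' @export
resample_volume <- function(vol, transform, affine = diag(4),
                            interpolation = c("linear", "nearest"),
                            fixed_dim = dim(vol), fixed_affine = affine) {
  interpolation <- match.arg(interpolation)
  P <- voxel_world_coords(fixed_dim, fixed_affine)
  M <- tf_matrix(transform)
  Q <- t(M %*% rbind(t(P), 1))[, 1:3, drop = FALSE]
  Vm <- t(solve(affine) %*% rbind(t(Q), 1))[, 1:3, drop = FALSE] + 1  # 1-based
  vals <- if (interpolation == "linear") trilinear_sample(vol, Vm)
          else nearest_sample(vol, Vm)
  array(vals, fixed_dim)
}

# soft (partial-volume) joint histogram mutual information
mi_similarity <- function(a, b, bins = 32) {
  a <- as.vector(a); b <- as.vector(b)
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ua <- (a - ra[1]) / diff(ra) * (bins - 1) + 1
  ub <- (b - rb[1]) / diff(rb) * (bins - 1) + 1
  ia <- pmin(floor(ua), bins - 1); ib <- pmin(floor(ub), bins - 1)
  fa <- ua - ia; fb <- ub - ib
  H <- matrix(0, bins, bins)
  acc <- function(i, j, w) {
    s <- rowsum(w, (j - 1) * bins + i)
    H[as.integer(rownames(s))] <<- H[as.integer(rownames(s))] + s[, 1]
  }
  acc(ia, ib, (1 - fa) * (1 - fb))
  acc(ia + 1, ib, fa * (1 - fb))
  acc(ia, ib + 1, (1 - fa) * fb)
  acc(ia + 1, ib + 1, fa * fb)
  p <- H / sum(H)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

smooth_volume <- function(vol, sigma = 1) gaussian_smooth_3d(vol, sigma)

#' Rigid registration by mutual information
#'
#' Estimates the 6-parameter rigid transform that aligns `moving` to `fixed`
#' by maximizing a soft-histogram mutual information between the fixed volume
#' and the resampled moving volume. Multi-resolution: a smoothed pass seeds a
#' full-resolution Nelder-Mead refinement. Fully deterministic.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param affine 4x4 voxel-to-world matrix shared by both volumes.
#' @param bins histogram bins (default 32).
#' @param max_iter iterations per optimization pass.
#' @return a `rigid_transform` `t` such that `resample_volume(moving, t)`
#'   approximates `fixed`.
#' @export
register_rigid <- function(moving, fixed, affine = diag(4), bins = 32,
                           max_iter = 400) {
  if (all(moving == 0) || all(fixed == 0)) stop("registration error: empty volume")
  if (!identical(dim(moving), dim(fixed))) stop("volumes must share a grid")
  center <- as.numeric(affine %*% c((dim(fixed) - 1) / 2, 1))[1:3]
  # light quadratic penalties (MI units per deg^2 / mm^2) pin the nearly flat
  # directions of thin-slab volumes toward zero motion. Through-plane
  # rotations (about x and y) are barely identifiable from ten smooth slices
  # and get a ten-fold stronger penalty than the well-determined in-plane
  # rotation; translations get a token penalty. All are small against the MI
  # scale, so well-determined parameters are biased by well under a tenth of
  # a voxel
  lambda_rot <- c(2e-2, 2e-2, 1e-3)
  lambda_t <- 2e-4
  P <- voxel_world_coords(dim(fixed), affine)        # precomputed once
  inv_affine <- solve(affine)
  cost_on <- function(mov, fix) {
    fixv <- as.vector(fix)
    function(par) {
      M <- tf_matrix(rigid_transform(par[1:3], par[4:6], center))
      Q <- P %*% t(M[1:3, 1:3])
      Q[, 1] <- Q[, 1] + M[1, 4]; Q[, 2] <- Q[, 2] + M[2, 4]
      Q[, 3] <- Q[, 3] + M[3, 4]
      Vm <- Q %*% t(inv_affine[1:3, 1:3])
      Vm[, 1] <- Vm[, 1] + inv_affine[1, 4] + 1
      Vm[, 2] <- Vm[, 2] + inv_affine[2, 4] + 1
      Vm[, 3] <- Vm[, 3] + inv_affine[3, 4] + 1
      -mi_similarity(fixv, trilinear_sample(mov, Vm), bins = bins) +
        sum(lambda_rot * par[4:6]^2) + lambda_t * sum(par[1:3]^2)
    }
  }
  sm_m <- smooth_volume(moving, 1)
  sm_f <- smooth_volume(fixed, 1)
  cost_sm <- cost_on(sm_m, sm_f)
  # coarse translation-only grid seeds the simplex (Nelder-Mead alone cannot
  # escape the capture range of the identity on a wiggly MI surface)
  steps <- seq(-4, 4, by = 2)
  grid <- as.matrix(expand.grid(tx = steps, ty = steps, tz = steps))
  vals <- apply(grid, 1, function(g) cost_sm(c(g, 0, 0, 0)))
  p0 <- c(grid[which.min(vals), ], 0, 0, 0)
  # per-axis rotation sweep: MI has a spurious local optimum at exactly
  # grid-aligned transforms (no interpolation blur), which traps a simplex
  # started at the identity
  for (ax in 1:3) {
    angles <- seq(-3, 3, by = 1.5)
    av <- vapply(angles, function(a) {
      p <- p0; p[3 + ax] <- p[3 + ax] + a; cost_sm(p)
    }, numeric(1))
    p0[3 + ax] <- p0[3 + ax] + angles[which.min(av)]
  }
  fit1 <- stats::optim(p0, cost_sm, method = "Nelder-Mead",
                       control = list(maxit = round(0.75 * max_iter), reltol = 1e-8,
                                      parscale = rep(8, 6)))
  # refinement on lightly smoothed volumes: resampling the moving volume blurs
  # it while the fixed volume stays sharp, and that asymmetry displaces the
  # raw-MI optimum by up to half a millimetre; matching the blur removes it
  cost_full <- cost_on(smooth_volume(moving, 0.7), smooth_volume(fixed, 0.7))
  fit2 <- stats::optim(fit1$par, cost_full, method = "Nelder-Mead",
                       control = list(maxit = round(0.5 * max_iter), reltol = 1e-9,
                                      parscale = rep(2, 6)))
  # fine per-axis sweeps knock the estimate out of sub-degree/sub-mm local
  # wiggles of the histogram MI surface before the last simplex passes
  p <- fit2$par
  for (k in 6:1) {
    local_steps <- if (k > 3) seq(-1.5, 1.5, by = 0.25) else seq(-1, 1, by = 0.25)
    vals <- vapply(local_steps, function(s) {
      q <- p; q[k] <- q[k] + s; cost_full(q)
    }, numeric(1))
    p[k] <- p[k] + local_steps[which.min(vals)]
  }
  fit2$par <- p
  fit3 <- stats::optim(fit2$par, cost_full, method = "Nelder-Mead",
                       control = list(maxit = round(0.4 * max_iter), reltol = 1e-9,
                                      parscale = rep(0.5, 6)))
  fit4 <- stats::optim(fit3$par, cost_full, method = "Nelder-Mead",
                       control = list(maxit = round(0.3 * max_iter), reltol = 1e-9,
                                      parscale = rep(0.15, 6)))
  best <- fit4
  rigid_transform(best$par[1:3], best$par[4:6], center)
}

#' Motion-correct a CEST volume series
#'
#' Each offset volume is zero-padded along z, rigidly registered to the
#' (equally padded) reference volume, and then resampled once from the
#' original unpadded data onto the original grid. The reference volume is
#' never altered. Per-offset registration failures flag the volume (its index
#' is returned in `excluded`) and the pipeline continues with a warning.
#'
#' @param series a `cest_series`.
#' @param backend `"internal"` (the built-in MI registrar) or `"external"`;
#'   no external adapter is bundled, so `"external"` falls back to the
#'   internal backend with a warning.
#' @param pad_slices zero-padding slices per end (default 2).
#' @param ... passed on to [register_rigid()].
#' @return list with `series` (corrected `cest_series`), `transforms` (list of
#'   `rigid_transform`, one per offset, in sorted-offset order), and
#'   `excluded` (integer indices of offsets whose registration failed).
#' @export
motion_correct_series <- function(series, backend = c("internal", "external"),
                                  pad_slices = 2, ...) {
  backend <- match.arg(backend)
  if (backend == "external") {
    warning("external registration backend unavailable; falling back to internal")
  }
  ref_p <- zero_pad_slices(series$reference, pad_slices, series$affine)
  n <- dim(series$data)[4]
  out <- series$data
  transforms <- vector("list", n)
  excluded <- integer(0)
  for (j in seq_len(n)) {
    mov <- series$data[, , , j]
    mov_p <- zero_pad_slices(mov, pad_slices, series$affine)
    t_j <- tryCatch(
      register_rigid(mov_p$data, ref_p$data, affine = mov_p$affine, ...),
      error = function(e) NULL
    )
    if (is.null(t_j)) {
      warning(sprintf("registration failed for offset %d; volume excluded", j))
      excluded <- c(excluded, j)
      transforms[[j]] <- rigid_transform()
      next
    }
    transforms[[j]] <- t_j
    out[, , , j] <- resample_volume(mov, t_j, affine = series$affine,
                                    interpolation = "linear")
  }
  corrected <- cest_series(out, series$reference, series$axis,
                           affine = series$affine, mask = series$mask)
  list(series = corrected, transforms = transforms, excluded = excluded)
}
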