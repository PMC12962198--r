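#' Lorentzian line shape
#'
#' The per-pool dip in a Z-spectrum: `L(x) = A * (G/2)^2 / ((G/2)^2 + (x - d)^2)`
#' with amplitude `A`, full width at half maximum `G` (ppm) and center `d`
#' (ppm). Peak value is `A` at `x = d`; the value falls to `A/2` at
#' `x = d +/- G/2`.
#'
#' @param amplitude dimensionless amplitude, in `[0, 1]`.
#' @param center peak position in ppm.
#' @param width full width at half maximum in ppm, `> 0`.
#' @param offsets frequency offsets (ppm) at which to evaluate; vectorized.
#' @return numeric vector of Lorentzian values.
#' @export
lorentzian_value <- function(amplitude, center, width, offsets) {
  if (any(width <= 0)) stop("Lorentzian width must be positive")
  hw2 <- (width / 2)^2
  amplitude * hw2 / (hw2 + (offsets - center)^2)
}

#' Construct a pool set
#'
#' A pool set is a data frame with one row per Lorentzian pool (columns
#' `name`, `amplitude`, `center`, `width`). The default six pools follow the
#' usual brain assignment at 3 T: water (0 ppm), hydroxyl (+1), amine (+2),
#' amide (+3.5), aliphatic rNOE (-3.5), and the broad semisolid MT background.
#'
#' @param name character vector of pool names.
#' @param amplitude,center,width numeric vectors, one value per pool
#'   (dimensionless, ppm, ppm FWHM).
#' @return data.frame of class `pool_set`.
#' @export
pool_set <- function(name, amplitude, center, width) {
  stopifnot(length(name) == length(amplitude),
            length(name) == length(center),
            length(name) == length(width))
  if (any(width <= 0)) stop("pool widths must be positive")
  if (any(amplitude < 0 | amplitude > 1)) stop("pool amplitudes must lie in [0, 1]")
  out <- data.frame(
    name = as.character(name), amplitude = as.numeric(amplitude),
    center = as.numeric(center), width = as.numeric(width),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pool_set", "data.frame")
  out
}

#' Default six-pool parameter set (gray-matter-like tissue at 3 T)
#' @export
default_pool_set <- function() {
  pool_set(
    name      = c("water", "hydroxyl", "amine", "amide", "rNOE", "MT"),
    amplitude = c(0.78,    0.030,      0.035,   0.040,   0.050,  0.10),
    center    = c(0.0,     1.0,        2.0,     3.5,     -3.5,   -2.4),
    width     = c(3.0,     1.2,        1.8,     2.2,     3.5,    25)
  )
}

#' Multi-pool model Z-spectrum
#'
#' `Z(x) = 1 - sum_i L_i(x)`. An empty pool set gives `Z == 1`.
#'
#' @param pools a `pool_set` (any number of rows).
#' @param offsets ppm values at which to evaluate.
#' @return numeric vector of model Z values.
#' @export
model_zspectrum <- function(pools, offsets) {
  z <- rep(1, length(offsets))
  if (nrow(pools) == 0L) return(z)
  for (i in seq_len(nrow(pools))) {
    z <- z - lorentzian_value(pools$amplitude[i], pools$center[i],
                              pools$width[i], offsets)
  }
  z
}

#' Pool priors (starts and bounds) for the six-pool fit
#'
#' One row per pool with start/lower/upper for amplitude, center and width.
#' Centers are tightly constrained: the fit is allowed to move each center by
#' at most +/- 0.01 ppm around its prior position, which stabilizes the fit on
#' low-spectral-resolution 3 T data at the cost of flexibility for the broad
#' pools. The default numeric bounds ship in an editable YAML config
#' (`inst/extdata/pool_priors.yaml`); every value can be overridden.
#'
#' @param pools character vector of pool names (default the six standard pools).
#' @return data.frame of class `pool_prior` with columns `name`,
#'   `amplitude_start/lower/upper`, `center_start/lower/upper`,
#'   `width_start/lower/upper`.
#' @export
default_pool_prior <- function(pools = c("water", "hydroxyl", "amine", "amide", "rNOE", "MT")) {
  tab <- data.frame(
    name             = c("water", "hydroxyl", "amine", "amide", "rNOE", "MT"),
    amplitude_start  = c(0.80,    0.05,       0.05,    0.05,    0.05,   0.10),
    amplitude_lower  = c(0.02,    0,          0,       0,       0,      0),
    amplitude_upper  = c(1.0,     0.3,        0.3,     0.3,     0.4,    0.5),
    center_start     = c(0.0,     1.0,        2.0,     3.5,     -3.5,   -2.4),
    width_start      = c(2.8,     1.2,        1.8,     2.0,     3.5,    25),
    width_lower      = c(1.5,     0.6,        1.0,     1.0,     2.0,    15),
    width_upper      = c(5.0,     2.5,        3.5,     3.5,     5.5,    60),
    stringsAsFactors = FALSE
  )
  tab$center_lower <- tab$center_start - 0.01
  tab$center_upper <- tab$center_start + 0.01
  tab <- tab[match(pools, tab$name), ]
  if (anyNA(tab$name)) stop("unknown pool name in `pools`")
  rownames(tab) <- NULL
  validate_pool_prior(tab)
}

validate_pool_prior <- function(tab) {
  needed <- c("name", "amplitude_start", "amplitude_lower", "amplitude_upper",
              "center_start", "center_lower", "center_upper",
              "width_start", "width_lower", "width_upper")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) stop("pool prior missing columns: ", paste(missing, collapse = ", "))
  for (q in c("amplitude", "center", "width")) {
    lo <- tab[[paste0(q, "_lower")]]; st <- tab[[paste0(q, "_start")]]
    hi <- tab[[paste0(q, "_upper")]]
    if (any(lo > st | st > hi)) stop("pool prior violates lower <= start <= upper for ", q)
  }
  if (any(tab$center_upper - tab$center_lower > 0.02 + 1e-12)) {
    stop("pool centers must be constrained to within +/- 0.01 ppm of their prior position")
  }
  if (any(tab$width_lower <= 0)) stop("width lower bounds must be positive")
  tab <- tab[, c("name", "amplitude_start", "amplitude_lower", "amplitude_upper",
                 "center_start", "width_start", "width_lower", "width_upper",
                 "center_lower", "center_upper")]
  class(tab) <- c("pool_prior", "data.frame")
  tab
}

#' Read / write pool priors as YAML
#'
#' The YAML layout is a map from pool name to a map with keys `amplitude`,
#' `center`, `width`, each a list of `[start, lower, upper]`.
#' @param path file path.
#' @return `read_pool_prior` returns a `pool_prior` data frame.
#' @export
read_pool_prior <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y), function(nm) {
    p <- y[[nm]]
    data.frame(
      name = nm,
      amplitude_start = p$amplitude[[1]], amplitude_lower = p$amplitude[[2]],
      amplitude_upper = p$amplitude[[3]],
      center_start = p$center[[1]], center_lower = p$center[[2]],
      center_upper = p$center[[3]],
      width_start = p$width[[1]], width_lower = p$width[[2]],
      width_upper = p$width[[3]],
      stringsAsFactors = FALSE
    )
  })
  validate_pool_prior(do.call(rbind, rows))
}

#' @rdname read_pool_prior
#' @param prior a `pool_prior` data frame.
#' @export
write_pool_prior <- function(prior, path) {
  y <- list()
  for (i in seq_len(nrow(prior))) {
    y[[prior$name[i]]] <- list(
      amplitude = c(prior$amplitude_start[i], prior$amplitude_lower[i], prior$amplitude_upper[i]),
      center = c(prior$center_start[i], prior$center_lower[i], prior$center_upper[i]),
      width = c(prior$width_start[i], prior$width_lower[i], prior$width_upper[i])
    )
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

prior_to_vectors <- function(prior) {
  n <- nrow(prior)
  start <- lower <- upper <- numeric(3 * n)
  for (i in seq_len(n)) {
    j <- (i - 1) * 3
    start[j + 1:3] <- c(prior$amplitude_start[i], prior$center_start[i], prior$width_start[i])
    lower[j + 1:3] <- c(prior$amplitude_lower[i], prior$center_lower[i], prior$width_lower[i])
    upper[j + 1:3] <- c(prior$amplitude_upper[i], prior$center_upper[i], prior$width_upper[i])
  }
  list(start = start, lower = lower, upper = upper)
}

vector_to_pools <- function(par, names) {
  n <- length(names)
  idx <- (seq_len(n) - 1) * 3
  pool_set(names, pmax(par[idx + 1], 0), par[idx + 2], par[idx + 3])
}

#' Fit the multi-pool Lorentzian model to a Z-spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box constraints)
#' minimizing the sum of squared differences between the measured Z values and
#' `1 - sum_i L_i`. The fit runs on the B0-corrected *sampled* offsets, not on
#' a dense interpolated grid, to avoid spline-induced residual correlation;
#' offsets whose corrected value is missing are dropped. On non-convergence
#' the fit restarts from up to `n_starts - 1` jittered start vectors and keeps
#' the lowest objective.
#'
#' @param spectrum a B0-corrected `zspectrum` (`b0_shift` must be set; pass a
#'   spectrum through [correct_b0()] first, or set `b0_shift = 0` explicitly
#'   for data known to be on-resonance).
#' @param prior a `pool_prior` data frame (default [default_pool_prior()]).
#' @param n_starts maximum number of starts (first from the prior, the rest
#'   low-discrepancy width vectors with linearly solved amplitudes);
#'   default 64.
#' @param n_stall stop the multistart after this many consecutive starts that
#'   fail to improve the best objective by at least 1 percent (default 8);
#'   raise it together with `n_starts` for pathological landscapes.
#' @param width_shrinkage empirical-Bayes width regularization: after the
#'   unpenalized fit, the residual noise level is estimated and the fit is
#'   repeated with a Gaussian prior of relative sd `width_shrinkage` pulling
#'   each width toward its prior start, scaled by that noise estimate (so
#'   noise-free fits are untouched). Shrinks the noise-driven dispersion of
#'   the small-pool amplitudes at low SNR; 0 disables. Default 0.1.
#' @param max_eval maximum function evaluations per start; default 2000.
#' @param seed integer seed for the jittered restarts.
#' @return object of class `fit_result`: list with `pools` (fitted
#'   `pool_set`), `r_squared`, `rmse`, `residuals`, `converged`,
#'   `n_iterations`, `offsets`, `fitted_z`.
#' @export
fit_multipool <- function(spectrum, prior = default_pool_prior(), n_starts = 64,
                          n_stall = 8, width_shrinkage = 0.1, max_eval = 2000,
                          seed = 1L) {
  if (is.null(spectrum$b0_shift)) {
    stop("spectrum must be B0-corrected before fitting (b0_shift is unset)")
  }
  keep <- is.finite(spectrum$z)
  x <- spectrum$offsets[keep]
  y <- spectrum$z[keep]
  n_par <- 3 * nrow(prior)
  if (length(y) < n_par + 1) {
    stop(sprintf("underdetermined fit: %d usable samples for %d parameters",
                 length(y), n_par))
  }
  pv <- prior_to_vectors(prior)
  resid_fun <- function(par) {
    y - model_zspectrum(vector_to_pools(par, prior$name), x)
  }
  # analytic Jacobian of the residual (residual = y - 1 + sum_i L_i)
  jac_fun <- function(par) {
    J <- matrix(0, length(x), length(par))
    for (i in seq_len(nrow(prior))) {
      j <- (i - 1) * 3
      A <- par[j + 1]; d <- par[j + 2]; G <- par[j + 3]
      hw2 <- (G / 2)^2
      den <- hw2 + (x - d)^2
      J[, j + 1] <- hw2 / den
      J[, j + 2] <- A * hw2 * 2 * (x - d) / den^2
      J[, j + 3] <- A * (G / 2) * (x - d)^2 / den^2
    }
    J
  }
  ssr <- function(par) sum(resid_fun(par)^2)

  run_one <- function(start) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = pv$lower, upper = pv$upper, fn = resid_fun,
        jac = jac_fun,
        control = minpack.lm::nls.lm.control(
          maxfev = max_eval, maxiter = min(1024L, max_eval),
          ftol = 1e-15, ptol = 1e-12, gtol = 0
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(par = start, ssr = ssr(start), ok = FALSE, niter = 0L))
    list(par = fit$par, ssr = sum(fit$fvec^2), ok = fit$info %in% 1:4,
         niter = fit$niter)
  }

  # amplitudes enter the model linearly, so every start is built from a
  # candidate width vector (centers stay at their hard priors) with the
  # least-squares amplitudes solved directly and clipped into bounds
  ia <- seq(1, n_par, by = 3)
  iw <- seq(3, n_par, by = 3)
  make_start <- function(widths) {
    start <- pv$start
    start[iw] <- widths
    basis <- vapply(seq_len(nrow(prior)), function(i) {
      lorentzian_value(1, prior$center_start[i], widths[i], x)
    }, numeric(length(x)))
    amp_ls <- tryCatch(qr.solve(basis, 1 - y), error = function(e) NULL)
    if (!is.null(amp_ls)) start[ia] <- pmin(pmax(amp_ls, pv$lower[ia]), pv$upper[ia])
    start
  }

  best <- run_one(pv$start)
  tries <- 1L
  if (!best$ok || best$ssr > 1e-12) {
    cand <- run_one(make_start(pv$start[iw]))
    if (cand$ssr < 0.5 * best$ssr || (!best$ok && cand$ssr < best$ssr)) {
      best <- cand
    }
    # diverse multistart over width space: deterministic low-discrepancy
    # width vectors (the global RNG is untouched), each completed by a linear
    # amplitude solve
    phi <- (sqrt(5) - 1) / 2
    stalled <- 0L
    while ((!best$ok || best$ssr > 1e-12) && tries < n_starts &&
           stalled < n_stall) {
      tries <- tries + 1L
      frac <- ((seed + tries * phi) * seq_len(length(iw)) * phi) %% 1
      cand <- run_one(make_start(pv$lower[iw] + frac * (pv$upper[iw] - pv$lower[iw])))
      if (cand$ssr < 0.99 * best$ssr) stalled <- 0L else stalled <- stalled + 1L
      # an alternative basin replaces the incumbent only if it halves the
      # objective: at measurement noise, near-equal basins abound and the
      # prior-anchored solution is the regularized choice
      if (cand$ssr < 0.5 * best$ssr || (!best$ok && cand$ssr < best$ssr)) {
        best <- cand
      }
    }
  }

  # empirical-Bayes width shrinkage: refit with a width prior scaled by the
  # estimated residual noise (inactive when the data are fit exactly)
  sigma_hat <- sqrt(best$ssr / max(1, length(y) - n_par))
  if (width_shrinkage > 0 && sigma_hat > 1e-9) {
    tau <- width_shrinkage * prior$width_start
    aug_resid <- function(par) {
      c(resid_fun(par), sigma_hat * (par[iw] - prior$width_start) / tau)
    }
    aug_jac <- function(par) {
      J <- jac_fun(par)
      P <- matrix(0, length(iw), length(par))
      P[cbind(seq_along(iw), iw)] <- sigma_hat / tau
      rbind(J, P)
    }
    refit <- tryCatch(
      minpack.lm::nls.lm(
        par = best$par, lower = pv$lower, upper = pv$upper, fn = aug_resid,
        jac = aug_jac,
        control = minpack.lm::nls.lm.control(
          maxfev = max_eval, maxiter = min(1024L, max_eval),
          ftol = 1e-15, ptol = 1e-12, gtol = 0
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(refit)) {
      best <- list(par = refit$par, ssr = ssr(refit$par), ok = best$ok,
                   niter = best$niter + refit$niter)
    }
  }

  # data objective must never exceed the starting objective
  if (best$ssr > ssr(pv$start)) best <- list(par = pv$start, ssr = ssr(pv$start),
                                             ok = FALSE, niter = 0L)
  pools <- vector_to_pools(best$par, prior$name)
  fitted_z <- model_zspectrum(pools, x)
  gof <- goodness_of_fit(zspectrum(y, x, spectrum$reference_offset, spectrum$b0_shift),
                         zspectrum(pmax(fitted_z, 0), x, spectrum$reference_offset,
                                   spectrum$b0_shift))
  structure(
    list(pools = pools, r_squared = gof$r_squared, rmse = gof$rmse,
         residuals = y - fitted_z, converged = best$ok,
         n_iterations = best$niter, n_starts_used = tries,
         offsets = x, fitted_z = fitted_z),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d pools, R^2 = %.4f, RMSE = %.2e, converged: %s\n",
              nrow(x$pools), x$r_squared, x$rmse, x$converged))
  print(x$pools)
  invisible(x)
}

#' Goodness of fit of a model spectrum to measured data
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' data mean, and `RMSE = sqrt(mean((data - model)^2))`. For constant data
#' (`SS_tot == 0`) the coefficient of determination is undefined and is
#' returned as `NA` with `r_squared_defined = FALSE`.
#'
#' @param data,model `zspectrum` objects on identical offsets (or bare numeric
#'   vectors of equal length).
#' @return list with `r_squared`, `rmse`, `r_squared_defined`.
#' @export
goodness_of_fit <- function(data, model) {
  dz <- if (inherits(data, "zspectrum")) data$z else as.numeric(data)
  mz <- if (inherits(model, "zspectrum")) model$z else as.numeric(model)
  if (inherits(data, "zspectrum") && inherits(model, "zspectrum")) {
    if (length(data$offsets) != length(model$offsets) ||
        any(abs(data$offsets - model$offsets) > 1e-9)) {
      stop("data and model spectra must be aligned on identical offsets")
    }
  }
  if (length(dz) != length(mz)) stop("data and model must have equal length")
  ok <- is.finite(dz) & is.finite(mz)
  dz <- dz[ok]; mz <- mz[ok]
  ss_res <- sum((dz - mz)^2)
  ss_tot <- sum((dz - mean(dz))^2)
  rmse <- sqrt(mean((dz - mz)^2))
  if (ss_tot == 0) {
    list(r_squared = NA_real_, rmse = rmse, r_squared_defined = FALSE)
  } else {
    list(r_squared = 1 - ss_res / ss_tot, rmse = rmse, r_squared_defined = TRUE)
  }
}
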