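# Shared fixtures: small phantoms sized for fast tests.

# Two-class bilateral phantom (gray-matter ellipsoids + ventricles) on a
# small grid; the ventricle class is on the default exclusion list, so a
# single analyzed ROI survives ROI construction.
small_classes <- function(group_effect = default_group_effect()) {
  list(
    tissue_class("Cerebral-Cortex", 3L, 42L, cestquant:::gm_pools(), group_effect,
                 center = c(0.28, 0.5, 0.5), radius = c(0.20, 0.35, 0.40)),
    tissue_class("Lateral-Ventricle", 4L, 43L, cestquant:::csf_pools(), NULL,
                 center = c(0.30, 0.5, 0.5), radius = c(0.10, 0.16, 0.30))
  )
}

small_spec <- function(noise_sigma = 0.005, b0_amplitude = 0.3,
                       grid_shape = c(16, 16, 4), group_effect = default_group_effect(),
                       ...) {
  phantom_spec(grid_shape = grid_shape, tissue_classes = small_classes(group_effect),
               noise_sigma = noise_sigma, b0_amplitude = b0_amplitude, ...)
}

# Phantom whose spectra are exactly symmetric about 0 ppm (water only), for
# tests that rely on a zero-asymmetry ground truth.
symmetric_classes <- function() {
  water_only <- pool_set("water", 0.8, 0, 3.0)
  narrow <- pool_set("water", 0.85, 0, 2.0)
  list(
    tissue_class("Cerebral-Cortex", 3L, 42L, water_only, NULL,
                 center = c(0.28, 0.5, 0.5), radius = c(0.20, 0.35, 0.40)),
    tissue_class("Thalamus", 10L, 49L, narrow, NULL,
                 center = c(0.32, 0.5, 0.5), radius = c(0.10, 0.16, 0.30))
  )
}

symmetric_spec <- function(noise_sigma = 0, b0_amplitude = 0, ...) {
  phantom_spec(grid_shape = c(16, 16, 4), tissue_classes = symmetric_classes(),
               noise_sigma = noise_sigma, b0_amplitude = b0_amplitude, ...)
}

# Brute-force two-sided exact Mann-Whitney p by enumerating all
# choose(n+m, n) group assignments (independent oracle for the package's
# distribution-based implementation).
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- min(u_of(seq_len(n)), length(x) * length(y) - u_of(seq_len(n)))
  all_u <- utils::combn(length(pooled), n, u_of)
  nm <- length(x) * length(y)
  all_min <- pmin(all_u, nm - all_u)
  mean_stat <- nm / 2
  # two-sided: assignments at least as extreme (as far from the mean) as observed
  mean(abs(all_u - mean_stat) >= abs(u_obs - mean_stat) - 1e-9)
}
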