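# Two-pool Bloch-McConnell forward model. Serves as a non-Lorentzian oracle
# for the phantom's Lorentzian generator: continuous-wave steady-state
# solution evaluated at B1 = B1rms of the pulsed scheme (the pulse train is
# approximated by its root-mean-square amplitude).

GAMMA_HZ_PER_UT <- 42.577478518   # proton gyromagnetic ratio, Hz per microtesla

#' Two-pool Bloch-McConnell steady-state Z-spectrum
#'
#' Continuous-wave steady-state solution of the coupled water/solute
#' Bloch-McConnell equations, evaluated at the root-mean-square B1 of the
#' saturation scheme. Used as an independent (non-Lorentzian) generator to
#' check that the multi-pool Lorentzian fit is not merely recovering its own
#' functional form.
#'
#' @param water_r1,water_r2 water longitudinal/transverse relaxation rates in
#'   1/s.
#' @param solute list with `rate` (solute-to-water exchange rate, 1/s),
#'   `fraction` (solute proton fraction relative to water, in \[0, 1);
#'   0 degenerates to water-only direct saturation), `offset_ppm` (chemical
#'   shift from water), and optional `r1`, `r2` (defaults 1 and 30 1/s).
#' @param scheme a [saturation_scheme()]; only `b1rms` enters the CW model.
#' @param axis a [frequency_axis()].
#' @param larmor_mhz proton Larmor frequency in MHz (default 127.74, a 3 T
#'   field), converting ppm to Hz.
#' @return a `zspectrum` with `Z = Mz_water(steady state) / M0_water`.
#' @export
forward_zspectrum_bm <- function(water_r1 = 1 / 1.3, water_r2 = 1 / 0.075,
                                 solute = list(rate = 50, fraction = 0.001,
                                               offset_ppm = 3.5),
                                 scheme = saturation_scheme(),
                                 axis = default_axis(),
                                 larmor_mhz = 127.74) {
  f <- solute$fraction
  kb <- solute$rate
  r1b <- solute$r1 %||% 1
  r2b <- solute$r2 %||% 30
  if (water_r1 <= 0 || water_r2 <= 0 || kb <= 0 || r1b <= 0 || r2b <= 0) {
    stop("relaxation and exchange rates must be positive")
  }
  if (f < 0 || f >= 1) stop("solute fraction must lie in [0, 1)")
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * scheme$b1rms       # rad/s
  ka <- f * kb                                         # water -> solute
  z <- vapply(axis$offsets, function(off) {
    bm_steady_state_z(off, w1, water_r1, water_r2, r1b, r2b, ka, kb, f,
                      solute$offset_ppm, larmor_mhz)
  }, numeric(1))
  zspectrum(pmin(pmax(z, 0), 1), axis$offsets, axis$reference_offset)
}

bm_steady_state_z <- function(offset_ppm, w1, r1a, r2a, r1b, r2b, ka, kb, f,
                              solute_ppm, larmor_mhz) {
  da <- 2 * pi * larmor_mhz * (0 - offset_ppm)          # water at 0 ppm
  db <- 2 * pi * larmor_mhz * (solute_ppm - offset_ppm)
  m0a <- 1; m0b <- f
  # state (Mxa, Mya, Mza, Mxb, Myb, Mzb); dM/dt = A M + b
  A <- matrix(0, 6, 6)
  A[1, ] <- c(-r2a - ka,  da,        0,        kb,       0,       0)
  A[2, ] <- c(-da,       -r2a - ka,  w1,       0,        kb,      0)
  A[3, ] <- c(0,         -w1,       -r1a - ka, 0,        0,       kb)
  A[4, ] <- c(ka,         0,         0,       -r2b - kb, db,      0)
  A[5, ] <- c(0,          ka,        0,       -db,      -r2b - kb, w1)
  A[6, ] <- c(0,          0,         ka,       0,       -w1,     -r1b - kb)
  b <- c(0, 0, r1a * m0a, 0, 0, r1b * m0b)
  m <- solve(A, -b)
  m[3] / m0a
}
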