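#' Saturation frequency axis
#'
#' The coordinate system of every Z-spectrum: the ordered saturation offsets
#' in ppm plus the far off-resonance reference offset used for normalization.
#' Offsets are stored in sorted order; the acquisition order is retained as an
#' attribute so that volume series written to disk can preserve it in their
#' sidecar.
#'
#' @param offsets numeric vector of saturation offsets in ppm, in acquisition
#'   order. Duplicates are not allowed.
#' @param reference_offset far off-resonance reference offset in ppm; must lie
#'   far outside the sampled range (|reference| > 100 ppm).
#' @return an object of class `frequency_axis` with elements `offsets`
#'   (sorted), `reference_offset`, and attribute `acq_order` such that
#'   `offsets[acq_order]` restores acquisition order... inverse permutation is
#'   stored as `sort_index`: `sorted = acquired[sort_index]`.
#' @export
frequency_axis <- function(offsets, reference_offset = -1560) {
  offsets <- as.numeric(offsets)
  if (length(offsets) < 2L) stop("frequency axis needs at least two offsets")
  if (anyNA(offsets)) stop("offsets must be finite")
  if (anyDuplicated(offsets)) stop("offsets must be distinct (strictly monotone after sorting)")
  if (abs(reference_offset) <= 100) {
    stop("reference offset must be far off-resonance (|reference| > 100 ppm)")
  }
  sort_index <- order(offsets)
  structure(
    list(
      offsets = offsets[sort_index],
      reference_offset = as.numeric(reference_offset),
      sort_index = sort_index
    ),
    class = "frequency_axis"
  )
}

#' Default saturation axis: 23 equally spaced offsets on [-6, +6] ppm with the
#' reference volume at -1560 ppm.
#' @export
default_axis <- function() {
  frequency_axis(seq(-6, 6, length.out = 23), reference_offset = -1560)
}

#' @export
print.frequency_axis <- function(x, ...) {
  cat(sprintf(
    "<frequency_axis> %d offsets on [%.3g, %.3g] ppm, reference %.5g ppm\n",
    length(x$offsets), min(x$offsets), max(x$offsets), x$reference_offset
  ))
  invisible(x)
}

#' A single Z-spectrum
#'
#' Normalized water signal Z(offset) = S(offset)/S0 at a set of saturation
#' offsets. `b0_shift` is `NULL` until the spectrum has been B0-corrected.
#'
#' @param z numeric vector of Z values (dimensionless), one per offset.
#' @param offsets numeric vector of offsets in ppm, strictly increasing.
#' @param reference_offset the reference offset of the parent axis (ppm).
#' @param b0_shift the B0 shift (ppm) this spectrum has been corrected by, or
#'   `NULL` if uncorrected.
#' @return object of class `zspectrum`.
#' @export
zspectrum <- function(z, offsets, reference_offset = -1560, b0_shift = NULL) {
  z <- as.numeric(z)
  offsets <- as.numeric(offsets)
  if (length(z) != length(offsets)) stop("z and offsets must have equal length")
  if (is.unsorted(offsets, strictly = TRUE)) stop("offsets must be strictly increasing")
  if (any(!is.na(z) & z < 0)) stop("Z values must be non-negative")
  structure(
    list(z = z, offsets = offsets, reference_offset = reference_offset,
         b0_shift = b0_shift),
    class = "zspectrum"
  )
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf(
    "<zspectrum> %d offsets on [%.3g, %.3g] ppm%s\n",
    length(x$offsets), min(x$offsets), max(x$offsets),
    if (is.null(x$b0_shift)) " (uncorrected)"
    else sprintf(", B0-corrected (shift %.3f ppm)", x$b0_shift)
  ))
  invisible(x)
}
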