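# Fourier processing ------------------------------------------------------

#' One-dimensional spectrum
#'
#' Thin container for a processed spectrum: complex intensities on a
#' strictly descending ppm axis (left = high ppm, the NMR convention),
#' plus the carrier position and the scale/phase corrections applied.
#'
#' @param values complex (or numeric) intensity vector.
#' @param ppm strictly descending ppm axis of the same length.
#' @param o1p carrier position, ppm.
#' @param bf1 observe frequency, MHz.
#' @param sweep_width spectral width, ppm.
#' @param scale multiplicative scale factor that was applied.
#' @param phase zeroth-order phase correction applied, degrees.
#' @return object of class `spectrum1d`.
#' @export
spectrum1d <- function(values, ppm, o1p, bf1, sweep_width,
                       scale = 1, phase = 0) {
  if (length(values) != length(ppm)) slogp_stop("values and ppm lengths differ")
  if (any(diff(ppm) >= 0)) slogp_stop("ppm axis must be strictly descending")
  structure(list(values = as.complex(values), ppm = ppm, o1p = o1p, bf1 = bf1,
                 sweep_width = sweep_width, scale = scale, phase = phase),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d: %d points, %.4g .. %.4g ppm, o1p %g, phase %.2f deg>\n",
              length(x$values), x$ppm[1], x$ppm[length(x$ppm)], x$o1p, x$phase))
  invisible(x)
}

#' Fourier-transform an FID into a spectrum
#'
#' Standard quadrature processing: the first time-domain point is halved
#' (so a decaying exponential transforms without a baseline offset and the
#' full-spectrum integral is Parseval-consistent), the FID is zero-filled
#' by `zero_fill`, discrete-Fourier transformed and mapped onto a ppm axis
#' centred at the carrier. The result is divided by `ns` so spectra
#' acquired with different transient counts share one amplitude scale.
#' No apodization is applied.
#'
#' @param fid complex FID vector.
#' @param params the [acq_params()] the FID was acquired with.
#' @param zero_fill zero-filling factor (>= 1; default 2).
#' @return a [spectrum1d()].
#' @export
fourier <- function(fid, params, zero_fill = 2) {
  n <- length(fid)
  if (n < 2) slogp_stop("fid must have at least 2 points")
  if (zero_fill < 1) slogp_stop("zero_fill must be >= 1")
  x <- fid
  x[1] <- 0.5 * x[1]
  nf <- round(n * zero_fill)
  if (nf > n) x <- c(x, complex(real = numeric(nf - n)))
  sp <- fft(x) / params$ns
  k <- 0:(nf - 1)
  freq <- ifelse(k < nf / 2, k, k - nf) * (params$sw_hz / nf)
  ppm <- params$o1p + freq / params$bf1
  ord <- order(ppm, decreasing = TRUE)
  spectrum1d(sp[ord], ppm[ord], o1p = params$o1p, bf1 = params$bf1,
             sweep_width = params$sweep_width, scale = 1 / params$ns)
}

#' Zeroth-order automatic phase correction
#'
#' Chooses the zeroth-order phase that maximizes the real-part integral
#' over detected peak regions (points whose magnitude exceeds
#' `threshold_k` times a robust noise estimate); for a symmetric window
#' around a Lorentzian this is the argument of the complex sum over those
#' points. A pure-noise spectrum does not fail: the phase is then derived
#' from all points and flagged with a low-confidence warning attribute.
#'
#' @param spec a [spectrum1d()].
#' @param threshold_k peak-detection threshold in noise-sigma units.
#' @return the phased [spectrum1d()]; the applied correction (degrees) is
#'   recorded in `$phase` and any warning in `attr(, "warning")`.
#' @export
autophase <- function(spec, threshold_k = 10) {
  v <- spec$values
  mag <- Mod(v)
  sigma <- stats::median(mag) / sqrt(2 * log(2))  # Rayleigh median -> sigma
  idx <- which(mag > threshold_k * sigma)
  warn <- NULL
  if (length(idx) == 0L) {
    idx <- seq_along(v)
    warn <- "no peaks above the noise floor; phase estimate has low confidence"
  }
  phi <- Arg(sum(v[idx]))
  out <- spec
  out$values <- v * exp(complex(imaginary = -phi))
  out$phase <- spec$phase + phi * 180 / pi
  if (!is.null(warn)) attr(out, "warning") <- warn
  out
}

#' Sum two spectra, optionally displacing the second
#'
#' Pointwise sum on the common axis; a non-zero `manual_offset_ppm`
#' displaces `spec_b` by grid interpolation first (the manual recourse
#' when the per-phase shift difference is too small to resolve the two
#' signals in the automatic sum). Points shifted outside the window are
#' dropped as zero; a shift that pushes the maximum of `spec_b` out of
#' the window raises a warning.
#'
#' @param spec_a,spec_b [spectrum1d()] objects on identical axes.
#' @param manual_offset_ppm displacement applied to `spec_b`, ppm.
#' @return the summed [spectrum1d()].
#' @export
shift_and_sum <- function(spec_a, spec_b, manual_offset_ppm = 0) {
  if (length(spec_a$values) != length(spec_b$values) ||
      max(abs(spec_a$ppm - spec_b$ppm)) > 1e-9)
    slogp_stop("spectra must share a common ppm axis")
  vb <- spec_b$values
  if (manual_offset_ppm != 0) {
    peak_ppm <- spec_b$ppm[which.max(Mod(vb))]
    if (peak_ppm + manual_offset_ppm > max(spec_a$ppm) ||
        peak_ppm + manual_offset_ppm < min(spec_a$ppm))
      warning("manual offset pushes the displaced spectrum's peak outside the window")
    xout <- spec_a$ppm - manual_offset_ppm
    re <- approx(spec_b$ppm, Re(vb), xout = xout)$y
    im <- approx(spec_b$ppm, Im(vb), xout = xout)$y
    re[is.na(re)] <- 0
    im[is.na(im)] <- 0
    vb <- complex(real = re, imaginary = im)
  }
  out <- spec_a
  out$values <- spec_a$values + vb
  out
}

#' Integrate the real part of a spectrum over a chemical-shift window
#'
#' Trapezoidal area over `[center - width/2, center + width/2]` ppm (the
#' protocol integrates each signal over a 1 ppm range centred on it). By
#' default a linear baseline, estimated from the mean level of two
#' flanking strips just outside the window, is subtracted first; this
#' removes the tail of any distant companion peak, which otherwise biases
#' the minor-peak integral when the two signals differ by orders of
#' magnitude.
#'
#' @param spec a [spectrum1d()].
#' @param center window centre, ppm.
#' @param width window width, ppm (default 1).
#' @param baseline `"linear"` (default) or `"none"`.
#' @param flank width of each flanking strip, ppm (default 0.3).
#' @return the integral (spectrum units x ppm).
#' @export
integrate_window <- function(spec, center, width = 1,
                             baseline = c("linear", "none"), flank = 0.3) {
  baseline <- match.arg(baseline)
  if (width <= 0) slogp_stop("width must be positive")
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < min(spec$ppm) || hi > max(spec$ppm))
    slogp_stop(sprintf("integration window [%.3f, %.3f] ppm lies outside the spectrum", lo, hi))
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (length(idx) < 2L) slogp_stop("integration window contains fewer than 2 points")
  x <- rev(spec$ppm[idx])           # ascending
  y <- rev(Re(spec$values[idx]))
  if (baseline == "linear") {
    i_hi <- which(spec$ppm > hi & spec$ppm <= hi + flank)
    i_lo <- which(spec$ppm < lo & spec$ppm >= lo - flank)
    if (length(i_hi) >= 3L && length(i_lo) >= 3L) {
      x_hi <- mean(spec$ppm[i_hi]); m_hi <- mean(Re(spec$values[i_hi]))
      x_lo <- mean(spec$ppm[i_lo]); m_lo <- mean(Re(spec$values[i_lo]))
      y <- y - (m_lo + (x - x_lo) * (m_hi - m_lo) / (x_hi - x_lo))
    }
  }
  trapz_asc(x, y)
}

#' Signal-to-noise ratio of a peak
#'
#' Peak amplitude over twice the RMS of the (mean-corrected) real part in
#' a signal-free noise region. A noiseless spectrum returns the capped
#' sentinel 1e12 so downstream arithmetic stays total.
#'
#' @param spec a [spectrum1d()].
#' @param peak_ppm approximate peak position, ppm.
#' @param noise_region length-2 numeric, ppm bounds of a signal-free
#'   region disjoint from all integration windows.
#' @param search half-width of the peak search interval, ppm.
#' @param cap sentinel value for a noiseless spectrum.
#' @return dimensionless SNR.
#' @export
snr_estimate <- function(spec, peak_ppm, noise_region, search = 0.2, cap = 1e12) {
  i_pk <- which(abs(spec$ppm - peak_ppm) <= search)
  if (length(i_pk) == 0L) slogp_stop("no points within the peak search interval")
  amp <- max(Re(spec$values[i_pk]))
  i_nr <- which(spec$ppm >= min(noise_region) & spec$ppm <= max(noise_region))
  if (length(i_nr) < 10L)
    slogp_stop("degenerate noise region (fewer than 10 points)")
  rms <- stats::sd(Re(spec$values[i_nr]))
  if (!is.finite(rms) || rms == 0) return(cap)
  min(amp / (2 * rms), cap)
}
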