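# Slice geometry ----------------------------------------------------------
#
# Under a linear z field gradient the resonance frequency becomes a linear
# function of position, so a frequency-selective pulse of bandwidth BW
# excites a slab of thickness
#
#     dz = BW / (gamma_bar * G)
#
# and offsetting the pulse by Omega translates the slab to
#
#     d = Omega / (gamma_bar * G)
#
# Units: BW and Omega in Hz, gamma_bar in MHz/T, G in G/cm. With
# 1 G/cm = 1e-4 T/cm the product gamma_bar*G is 100*gamma_bar*G Hz/cm,
# hence the factor 10 below for results in mm.

#' Slice thickness from pulse bandwidth and gradient strength
#'
#' @param bandwidth selective-pulse bandwidth, Hz.
#' @param gradient absolute gradient (G/cm) or a [gradient_spec()].
#' @param nuc a [nucleus_spec()]; defaults to 19F.
#' @return slice thickness in mm.
#' @export
#' @examples
#' slice_thickness(6000, gradient_spec(16))  # ~1.7 mm
slice_thickness <- function(bandwidth, gradient, nuc = nucleus("19F")) {
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    slogp_stop("bandwidth must be positive")
  g <- as_gradient_abs(gradient)
  bandwidth / (nuc$gamma_bar * g * 10)
}

#' Slice position from a pulse offset
#'
#' Signed distance of the selected slice from the coil centre (placed at
#' the solvent interface): positive offsets select from the upper
#' (n-octanol) phase, negative offsets from the lower (aqueous) phase.
#'
#' @param offset pulse offset, Hz (signed).
#' @param gradient absolute gradient (G/cm) or a [gradient_spec()].
#' @param nuc a [nucleus_spec()].
#' @return signed position in mm.
#' @export
#' @examples
#' offset_to_position(21500, gradient_spec(16))  # ~6.1 mm
offset_to_position <- function(offset, gradient, nuc = nucleus("19F")) {
  if (!is.numeric(offset)) slogp_stop("offset must be numeric")
  g <- as_gradient_abs(gradient)
  offset / (nuc$gamma_bar * g * 10)
}

#' Convert a chemical-shift offset in ppm to Hz (and back)
#'
#' @param ppm offset in ppm.
#' @param nuc a [nucleus_spec()].
#' @param proton_freq 1H frequency of the magnet, MHz.
#' @return offset in Hz.
#' @export
#' @examples
#' ppm_to_hz(60, nucleus("19F"), 400.13)  # ~22.6 kHz
ppm_to_hz <- function(ppm, nuc = nucleus("19F"), proton_freq = 400.13) {
  ppm * basic_frequency(nuc, proton_freq)
}

#' @rdname ppm_to_hz
#' @param hz offset in Hz.
#' @export
hz_to_ppm <- function(hz, nuc = nucleus("19F"), proton_freq = 400.13) {
  hz / basic_frequency(nuc, proton_freq)
}

# Time-bandwidth products of the shape library used for slice selection.
.shape_factors <- data.frame(
  shape = c("G4", "Rsnob"),
  flip_angle = c(90, 180),
  bw_factor = c(7.82, 2.332),
  stringsAsFactors = FALSE
)

#' Time-bandwidth factor of a shaped pulse
#'
#' @param shape shape name, `"G4"` or `"Rsnob"` (case-insensitive).
#' @param flip_angle flip angle in degrees (90 for G4, 180 for Rsnob).
#' @return dimensionless time-bandwidth product.
#' @export
shape_bw_factor <- function(shape, flip_angle) {
  hit <- which(tolower(.shape_factors$shape) == tolower(shape) &
                 .shape_factors$flip_angle == flip_angle)
  if (length(hit) != 1L)
    slogp_stop(sprintf("no bandwidth factor for shape '%s' at %g degrees", shape, flip_angle))
  .shape_factors$bw_factor[hit]
}

#' Shaped-pulse duration from its time-bandwidth product
#'
#' The duration of a frequency-selective shaped pulse is its dimensionless
#' time-bandwidth product divided by the desired excitation bandwidth;
#' reported in microseconds to 0.01 us.
#'
#' @param bw_factor dimensionless time-bandwidth product.
#' @param bandwidth desired bandwidth, Hz.
#' @return duration in microseconds.
#' @export
#' @examples
#' pulse_duration(shape_bw_factor("G4", 90), 6000)     # 1303.33
#' pulse_duration(shape_bw_factor("Rsnob", 180), 6000) # 388.67
pulse_duration <- function(bw_factor, bandwidth) {
  if (!is.numeric(bw_factor) || bw_factor <= 0) slogp_stop("bw_factor must be positive")
  if (!is.numeric(bandwidth) || bandwidth <= 0) slogp_stop("bandwidth must be positive")
  round(bw_factor / bandwidth * 1e6, 2)
}

#' Shaped-pulse specification
#'
#' @inheritParams pulse_duration
#' @param shape shape name.
#' @param flip_angle flip angle, degrees.
#' @return object of class `shaped_pulse_spec` with the resolved duration (us).
#' @export
shaped_pulse_spec <- function(shape, flip_angle, bandwidth,
                              bw_factor = shape_bw_factor(shape, flip_angle)) {
  structure(list(shape_name = shape, flip_angle = flip_angle,
                 bw_factor = bw_factor, bandwidth = bandwidth,
                 duration = pulse_duration(bw_factor, bandwidth)),
            class = "shaped_pulse_spec")
}

#' Plan the slice geometry of a spatially encoded experiment
#'
#' Resolves slice thickness and the symmetric upper/lower slice positions
#' for a pulse offset of `omega` (ppm by default), then checks that each
#' slice lies entirely within its phase (clear of the interface) and
#' entirely inside the active region of the rf coil. Invalid plans are
#' returned with `valid = FALSE` and human-readable violation messages,
#' never raised as errors.
#'
#' @param nuc a [nucleus_spec()].
#' @param proton_freq 1H frequency, MHz (sets the ppm to Hz conversion).
#' @param gradient a [gradient_spec()] or absolute gradient in G/cm.
#' @param bandwidth selective-pulse bandwidth, Hz.
#' @param omega pulse offset magnitude applied as +omega (octanol slice)
#'   and -omega (aqueous slice).
#' @param omega_unit `"ppm"` (default) or `"Hz"`.
#' @param coil_half_length active coil half-length, mm (default 9.0,
#'   a typical 5 mm-probe active region of ~18 mm).
#' @param interface_clearance minimum distance of a slice edge from the
#'   interface, mm (default 0).
#' @return object of class `slice_plan`.
#' @export
#' @examples
#' plan_slices(proton_freq = 400.13, gradient = gradient_spec(16),
#'             bandwidth = 6000, omega = 60)
plan_slices <- function(nuc = nucleus("19F"), proton_freq, gradient, bandwidth,
                        omega, omega_unit = c("ppm", "Hz"),
                        coil_half_length = 9, interface_clearance = 0) {
  omega_unit <- match.arg(omega_unit)
  if (!is.numeric(omega) || omega < 0) slogp_stop("omega must be non-negative")
  if (coil_half_length <= 0) slogp_stop("coil_half_length must be positive")
  grad <- if (inherits(gradient, "gradient_spec")) gradient else
    gradient_spec(100, as_gradient_abs(gradient))
  offset_hz <- if (omega_unit == "ppm") ppm_to_hz(omega, nuc, proton_freq) else omega
  dz <- slice_thickness(bandwidth, grad, nuc)
  d_up <- offset_to_position(offset_hz, grad, nuc)
  d_lo <- offset_to_position(-offset_hz, grad, nuc)

  msgs <- character()
  check_slice <- function(d, label) {
    if (abs(d) - dz / 2 <= interface_clearance)
      msgs <<- c(msgs, sprintf("%s slice (centre %.3f mm, thickness %.3f mm) straddles or touches the solvent interface",
                               label, d, dz))
    if (abs(d) + dz / 2 > coil_half_length)
      msgs <<- c(msgs, sprintf("%s slice (centre %.3f mm, thickness %.3f mm) extends beyond the %.1f mm coil half-length",
                               label, d, dz, coil_half_length))
  }
  check_slice(d_up, "upper (octanol)")
  check_slice(d_lo, "lower (aqueous)")

  structure(list(
    nucleus = nuc, gradient = grad, bandwidth = bandwidth,
    proton_freq = proton_freq,
    offset_upper = offset_hz, offset_lower = -offset_hz,
    thickness = dz, position_upper = d_up, position_lower = d_lo,
    coil_half_length = coil_half_length,
    interface_clearance = interface_clearance,
    valid = length(msgs) == 0L, messages = msgs
  ), class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat("<slice plan>\n")
  cat(sprintf("  nucleus          : %s at %.2f MHz (1H %.2f MHz)\n",
              x$nucleus$name, basic_frequency(x$nucleus, x$proton_freq), x$proton_freq))
  cat(sprintf("  gradient         : %g%% of %g G/cm = %g G/cm\n",
              x$gradient$percent, x$gradient$g_max, x$gradient$g_abs))
  cat(sprintf("  pulse bandwidth  : %g Hz\n", x$bandwidth))
  cat(sprintf("  slice thickness  : %.2f mm\n", x$thickness))
  cat(sprintf("  offsets          : %+.1f / %+.1f Hz\n", x$offset_upper, x$offset_lower))
  cat(sprintf("  slice positions  : %+.2f mm (octanol) / %+.2f mm (aqueous)\n",
              x$position_upper, x$position_lower))
  cat(sprintf("  valid            : %s\n", if (x$valid) "yes" else "NO"))
  for (m in x$messages) cat("   - ", m, "\n", sep = "")
  invisible(x)
}
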