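# Acquisition parameters --------------------------------------------------

#' Acquisition parameters for a (pseudo-2D or scout) 19F experiment
#'
#' @param proton_freq 1H frequency of the magnet, MHz (400.13 for 9.4 T,
#'   600.13 for 14.1 T).
#' @param o1p transmitter (carrier) offset, ppm.
#' @param sweep_width spectral width, ppm (default 10).
#' @param td total number of real time-domain points (`td/2` complex
#'   points; a power of two by default).
#' @param ns number of transients (scans) co-added per row.
#' @param ds dummy transients (metadata only; steady state is modelled by
#'   the saturation factor, not by simulating dummies).
#' @param d1 relaxation delay between transients, s.
#' @param tau echo delay of the d1-90-tau-(sel180/grad)-tau-acquire
#'   sequence, s.
#' @param noise_sigma per-point time-domain noise scale (sd of each of the
#'   real and imaginary components, per transient).
#' @param seed integer seed for the generator.
#' @param nuc observed nucleus, a [nucleus_spec()].
#' @return object of class `acq_params`, with derived fields `bf1`
#'   (observe frequency, MHz), `sw_hz`, `dwell` (s) and `aq_time` (s).
#' @export
#' @examples
#' p <- acq_params(o1p = -62)
#' p$aq_time  # 2.17 s at 9.4 T with td 16384 over 10 ppm
acq_params <- function(proton_freq = 400.13, o1p, sweep_width = 10,
                       td = 16384, ns = 16, ds = 2, d1 = 30, tau = 0.005,
                       noise_sigma = 0, seed = 1L, nuc = nucleus("19F")) {
  if (td < 4 || td %% 2 != 0) slogp_stop("td must be an even number >= 4")
  if (sweep_width <= 0) slogp_stop("sweep_width must be positive")
  if (ns < 1) slogp_stop("ns must be >= 1")
  if (d1 <= 0) slogp_stop("d1 must be positive")
  if (tau < 0) slogp_stop("tau must be non-negative")
  if (noise_sigma < 0) slogp_stop("noise_sigma must be non-negative")
  bf1 <- basic_frequency(nuc, proton_freq)
  sw_hz <- sweep_width * bf1
  structure(list(proton_freq = proton_freq, o1p = o1p, sweep_width = sweep_width,
                 td = td, ns = ns, ds = ds, d1 = d1, tau = tau,
                 noise_sigma = noise_sigma, seed = as.integer(seed), nuc = nuc,
                 bf1 = bf1, sw_hz = sw_hz, dwell = 1 / sw_hz,
                 aq_time = (td / 2) / sw_hz),
            class = "acq_params")
}

#' Scout-scan acquisition parameters
#'
#' Wide-window single-pulse survey used to locate the strongest signal and
#' centre the carrier automatically: 490 ppm sweep centred at -50 ppm,
#' one transient, short relaxation delay.
#'
#' @inheritParams acq_params
#' @return an [acq_params()] object.
#' @export
scout_params <- function(proton_freq = 400.13, o1p = -50, sweep_width = 490,
                         td = 16384, ns = 1, d1 = 1, noise_sigma = 0,
                         seed = 1L, nuc = nucleus("19F")) {
  acq_params(proton_freq = proton_freq, o1p = o1p, sweep_width = sweep_width,
             td = td, ns = ns, ds = 0, d1 = d1, tau = 0,
             noise_sigma = noise_sigma, seed = seed, nuc = nuc)
}

# Counter-based seed substreams: one user-facing seed expands into
# independent per-row (and per-stage) seeds. Multiplier kept small enough
# that seed*69069 stays exactly representable in doubles for seed < 2^31.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 12345) %% 2147483647)
}
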