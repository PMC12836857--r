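# Scout-scan carrier placement --------------------------------------------

#' Pick the carrier position from a scout spectrum
#'
#' Returns the ppm position of the global magnitude maximum of a
#' wide-window scout spectrum, the automation's choice for the carrier
#' (o1p) of the subsequent slice-selective acquisitions. When the largest
#' signal is weaker than `noise_floor_k` times a robust estimate of the
#' spectral noise RMS and fewer than `max_ns` transients were used, the
#' scout is flagged for re-acquisition at `max_ns` transients - the
#' failure mode of near-even partitioning, where neither phase gives a
#' strong enough line in a single transient and the carrier would
#' otherwise land on a noise spike.
#'
#' @param spec a [spectrum1d()] of the scout scan.
#' @param ns_used transients used to acquire `spec`.
#' @param noise_floor_k detection threshold in noise-RMS units (default 10).
#' @param max_ns transient count of the rescan rule (default 16).
#' @return list with `o1p` (ppm of the maximum) and `rescan_needed`.
#' @export
determine_o1p <- function(spec, ns_used, noise_floor_k = 10, max_ns = 16) {
  if (length(spec$values) == 0L) slogp_stop("empty scout spectrum")
  mag <- Mod(spec$values)
  i_max <- which.max(mag)
  noise_rms <- stats::mad(Re(spec$values))
  rescan <- is.finite(noise_rms) && noise_rms > 0 &&
    mag[i_max] < noise_floor_k * noise_rms && ns_used < max_ns
  list(o1p = spec$ppm[i_max], rescan_needed = rescan)
}

#' Run the automated scout procedure on a sample
#'
#' Simulates the wide-window scout at `scout$ns` transients, peak-picks
#' it with [determine_o1p()], and - when flagged - re-simulates at
#' `max_ns` transients before picking again.
#'
#' @param sample a [partition_sample()].
#' @param scout scout acquisition, an [acq_params()] (default
#'   [scout_params()]).
#' @param main_params optional main-experiment [acq_params()] used to
#'   scale the scout noise (see [simulate_scout()]).
#' @param seed integer seed.
#' @param noise_floor_k,max_ns rescan rule parameters.
#' @return list with `o1p`, `ns_used`, `rescanned`.
#' @export
scout_o1p <- function(sample, scout = scout_params(), main_params = NULL,
                      seed = scout$seed, noise_floor_k = 10, max_ns = 16) {
  sc <- simulate_scout(sample, scout, main_params, seed = substream(seed, 10L))
  spec <- fourier(sc$fid, scout)
  pick <- determine_o1p(spec, ns_used = scout$ns, noise_floor_k = noise_floor_k,
                        max_ns = max_ns)
  rescanned <- FALSE
  ns_used <- scout$ns
  if (pick$rescan_needed) {
    scout2 <- scout
    scout2$ns <- max_ns
    sc2 <- simulate_scout(sample, scout2, main_params, seed = substream(seed, 11L))
    spec2 <- fourier(sc2$fid, scout2)
    pick <- determine_o1p(spec2, ns_used = max_ns, noise_floor_k = noise_floor_k,
                          max_ns = max_ns)
    rescanned <- TRUE
    ns_used <- max_ns
  }
  list(o1p = pick$o1p, ns_used = ns_used, rescanned = rescanned)
}
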