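# Signal model ------------------------------------------------------------
#
# Each slice row is a sum of damped complex exponentials (Lorentzian lines
# after FT) plus complex white Gaussian noise added per transient. Row
# amplitudes carry the physics the ratio method relies on:
#
#   A_phase = c_phase * slice_thickness * n_F * (1 - exp(-d1/T1)) * exp(-2 tau/T2)
#
# The slice cross-section is identical for the two rows and cancels in the
# ratio, so it is left out.

#' Steady-state saturation factor
#'
#' Fraction of equilibrium longitudinal magnetization recovered between
#' transients separated by a relaxation delay `d1`. Quantitative integrals
#' require `d1 >= 5 * T1` (factor >= 0.9933); shorter delays erode the
#' accuracy of the integral ratio.
#'
#' @param d1 relaxation delay, s.
#' @param t1 longitudinal relaxation time, s.
#' @return dimensionless scale in (0, 1].
#' @export
#' @examples
#' saturation_factor(30, 3)  # 1 - exp(-10)
saturation_factor <- function(d1, t1) {
  if (d1 <= 0 || t1 <= 0) slogp_stop("d1 and t1 must be positive")
  1 - exp(-d1 / t1)
}

#' Spin-echo attenuation factor
#'
#' Transverse relaxation loss over the 2*tau echo of the
#' d1-90-tau-(sel180/grad)-tau-acquire sequence.
#'
#' @param tau echo delay, s.
#' @param t2 transverse relaxation time, s.
#' @return `exp(-2 * tau / t2)`.
#' @export
echo_attenuation <- function(tau, t2) {
  if (tau < 0) slogp_stop("tau must be non-negative")
  if (t2 <= 0) slogp_stop("t2 must be positive")
  exp(-2 * tau / t2)
}

# Split (amplitude, hz) into multiplet lines with binomial weights.
expand_multiplet <- function(amplitude, hz, couplings) {
  lines <- data.frame(amp = amplitude, hz = hz)
  if (is.null(couplings)) return(lines)
  for (cp in couplings) {
    j <- cp[1]; m <- as.integer(cp[2])
    w <- choose(m - 1L, 0:(m - 1L)); w <- w / sum(w)
    offs <- (0:(m - 1L) - (m - 1L) / 2) * j
    lines <- do.call(rbind, lapply(seq_len(m), function(i)
      data.frame(amp = lines$amp * w[i], hz = lines$hz + offs[i])))
  }
  lines
}

#' Synthesize a single free-induction decay
#'
#' Builds `ns * sum_k A_k exp(i 2 pi nu_k t - pi Lambda_k t)` over the
#' acquisition grid of `params`, plus complex Gaussian noise of per-point
#' scale `noise_sigma * sqrt(ns)` (noise is added per transient, so the
#' co-added amplitude scales with `ns` and the noise with `sqrt(ns)`).
#'
#' @param peaks list of peak descriptions, each a list with `amplitude`
#'   (per-transient), `shift` (ppm), `fwhm` (Hz) and optional `couplings`.
#'   An empty list gives a noise-only FID.
#' @param params an [acq_params()].
#' @param noise_sigma per-transient time-domain noise scale; defaults to
#'   `params$noise_sigma`.
#' @param seed integer seed; defaults to `params$seed`.
#' @return complex vector of `params$td / 2` points.
#' @export
synth_fid <- function(peaks, params, noise_sigma = params$noise_sigma,
                      seed = params$seed) {
  n <- params$td / 2
  t <- (0:(n - 1)) * params$dwell
  sig <- complex(real = numeric(n), imaginary = numeric(n))
  for (pk in peaks) {
    nu0 <- (pk$shift - params$o1p) * params$bf1
    lines <- expand_multiplet(pk$amplitude, nu0, pk$couplings %||% NULL)
    for (i in seq_len(nrow(lines))) {
      sig <- sig + lines$amp[i] *
        exp(complex(imaginary = 2 * pi * lines$hz[i] * t) - pi * pk$fwhm * t)
    }
  }
  fid <- params$ns * sig
  if (noise_sigma > 0) {
    set.seed(seed)
    fid <- fid + sqrt(params$ns) * noise_sigma *
      complex(real = rnorm(n), imaginary = rnorm(n))
  }
  fid
}

#' Simulate a slice-selective pseudo-2D dataset
#'
#' Two spatially encoded FID rows from one partitioned sample: row 1 from
#' the upper n-octanol slice, row 2 from the lower aqueous slice. Row
#' amplitudes are proportional to the phase concentration, the (common)
#' slice volume, the equivalent 19F count, the T1 saturation factor at
#' `d1` and the echo attenuation at `tau`. Noise is seeded independently
#' per row from `params$seed` via counter-based substreams.
#'
#' @param sample a [partition_sample()].
#' @param plan a valid [plan_slices()] result; invalid plans are refused
#'   with their violation messages.
#' @param params an [acq_params()].
#' @return object of class `pseudo_spectrum2d`: `rows` (list of 2 complex
#'   FIDs, octanol first), `params`, `plan`, `provenance`.
#' @export
#' @examples
#' samp <- partition_sample(builtin_analytes("4-fluorophenol"))
#' plan <- plan_slices(proton_freq = 400.13, gradient = gradient_spec(16),
#'                     bandwidth = 6000, omega = 60)
#' ds <- simulate_pseudo2d(samp, plan, acq_params(o1p = -123.5, seed = 7))
simulate_pseudo2d <- function(sample, plan, params) {
  if (!inherits(sample, "partition_sample")) slogp_stop("sample must be a partition_sample")
  if (!inherits(plan, "slice_plan")) slogp_stop("plan must be a slice_plan")
  if (!plan$valid)
    slogp_stop(paste0("refusing to simulate from an invalid slice plan:\n  ",
                      paste(plan$messages, collapse = "\n  ")))
  a <- sample$analyte
  amp <- function(conc, t1, t2) {
    conc * plan$thickness * a$n_fluorine *
      saturation_factor(params$d1, t1) * echo_attenuation(params$tau, t2)
  }
  peaks_oct <- list(list(amplitude = amp(sample$c_oct, a$t1_oct, a$t2_oct),
                         shift = a$shift_oct, fwhm = a$linewidth_oct,
                         couplings = a$couplings))
  peaks_aq <- list(list(amplitude = amp(sample$c_aq, a$t1_aq, a$t2_aq),
                        shift = a$shift_aq, fwhm = a$linewidth_aq,
                        couplings = a$couplings))
  rows <- list(
    synth_fid(peaks_oct, params, seed = substream(params$seed, 1L)),
    synth_fid(peaks_aq, params, seed = substream(params$seed, 2L))
  )
  structure(list(
    rows = rows, params = params, plan = plan,
    provenance = list(
      generator = "slicelogp::simulate_pseudo2d",
      version = as.character(utils::packageVersion("slicelogp")),
      logp_true = sample$logp_true, seed = params$seed,
      row_order = c("oct", "aq"),
      analyte = unclass(a)[!vapply(unclass(a), is.null, logical(1))],
      n_total = sample$n_total, v_oct = sample$v_oct, v_aq = sample$v_aq
    )
  ), class = "pseudo_spectrum2d")
}

#' @export
print.pseudo_spectrum2d <- function(x, ...) {
  cat(sprintf("<pseudo-2D 19F dataset: %d rows x %d complex points>\n",
              length(x$rows), length(x$rows[[1]])))
  cat(sprintf("  sw %g ppm at o1p %g ppm, ns %d, d1 %g s\n",
              x$params$sweep_width, x$params$o1p, x$params$ns, x$params$d1))
  if (!is.null(x$provenance$logp_true))
    cat(sprintf("  provenance: %s, true log P %.3f, seed %d\n",
                x$provenance$analyte$name %||% "?", x$provenance$logp_true,
                x$provenance$seed))
  invisible(x)
}

#' Simulate the wide-window scout scan
#'
#' Whole-sample (non-slice-selective) single-pulse spectrum over a very
#' wide window, used by the automation to place the carrier. Per-phase
#' amplitudes are proportional to concentration times the detected column
#' height of each phase (phase volume over the tube cross-section, capped
#' at the coil half-length) times the 19F count and the saturation factor
#' at the scout's short `d1`. The scout's noise scale is derived from the
#' main experiment's per-point sigma by the detection-bandwidth ratio
#' `sqrt(sw_scout / sw_main)` when `main_params` is given.
#'
#' @param sample a [partition_sample()].
#' @param scout an [acq_params()], typically [scout_params()].
#' @param main_params optional [acq_params()] of the slice experiment,
#'   used to scale the noise; if `NULL`, `scout$noise_sigma` is used as is.
#' @param seed integer seed (defaults to `scout$seed`).
#' @param cross_section tube cross-section, mm^2 (default 13.85, a 4.2 mm
#'   inner diameter).
#' @param coil_half_length detected half-height, mm (default 9).
#' @return object of class `fid1d`: `fid`, `params`, `provenance`.
#' @export
simulate_scout <- function(sample, scout = scout_params(), main_params = NULL,
                           seed = scout$seed, cross_section = 13.85,
                           coil_half_length = 9) {
  a <- sample$analyte
  height <- function(v) min(v / cross_section, coil_half_length)
  peaks <- list(
    list(amplitude = sample$c_oct * height(sample$v_oct) * a$n_fluorine *
           saturation_factor(scout$d1, a$t1_oct),
         shift = a$shift_oct, fwhm = a$linewidth_oct, couplings = a$couplings),
    list(amplitude = sample$c_aq * height(sample$v_aq) * a$n_fluorine *
           saturation_factor(scout$d1, a$t1_aq),
         shift = a$shift_aq, fwhm = a$linewidth_aq, couplings = a$couplings)
  )
  sigma <- if (scout$noise_sigma > 0) {
    scout$noise_sigma
  } else if (!is.null(main_params)) {
    main_params$noise_sigma * sqrt(scout$sw_hz / main_params$sw_hz)
  } else 0
  structure(list(
    fid = synth_fid(peaks, scout, noise_sigma = sigma, seed = seed),
    params = scout,
    provenance = list(analyte = a$name, logp_true = sample$logp_true, seed = seed)
  ), class = "fid1d")
}

#' Time-domain noise scale needed for a target signal-to-noise ratio
#'
#' Runs a noiseless simulation of `sample` under `plan`/`params`, measures
#' the per-row peak heights the processing chain would see, and returns
#' the per-transient time-domain sigma for which the chosen peak attains
#' `snr_target` (with SNR defined as amplitude over twice the spectral
#' noise RMS). `reference = "summed"` targets the SNR in the summed
#' spectrum, whose noise is sqrt(2) times a single row's.
#'
#' @param sample a [partition_sample()].
#' @param plan a valid [plan_slices()] result.
#' @param params an [acq_params()] (its `noise_sigma`/`seed` are ignored).
#' @param snr_target desired SNR of the chosen peak.
#' @param peak `"minor"` (default; the smaller of the two), `"octanol"`
#'   or `"aqueous"`.
#' @param reference `"summed"` (default) or `"row"`.
#' @param zero_fill zero-filling factor used when measuring heights; keep
#'   equal to the processing setting.
#' @return per-transient time-domain noise sigma.
#' @export
noise_sigma_for_snr <- function(sample, plan, params, snr_target,
                                peak = c("minor", "octanol", "aqueous"),
                                reference = c("summed", "row"),
                                zero_fill = 2) {
  peak <- match.arg(peak)
  reference <- match.arg(reference)
  if (snr_target <= 0) slogp_stop("snr_target must be positive")
  p0 <- params
  p0$noise_sigma <- 0
  ds <- simulate_pseudo2d(sample, plan, p0)
  h <- vapply(ds$rows, function(fid)
    max(Re(fourier(fid, p0, zero_fill = zero_fill)$values)), numeric(1))
  h_peak <- switch(peak, minor = min(h), octanol = h[1], aqueous = h[2])
  sigma_row <- h_peak / (2 * snr_target)
  if (reference == "summed") sigma_row <- sigma_row / sqrt(2)
  # spectral real-part RMS of one row = sigma_t * sqrt(n_complex / ns)
  sigma_row * sqrt(params$ns / (params$td / 2))
}

#' Scout noise scale for a target detection margin
#'
#' Solves for the per-transient time-domain sigma at which the largest
#' scout peak sits at `target_margin` times the spectral noise RMS when
#' acquired with `scout$ns` transients. A margin below the automation's
#' detection floor (10) reproduces the reported failure mode of dilute,
#' near-evenly partitioned samples - a single-transient scout too weak to
#' place the carrier - while the 16-transient rescan quadruples the
#' margin and locates the signal reliably.
#'
#' @param sample a [partition_sample()].
#' @param scout scout acquisition parameters.
#' @param target_margin desired peak-to-noise-RMS ratio (default 7,
#'   below the floor of 10 so the rescan rule engages).
#' @return per-transient time-domain noise sigma for the scout.
#' @export
scout_noise_for_margin <- function(sample, scout = scout_params(),
                                   target_margin = 7) {
  if (target_margin <= 0) slogp_stop("target_margin must be positive")
  s0 <- scout
  s0$noise_sigma <- 0
  sc <- simulate_scout(sample, s0)
  h <- max(Mod(fourier(sc$fid, s0)$values))
  (h / target_margin) * sqrt(scout$ns / (scout$td / 2))
}
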