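# Shared fixtures, all built in code.

# Symmetric probe analyte: identical linewidths and relaxation in both
# phases, so the integral ratio carries no relaxation or capture bias and
# noiseless recovery is exact.
symmetric_analyte <- function(fwhm = 5, t1 = 3, t2 = 0.8) {
  analyte("probe", 3, shift_oct = -76.5, shift_aq = -73.5,
          linewidth_oct = fwhm, linewidth_aq = fwhm,
          t1_oct = t1, t1_aq = t1, t2_oct = t2, t2_aq = t2)
}

probe_params <- function(seed = 1L, ...) {
  acq_params(o1p = -75, seed = seed, ...)
}

# A quick noiseless dataset at a given true log P.
probe_dataset <- function(logp_true, seed = 1L, d1 = 30, a = symmetric_analyte()) {
  samp <- partition_sample(a, logp_true)
  simulate_pseudo2d(samp, default_plan(), probe_params(seed = seed, d1 = d1))
}
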