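test_that("fourier maps a delta FID to a flat spectrum and halves grid spacing on zero-fill", {
  p <- acq_params(o1p = -75, ns = 1, td = 1024)
  delta <- c(complex(real = 1), complex(real = numeric(511)))
  flat <- fourier(delta, p, zero_fill = 1)
  expect_equal(Re(flat$values), rep(0.5, 512))  # first-point halving
  expect_lt(max(abs(Im(flat$values))), 1e-12)

  pk <- list(list(amplitude = 1, shift = -75, fwhm = 6))
  p2 <- acq_params(o1p = -75, ns = 1, td = 8192)
  fid <- synth_fid(pk, p2)
  s1 <- fourier(fid, p2, zero_fill = 1)
  s2 <- fourier(fid, p2, zero_fill = 2)
  expect_equal(length(s2$values), 2 * length(s1$values))
  expect_equal(abs(diff(s2$ppm[1:2])), abs(diff(s1$ppm[1:2])) / 2)
  expect_equal(integrate_window(s2, -75, baseline = "none"),
               integrate_window(s1, -75, baseline = "none"), tolerance = 1e-3)
})

test_that("a damped exponential transforms to a Lorentzian of the right width", {
  p <- acq_params(o1p = -75, ns = 1, td = 16384)
  fwhm_hz <- 20
  fid <- synth_fid(list(list(amplitude = 1, shift = -75, fwhm = fwhm_hz)), p)
  sp <- fourier(fid, p)
  re <- Re(sp$values)
  half <- max(re) / 2
  above <- range(which(re > half))
  grid_hz <- abs(diff(sp$ppm[1:2])) * sp$bf1
  measured <- (diff(above) + 1) * grid_hz
  expect_equal(measured, fwhm_hz, tolerance = 2 * grid_hz / fwhm_hz)
})

test_that("autophase recovers an imposed rotation and tolerates pure noise", {
  p <- acq_params(o1p = -75, ns = 1, td = 8192)
  fid <- synth_fid(list(list(amplitude = 1, shift = -75, fwhm = 5)), p)
  sp <- fourier(fid, p)

  rot <- sp
  rot$values <- sp$values * exp(complex(imaginary = 37 * pi / 180))
  fixed <- autophase(rot)
  expect_equal(fixed$phase, 37, tolerance = 0.5)
  expect_equal(max(Re(fixed$values)), max(Re(sp$values)), tolerance = 1e-4)

  # already phased: correction below half a degree
  expect_lt(abs(autophase(sp)$phase), 0.5)

  # pure noise: no failure, low-confidence flag
  pn <- acq_params(o1p = -75, ns = 1, td = 2048, noise_sigma = 1)
  noise_spec <- fourier(synth_fid(list(), pn, seed = 3), pn)
  phased <- autophase(noise_spec)
  expect_s3_class(phased, "spectrum1d")
  expect_match(attr(phased, "warning"), "confidence")
})

test_that("windowed integrals follow the Lorentzian capture-fraction law", {
  p <- acq_params(o1p = -75, ns = 1, td = 16384)
  fwhm_hz <- 2
  fid <- synth_fid(list(list(amplitude = 1, shift = -75, fwhm = fwhm_hz)), p)
  sp <- fourier(fid, p)
  total <- 1 * sp$sweep_width / 2       # closed-form full integral
  win_hz <- 1 * sp$bf1
  capture <- (2 / pi) * atan(win_hz / fwhm_hz)
  got <- integrate_window(sp, -75, width = 1, baseline = "none")
  expect_equal(got / total, capture, tolerance = 0.002)

  # doubling the amplitude doubles the integral
  fid2 <- synth_fid(list(list(amplitude = 2, shift = -75, fwhm = fwhm_hz)), p)
  got2 <- integrate_window(fourier(fid2, p), -75, width = 1, baseline = "none")
  expect_equal(got2 / got, 2, tolerance = 1e-9)

  # a pure-noise window integrates to zero on average
  pn <- acq_params(o1p = -75, ns = 1, td = 2048, noise_sigma = 0.5)
  vals <- vapply(1:200, function(s)
    integrate_window(fourier(synth_fid(list(), pn, seed = s), pn), -75,
                     baseline = "none"),
    numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))

  expect_error(integrate_window(sp, -75, width = 30), class = "slicelogp_error")
})

test_that("SNR estimates hit a constructed target and scale with sqrt(ns)", {
  samp <- partition_sample(symmetric_analyte(), 0.5)
  plan <- default_plan()
  base <- probe_params()
  sigma <- noise_sigma_for_snr(samp, plan, base, 10, peak = "minor",
                               reference = "row")
  region <- c(-71.5, -70.2)
  snrs <- vapply(1:100, function(s) {
    p <- probe_params(seed = s, noise_sigma = sigma)
    ds <- simulate_pseudo2d(samp, plan, p)
    snr_estimate(fourier(ds$rows[[2]], p), -73.5, region)
  }, numeric(1))
  expect_equal(mean(snrs), 10, tolerance = 0.15)

  # quadrupling the transients doubles the SNR
  snrs64 <- vapply(1:50, function(s) {
    p <- probe_params(seed = s, noise_sigma = sigma, ns = 64)
    ds <- simulate_pseudo2d(samp, plan, p)
    snr_estimate(fourier(ds$rows[[2]], p), -73.5, region)
  }, numeric(1))
  expect_equal(mean(snrs64) / mean(snrs), 2, tolerance = 0.15)

  # a strictly noise-free region returns the capped sentinel
  flat <- spectrum1d(complex(real = c(rep(0, 200), 10, rep(0, 200))),
                     seq(5, -5, length.out = 401), o1p = 0, bf1 = 376.5,
                     sweep_width = 10)
  expect_equal(snr_estimate(flat, 0, c(2, 4)), 1e12)
  # a noiseless simulated spectrum is effectively infinite (truncation
  # wiggles only) and the degenerate-region contract errors
  p0 <- probe_params()
  ds0 <- simulate_pseudo2d(samp, plan, p0)
  sp0 <- fourier(ds0$rows[[1]], p0)
  expect_gt(snr_estimate(sp0, -76.5, region), 1e5)
  expect_error(snr_estimate(sp0, -76.5, c(-70.001, -70.0)),
               class = "slicelogp_error")
})

test_that("carrier placement picks the largest signal and applies the rescan rule", {
  p <- scout_params(td = 8192)
  clean <- fourier(synth_fid(list(list(amplitude = 1, shift = -75, fwhm = 5)), p), p)
  pick <- determine_o1p(clean, ns_used = 1)
  expect_equal(pick$o1p, -75, tolerance = 0.1)
  expect_false(pick$rescan_needed)

  two <- fourier(synth_fid(list(list(amplitude = 5, shift = -120, fwhm = 5),
                                list(amplitude = 1, shift = -75, fwhm = 5)), p), p)
  expect_equal(determine_o1p(two, 1)$o1p, -120, tolerance = 0.1)

  # a scout at SNR ~2 requests a rescan in at least 90% of seeds
  samp <- partition_sample(symmetric_analyte(), 0)
  scp <- scout_params()
  scp$noise_sigma <- scout_noise_for_margin(samp, scp, target_margin = 4)
  flags <- vapply(1:100, function(s) {
    spec <- fourier(simulate_scout(samp, scp, seed = s)$fid, scp)
    determine_o1p(spec, ns_used = 1)$rescan_needed
  }, logical(1))
  expect_gte(mean(flags), 0.9)

  # after the 16-transient rescan the carrier is found
  res <- scout_o1p(samp, scp, seed = 1)
  expect_true(res$rescanned)
  expect_equal(res$ns_used, 16)
  expect_equal(res$o1p, -75, tolerance = 0.2)
})

test_that("summation preserves integrals and resolves manually displaced peaks", {
  p <- acq_params(o1p = -75, ns = 1, td = 8192)
  a <- fourier(synth_fid(list(list(amplitude = 1, shift = -75.2, fwhm = 5)), p), p)
  b <- fourier(synth_fid(list(list(amplitude = 1, shift = -74.9, fwhm = 5)), p), p)

  s0 <- shift_and_sum(a, b, 0)
  expect_equal(s0$values, a$values + b$values)

  s2 <- shift_and_sum(a, b, 2)
  i_b0 <- integrate_window(b, -74.9, baseline = "none")
  i_b2 <- integrate_window(s2, -72.9, baseline = "none") -
    integrate_window(a, -72.9, baseline = "none")
  expect_equal(i_b2, i_b0, tolerance = 1e-3)

  # overlapping peaks become two resolvable maxima after displacement
  re <- Re(s2$values)
  pk1 <- which.max(re)
  far <- abs(s2$ppm - s2$ppm[pk1]) > 1
  expect_gt(max(re[far]), 0.5 * re[pk1])

  expect_warning(shift_and_sum(a, b, 80), "outside")
})

test_that("mode choice, log P arithmetic and error propagation follow their contracts", {
  expect_equal(choose_mode(35.66), "summed")
  expect_equal(choose_mode(8.01), "separate")
  expect_equal(choose_mode(10), "summed")  # >= at the boundary

  expect_equal(logp_value(1, 1), 0)
  expect_equal(logp_value(10, 1), 1)
  set.seed(13)
  for (i in 1:20) {
    x <- runif(2, 1e-6, 1e6)
    expect_equal(logp_value(x[1], x[2]), log10(x[1] / x[2]))
  }
  expect_error(logp_value(-1, 1), "octanol", class = "slicelogp_quant_error")
  expect_error(logp_value(1, 0), "aqueous", class = "slicelogp_quant_error")

  expect_equal(logp_error(10, 10), sqrt(2) / (10 * log(10)))
  expect_equal(logp_error(1e12, 1e12), 0, tolerance = 1e-11)
  # monotone decreasing in each argument
  s <- seq(5, 100, by = 5)
  expect_true(all(diff(vapply(s, logp_error, numeric(1), snr_aq = 10)) < 0))
  expect_true(all(diff(vapply(s, logp_error, numeric(1), snr_oct = 10)) < 0))
})
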