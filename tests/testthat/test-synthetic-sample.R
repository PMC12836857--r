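test_that("partition concentrations satisfy mass balance and the equilibrium", {
  # even split at log P = 0
  cc <- partition_concentrations(0, 0.1, 270, 270)
  expect_equal(cc$c_oct, cc$c_aq)
  expect_equal(cc$c_oct, 1000 * 0.1 / 540)

  # sign symmetry
  cm <- partition_concentrations(-1, 0.1, 300, 300)
  expect_equal(cm$c_aq / cm$c_oct, 10)

  # dilute trifluorotoluene case: 0.024 M nominal in 270 + 270 uL ends up
  # at ~2x the nominal total concentration in the octanol phase
  n <- 0.024 * 0.54
  ct <- partition_concentrations(3.01, n, 270, 270)
  expect_equal(ct$c_oct / ct$c_aq, 10^3.01)
  expect_equal(ct$c_oct / 0.024, 2, tolerance = 1e-3)

  # mass balance exact across the working range (mol/L x uL / 1000 = mmol)
  for (lp in seq(-5, 5, by = 0.5)) {
    cx <- partition_concentrations(lp, 0.05, 270, 270)
    expect_equal((cx$c_oct * 270 + cx$c_aq * 270) / 1000, 0.05)
  }
  expect_error(partition_concentrations(0, 0.1, 0, 270), class = "slicelogp_error")
})

test_that("saturation and echo factors match their closed forms", {
  expect_equal(saturation_factor(5 * 3, 3), 1 - exp(-5))
  expect_equal(saturation_factor(1e6, 3), 1)
  expect_equal(saturation_factor(30, 3), 1 - exp(-10))
  expect_equal(echo_attenuation(0, 1), 1)
  expect_equal(echo_attenuation(0.5, 1), exp(-1))
  expect_equal(echo_attenuation(0.005, 0.05), exp(-0.2))
  expect_error(saturation_factor(-1, 3), class = "slicelogp_error")
  expect_error(echo_attenuation(1, 0), class = "slicelogp_error")
})

test_that("synthesized FIDs are linear in amplitude and Parseval-consistent", {
  p <- acq_params(o1p = -75, ns = 1, noise_sigma = 0, td = 8192)
  pk <- function(a, s) list(amplitude = a, shift = s, fwhm = 4)

  # single noiseless peak: total spectrum integral equals A * sw_ppm / 2,
  # independent of td, and linear in A
  total_integral <- function(a, td) {
    pp <- acq_params(o1p = -75, ns = 1, td = td)
    sp <- fourier(synth_fid(list(pk(a, -75)), pp), pp, zero_fill = 1)
    x <- rev(sp$ppm)
    sum(diff(x) * (Re(sp$values)[-1] + Re(sp$values)[-length(x)]) / 2)
  }
  expect_equal(total_integral(1, 8192), 1 * 10 / 2, tolerance = 1e-3)
  expect_equal(total_integral(3, 8192) / total_integral(1, 8192), 3)
  expect_equal(total_integral(1, 16384), total_integral(1, 8192), tolerance = 1e-3)

  # two peaks with amplitudes 1 and 1e-3: windowed integral ratio 1e3.
  # The flanking baseline removes the major line's tail from the minor
  # window; a few percent of residual curvature (tail plus its spectral
  # fold-in around the 10 ppm window) remains at a 1000:1 ratio.
  fid <- synth_fid(list(pk(1, -76.5), pk(1e-3, -73.5)), p)
  sp <- fourier(fid, p)
  i1 <- integrate_window(sp, -76.5)
  i2 <- integrate_window(sp, -73.5)
  expect_equal(i1 / i2, 1e3, tolerance = 0.03)
  # without the correction the bias is an order of magnitude larger
  expect_gt(abs(integrate_window(sp, -73.5, baseline = "none") / i2 - 1), 0.1)

  # noise-only FIDs: spectral real-part RMS matches sigma * sqrt(n) over seeds
  p4 <- acq_params(o1p = -75, ns = 1, td = 4096, noise_sigma = 1)
  rms <- vapply(1:200, function(s)
    sd(Re(fourier(synth_fid(list(), p4, seed = s), p4, zero_fill = 1)$values)),
    numeric(1))
  expect_equal(mean(rms), sqrt(4096 / 2), tolerance = 0.1)
})

test_that("multiplets split with binomial weights and conserve amplitude", {
  p <- acq_params(o1p = -75, ns = 1, td = 8192)
  plain <- list(list(amplitude = 1, shift = -75, fwhm = 3))
  trip <- list(list(amplitude = 1, shift = -75, fwhm = 3,
                    couplings = list(c(12, 3))))
  sp_p <- fourier(synth_fid(plain, p), p)
  sp_t <- fourier(synth_fid(trip, p), p)
  expect_equal(integrate_window(sp_t, -75, baseline = "none"),
               integrate_window(sp_p, -75, baseline = "none"), tolerance = 1e-4)
  # central line of a 1:2:1 triplet carries about half the height (the
  # outer lines' tails add a percent or two at the centre)
  expect_equal(max(Re(sp_t$values)) / max(Re(sp_p$values)), 0.5, tolerance = 0.05)
})

test_that("pseudo-2D rows encode concentration, saturation and echo physics", {
  plan <- default_plan()
  a <- symmetric_analyte()

  # log P = 0, identical relaxation: equal row integrals
  ds0 <- probe_dataset(0)
  sp <- lapply(ds0$rows, fourier, params = ds0$params)
  i_oct <- integrate_window(sp[[1]], a$shift_oct, baseline = "none")
  i_aq <- integrate_window(sp[[2]], a$shift_aq, baseline = "none")
  expect_equal(i_oct / i_aq, 1, tolerance = 1e-9)

  # log P = 1: ratio 10 by construction
  ds1 <- probe_dataset(1)
  sp1 <- lapply(ds1$rows, fourier, params = ds1$params)
  r <- integrate_window(sp1[[1]], a$shift_oct, baseline = "none") /
    integrate_window(sp1[[2]], a$shift_aq, baseline = "none")
  expect_equal(r, 10, tolerance = 1e-6)

  # short d1 with unequal T1: recovered ratio biased by the saturation oracle
  au <- analyte("probe", 3, -76.5, -73.5, 5, 5,
                t1_oct = 1, t1_aq = 4, t2_oct = 0.8, t2_aq = 0.8)
  samp <- partition_sample(au, 1)
  pshort <- probe_params(d1 = 4)
  dss <- simulate_pseudo2d(samp, plan, pshort)
  sps <- lapply(dss$rows, fourier, params = pshort)
  ratio <- integrate_window(sps[[1]], -76.5, baseline = "none") /
    integrate_window(sps[[2]], -73.5, baseline = "none")
  bias_pred <- log10(saturation_factor(4, 1) / saturation_factor(4, 4))
  expect_equal(log10(ratio) - 1, bias_pred, tolerance = 1e-9)

  # an invalid plan is refused with its messages
  bad <- plan_slices(nucleus("19F"), 600.13, gradient_spec(16), 6000, 60)
  expect_error(simulate_pseudo2d(samp, bad, pshort), "coil",
               class = "slicelogp_error")
})

test_that("identical seeds give bit-identical datasets", {
  samp <- partition_sample(symmetric_analyte(), 1.2)
  p <- probe_params(seed = 77L, noise_sigma = 0.05)
  d1 <- simulate_pseudo2d(samp, default_plan(), p)
  d2 <- simulate_pseudo2d(samp, default_plan(), p)
  expect_identical(d1$rows, d2$rows)
  p2 <- probe_params(seed = 78L, noise_sigma = 0.05)
  d3 <- simulate_pseudo2d(samp, default_plan(), p2)
  expect_false(identical(d1$rows, d3$rows))
  # the two rows draw from independent noise substreams
  blank <- simulate_pseudo2d(partition_sample(symmetric_analyte(), 0, n_total = 0),
                             default_plan(), p)
  expect_false(identical(blank$rows[[1]], blank$rows[[2]]))
})

test_that("scout scans reflect whole-phase amounts and the sqrt(ns) law", {
  a <- builtin_analytes("trifluorotoluene")
  samp <- partition_sample(a, 3.01, n_total = 0.013)
  # well-partitioned: largest scout peak at the octanol shift
  sc <- simulate_scout(samp, scout_params())
  spec <- fourier(sc$fid, sc$params)
  expect_equal(spec$ppm[which.max(Mod(spec$values))], a$shift_oct,
               tolerance = 0.05)

  # peak-to-noise improves by 4 in expectation from ns 1 to ns 16
  scp <- scout_params()
  scp$noise_sigma <- scout_noise_for_margin(samp, scp, target_margin = 7)
  margin <- function(ns, seed) {
    s <- scp; s$ns <- ns
    sp <- fourier(simulate_scout(samp, s, seed = seed)$fid, s)
    max(Mod(sp$values)) / mad(Re(sp$values))
  }
  m1 <- vapply(1:100, function(s) margin(1, s), numeric(1))
  m16 <- vapply(1:100, function(s) margin(16, s), numeric(1))
  expect_equal(mean(m16) / mean(m1), 4, tolerance = 0.15)
})
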