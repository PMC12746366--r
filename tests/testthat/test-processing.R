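test_that("apodization is the identity at lb = 0 and composes additively", {
  p <- quiet_protocol()
  fid <- synthesize_fid(list(resonance_spec("NAD_H2", 9.3, 28)), 1, p, seed = 1)
  expect_identical(apodize(fid, 0)$samples, fid$samples)
  a <- apodize(apodize(fid, 2), 3)
  b <- apodize(fid, 5)
  expect_equal(a$samples, b$samples, tolerance = 1e-14)

  # attenuation of the last sample of a constant signal
  const <- fid_series(rep(1 + 0i, 64), p$dwell_time, p$transmitter_freq)
  last_t <- 63 * p$dwell_time
  expect_equal(Re(apodize(const, 5)$samples[1, 64]), exp(-pi * 5 * last_t))
})

test_that("5 Hz line broadening widens a 28 Hz Lorentzian to 33 Hz", {
  p <- quiet_protocol()
  fid <- synthesize_fid(list(resonance_spec("NAD_H2", 9.3, 28)), 1, p, seed = 1)
  grid <- 1 / (p$n_points * p$dwell_time)
  expect_lt(abs(measure_linewidth(to_spectrum(fid), 9.3) - 28), grid)
  expect_lt(abs(measure_linewidth(to_spectrum(apodize(fid, 5)), 9.3) - 33), grid)
})

test_that("coil combination is a matched filter against the water reference", {
  truth <- small_truth()
  p <- acquisition_protocol(n_channels = 4)
  ds <- generate_saturation_series(truth, p, resonances = small_resonances(),
                                   seed = 21)
  # single channel: unit-magnitude rescaling
  one <- ds$m0; one$samples <- one$samples[1, , drop = FALSE]
  wone <- ds$water_ref; wone$samples <- wone$samples[1, , drop = FALSE]
  comb1 <- combine_channels(one, wone)
  expect_equal(Mod(comb1$samples), Mod(one$samples), tolerance = 1e-9)

  # combination beats every individual channel's SNR (matched-filter property)
  snr_comb <- measure_snr(to_spectrum(apodize(combine_channels(ds$m0, ds$water_ref), 5)))
  for (c in 1:4) {
    ch <- ds$m0; ch$samples <- ch$samples[c, , drop = FALSE]
    wch <- ds$water_ref; wch$samples <- wch$samples[c, , drop = FALSE]
    snr_ch <- measure_snr(to_spectrum(apodize(combine_channels(ch, wch), 5)))
    expect_gt(snr_comb, snr_ch)
  }

  # common complex rescaling of channels + water: output changes only by |c|
  scale <- 2 - 1i
  sc <- ds$m0; sc$samples <- sc$samples * scale
  sw <- ds$water_ref; sw$samples <- sw$samples * scale
  comb_sc <- combine_channels(sc, sw)
  comb <- combine_channels(ds$m0, ds$water_ref)
  expect_equal(comb_sc$samples, comb$samples * Mod(scale), tolerance = 1e-9)

  # all-zero water reference is an error
  zw <- ds$water_ref; zw$samples[] <- 0
  expect_error(combine_channels(ds$m0, zw), "water reference")
})

test_that("equal-signal channels with independent noise gain ~sqrt(n) amplitude SNR at n = 4", {
  res <- list(resonance_spec("NAD_H2", 9.3, 28))
  gains <- rep(1 + 0i, 4)
  ratio <- vapply(1:8, function(i) {
    p4 <- acquisition_protocol(n_channels = 4, noise_sigma = 0.3,
                               channel_gain_range = c(1, 1))
    fid <- synthesize_fid(res, 1, p4, channel_weights = gains, seed = 300 + i)
    water <- resonance_spec("water", 4.7, 22, rel_amplitude = 50)
    pw <- p4; pw$reference_shift <- 4.7; pw$excitation_center <- 4.7
    wref <- synthesize_fid(list(water), 1, pw, channel_weights = gains,
                           seed = 600 + i)
    snr4 <- measure_snr(to_spectrum(combine_channels(fid, wref)))
    ch <- fid; ch$samples <- ch$samples[1, , drop = FALSE]
    wch <- wref; wch$samples <- wch$samples[1, , drop = FALSE]
    snr1 <- measure_snr(to_spectrum(combine_channels(ch, wch)))
    snr4 / snr1
  }, numeric(1))
  expect_gt(mean(ratio), 1.5)
  expect_lt(mean(ratio), 2.5)
})

test_that("channel alignment recovers an injected frequency offset and rejects a noise channel", {
  truth <- subject_truth()
  p <- acquisition_protocol(n_channels = 8, noise_sigma = 0.2)
  ds <- generate_saturation_series(truth, p, seed = 33)
  fid <- ds$m0
  df <- 1 / (ncol(fid$samples) * fid$dwell_time)

  # identical channels: zero shifts, nothing rejected
  same <- fid
  same$samples <- matrix(rep(fid$samples[1, ], 4), nrow = 4, byrow = TRUE)
  al0 <- align_and_reject_channels(same)
  expect_true(all(al0$shifts_hz == 0))
  expect_length(al0$rejected, 0)

  # +10 Hz offset on channel 3 is corrected by about -10 Hz
  t_ax <- (seq_len(ncol(fid$samples)) - 1) * fid$dwell_time
  shifted <- fid
  shifted$samples[3, ] <- shifted$samples[3, ] * exp(1i * 2 * pi * 10 * t_ax)
  al <- align_and_reject_channels(shifted)
  expect_lt(abs(al$shifts_hz[3] + 10), 1.5 * df)
  expect_length(al$rejected, 0)

  # a pure-noise channel among good ones is rejected
  noisy <- fid
  noisy$samples[5, ] <- complex(real = rnorm(ncol(fid$samples), 0, 0.3),
                                imaginary = rnorm(ncol(fid$samples), 0, 0.3))
  al2 <- align_and_reject_channels(noisy)
  expect_true(5 %in% al2$rejected)
  expect_equal(nrow(al2$fid$samples), 8 - length(al2$rejected))
})

test_that("the Fourier transform places tones correctly, conserves energy, and inverts", {
  p <- quiet_protocol()
  t <- (seq_len(p$n_points) - 1) * p$dwell_time
  tone <- fid_series(exp(1i * 2 * pi * 200 * t) * exp(-50 * t),
                     p$dwell_time, p$transmitter_freq, p$reference_shift)
  spec <- to_spectrum(tone)
  pk_ppm <- spec$ppm_axis[which.max(Mod(spec$values))]
  expect_lt(abs(pk_ppm - (p$reference_shift + 200 / p$transmitter_freq)), 0.005)

  # Parseval with the unitary normalization
  expect_equal(sum(Mod(spec$values)^2), sum(Mod(tone$samples)^2),
               tolerance = 1e-12)

  # lossless inversion
  back <- to_fid(spec)
  expect_equal(back$samples, tone$samples, tolerance = 1e-12)
})

test_that("SNR is linear in amplitude and infinite on noiseless input", {
  p <- acquisition_protocol(n_channels = 1, noise_sigma = 0.1)
  res <- small_resonances()
  f1 <- synthesize_fid(res, c(TRP = 1, NAD_H2 = 1), p, seed = 4)
  f2 <- synthesize_fid(res, c(TRP = 2, NAD_H2 = 2), p, seed = 4)
  s1 <- measure_snr(to_spectrum(apodize(f1, 5)))
  s2 <- measure_snr(to_spectrum(apodize(f2, 5)))
  expect_equal(s2 / s1, 2, tolerance = 0.1)

  f0 <- synthesize_fid(res, c(TRP = 1, NAD_H2 = 1), quiet_protocol(), seed = 4)
  expect_identical(measure_snr(to_spectrum(f0)), Inf)
  expect_error(measure_snr(to_spectrum(f1), noise_window = c(40, 50)),
               "noise window")
})

test_that("linewidth interpolation is accurate on an analytically sampled Lorentzian", {
  hz <- seq(-500, 500, by = 2)
  f0 <- 37.3
  hwhm <- 21
  vals <- complex(real = 1 / (1 + ((hz - f0) / hwhm)^2), imaginary = 0)
  tf <- 297.2
  spec <- mrs_spectrum(rev(vals), rev(9.7 + hz / tf))
  attr(spec, "transmitter_freq") <- tf
  attr(spec, "reference_shift") <- 9.7
  lw <- measure_linewidth(spec, 9.7 + f0 / tf)
  expect_lt(abs(lw - 2 * hwhm), 0.15)

  flat <- mrs_spectrum(rep(1 + 0i, length(hz)), rev(9.7 + hz / tf))
  attr(flat, "transmitter_freq") <- tf
  attr(flat, "reference_shift") <- 9.7
  expect_error(measure_linewidth(flat, 9.7), "local maximum")
})
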