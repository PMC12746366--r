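#' Acquisition protocol
#'
#' Parameters of the spectrally selective saturation-recovery acquisition the
#' simulator emulates: 7 T transmitter (297.2 MHz), excitation window
#' 9.7 +/- 1 ppm (FWHM 2 ppm), selective saturation delays
#' TS = 25, 50, 300, 600 ms, broadband delays TS = 500, 1000, 2000, 4000 ms,
#' and a no-saturation scan treated as TS = 10 s for fitting purposes.
#'
#' `noise_sigma` is the per-channel standard deviation of each real/imaginary
#' noise component per time sample; the default is calibrated by simulation so
#' the NAD+ H2 spectral SNR of the processed no-saturation scan is ~27 (see
#' [calibrate_noise_sigma()]).
#'
#' @param transmitter_freq MHz.
#' @param dwell_time Seconds per complex point.
#' @param n_points Complex points per FID.
#' @param n_channels Receive channels.
#' @param excitation_center,excitation_fwhm Excitation window, ppm.
#' @param ts_selective,ts_broadband Saturation delays, ms (sorted, positive).
#' @param ts_m0 Nominal TS assigned to the no-saturation scan, ms.
#' @param noise_sigma Per-channel complex-Gaussian noise SD.
#' @param reference_shift Carrier position, ppm.
#' @param channel_gain_range Magnitude range for per-channel complex
#'   sensitivities.
#' @param seed Default RNG seed for generation.
#' @return Object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(transmitter_freq = 297.2,
                                 dwell_time = 1 / 3000,
                                 n_points = 1024,
                                 n_channels = 8,
                                 excitation_center = 9.7,
                                 excitation_fwhm = 2,
                                 ts_selective = c(25, 50, 300, 600),
                                 ts_broadband = c(500, 1000, 2000, 4000),
                                 ts_m0 = 10000,
                                 noise_sigma = 0.44,
                                 reference_shift = 9.7,
                                 channel_gain_range = c(0.7, 1.3),
                                 seed = 1L) {
  stopifnot(dwell_time > 0, n_points >= 2, n_channels >= 1,
            excitation_fwhm > 0, noise_sigma >= 0,
            all(ts_selective > 0), !is.unsorted(ts_selective),
            all(ts_broadband > 0), !is.unsorted(ts_broadband), ts_m0 > 0)
  structure(as.list(environment()), class = "acquisition_protocol")
}

#' Subject-level ground truth for the two-pool exchange simulator
#'
#' Per-resonance longitudinal relaxation time of the metabolite pool (spin A),
#' metabolite-to-water magnetization exchange rate sigma_AB, and saturation
#' efficiencies for the selective and broadband experiments. Water (spin B)
#' has fixed T1 (1800 ms) and an equilibrium-magnetization ratio
#' M0_B / M0_A = (2 x 55 M) / (0.3 mM), i.e. two water protons at 55 M against
#' 0.3 mM metabolite.
#'
#' @param T1_A_ms Named per-resonance metabolite T1, ms.
#' @param sigma_AB_hz Named per-resonance exchange rate, Hz.
#' @param k_sel,k_broad Named per-resonance saturation efficiencies in \[0,1\].
#' @param M0_A Equilibrium metabolite magnetization (arbitrary units).
#' @param M0_B_over_M0_A Water/metabolite equilibrium ratio.
#' @param T1_B_ms Water T1, ms.
#' @param T1_baseline_ms,k_baseline Mono-exponential recovery parameters for
#'   the upfield baseline complex.
#' @return Object of class `subject_truth`.
#' @export
subject_truth <- function(T1_A_ms = c(TRP = 622.3, NAD_H2 = 924.9,
                                      NAD_H6 = 1800.0, NAD_H4 = 2057.3),
                          sigma_AB_hz = c(TRP = 12.3, NAD_H2 = 5.7,
                                          NAD_H6 = 3.3, NAD_H4 = 3.0),
                          k_sel = c(TRP = 0.85, NAD_H2 = 0.85,
                                    NAD_H6 = 0.85, NAD_H4 = 0.60),
                          k_broad = c(TRP = 0.85, NAD_H2 = 0.85,
                                      NAD_H6 = 0.85, NAD_H4 = 0.85),
                          M0_A = 1,
                          M0_B_over_M0_A = 2 * 55 / 0.3e-3,
                          T1_B_ms = 1800,
                          T1_baseline_ms = 300,
                          k_baseline = 0.85) {
  stopifnot(all(T1_A_ms > 0), all(sigma_AB_hz >= 0),
            all(k_sel >= 0 & k_sel <= 1), all(k_broad >= 0 & k_broad <= 1),
            M0_A > 0, M0_B_over_M0_A > 0, T1_B_ms > 0)
  stopifnot(identical(names(T1_A_ms), names(sigma_AB_hz)),
            identical(names(T1_A_ms), names(k_sel)),
            identical(names(T1_A_ms), names(k_broad)))
  structure(as.list(environment()), class = "subject_truth")
}

#' Cohort truth sampler at the in-vivo summary statistics
#'
#' Returns a function drawing `subject_truth` objects whose T1_A and sigma_AB
#' are normal at the cohort means/SDs of the 7 T two-spin fits
#' (T1: 622.3 +/- 405.5, 924.9 +/- 233.7, 1800.0 +/- 985.5, 2057.3 +/- 573.5 ms;
#' sigma: 12.3 +/- 3.1, 5.7 +/- 1.6, 3.3 +/- 0.8, 3.0 +/- 1.5 Hz for TRP,
#' NAD H2, H6, H4), truncated to physical ranges. Saturation efficiencies get
#' a small jitter around their defaults.
#'
#' @param t1_mean,t1_sd,sigma_mean,sigma_sd Named per-resonance vectors.
#' @param t1_min Lower truncation for T1_A, ms.
#' @param k_jitter_sd SD of truncated-normal jitter on saturation
#'   efficiencies.
#' @return `function(n)` returning a list of `subject_truth`.
#' @export
truth_sampler <- function(t1_mean = c(TRP = 622.3, NAD_H2 = 924.9,
                                      NAD_H6 = 1800.0, NAD_H4 = 2057.3),
                          t1_sd = c(TRP = 405.5, NAD_H2 = 233.7,
                                    NAD_H6 = 985.5, NAD_H4 = 573.5),
                          sigma_mean = c(TRP = 12.3, NAD_H2 = 5.7,
                                         NAD_H6 = 3.3, NAD_H4 = 3.0),
                          sigma_sd = c(TRP = 3.1, NAD_H2 = 1.6,
                                       NAD_H6 = 0.8, NAD_H4 = 1.5),
                          t1_min = 100, k_jitter_sd = 0.03) {
  force(t1_mean); force(t1_sd); force(sigma_mean); force(sigma_sd)
  base <- subject_truth()
  function(n) {
    lapply(seq_len(n), function(i) {
      t1 <- pmax(t1_min, stats::rnorm(length(t1_mean), t1_mean, t1_sd))
      sg <- pmax(0.2, stats::rnorm(length(sigma_mean), sigma_mean, sigma_sd))
      names(t1) <- names(t1_mean); names(sg) <- names(sigma_mean)
      jit <- function(k) stats::setNames(
        pmin(0.98, pmax(0.3, k + stats::rnorm(length(k), 0, k_jitter_sd))),
        names(k))
      subject_truth(T1_A_ms = t1, sigma_AB_hz = sg,
                    k_sel = jit(base$k_sel), k_broad = jit(base$k_broad))
    })
  }
}

#' Degenerate sampler returning a fixed truth for every subject
#'
#' @param truth A `subject_truth`.
#' @return `function(n)` returning `n` copies of `truth`.
#' @export
constant_sampler <- function(truth = subject_truth()) {
  force(truth)
  function(n) rep(list(truth), n)
}
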