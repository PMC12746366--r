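#' Exponential line broadening
#'
#' Multiplies every sample by `exp(-pi * lb * t)`, which adds `lb` Hz to the
#' Lorentzian full width at half maximum of every line. `lb = 0` is the
#' identity; successive apodizations compose additively.
#'
#' @param fid A [fid_series()].
#' @param lb Line broadening, Hz (>= 0).
#' @return Apodized [fid_series()].
#' @export
apodize <- function(fid, lb = 5) {
  stopifnot(inherits(fid, "fid_series"), lb >= 0)
  if (lb == 0) return(fid)
  w <- exp(-pi * lb * fid_time(fid))
  fid$samples <- sweep(fid$samples, 2, w, "*")
  fid$meta$lb_hz <- (fid$meta$lb_hz %||% 0) + lb
  fid
}

# water-reference complex amplitude per channel ("peak": spectral peak value;
# "first_point": first FID sample)
water_channel_amplitudes <- function(water_ref, method = c("peak", "first_point")) {
  method <- match.arg(method)
  if (method == "first_point") return(water_ref$samples[, 1])
  apply(water_ref$samples, 1, function(ch) {
    sp <- stats::fft(ch)
    sp[which.max(Mod(sp))]
  })
}

#' Combine receive channels using the water reference scan
#'
#' Matched-filter coil combination: per-channel complex weights are the
#' conjugates of the water-reference channel amplitudes, normalized to unit
#' total power, so channel signals add coherently and the combined noise SD
#' equals the single-channel noise SD. With one channel this is a
#' unit-magnitude rescaling. Invariant to a common complex scale applied to
#' all channels and the water reference.
#'
#' @param fid Multi-channel [fid_series()].
#' @param water_ref Water reference [fid_series()] with the same channel
#'   count.
#' @param method `"peak"` (water spectral peak; robust at short dead time) or
#'   `"first_point"`.
#' @return Single-channel [fid_series()].
#' @export
combine_channels <- function(fid, water_ref, method = c("peak", "first_point")) {
  stopifnot(inherits(fid, "fid_series"), inherits(water_ref, "fid_series"))
  if (n_channels(fid) != n_channels(water_ref)) {
    stop("channel counts differ between fid and water reference")
  }
  amps <- water_channel_amplitudes(water_ref, method)
  norm <- sqrt(sum(Mod(amps)^2))
  if (norm == 0) stop("water reference is all zero: cannot derive channel weights")
  w <- Conj(amps) / norm
  combined <- as.vector(w %*% fid$samples)
  out <- fid_series(combined, fid$dwell_time, fid$transmitter_freq,
                    fid$reference_shift, meta = fid$meta)
  out$meta$combined <- TRUE
  out
}

# fftshift-style frequency axis (Hz, relative to carrier) for n points
fft_freqs <- function(n, dwell) {
  k <- seq_len(n) - 1
  f <- k / (n * dwell)
  f[k >= n / 2] <- f[k >= n / 2] - 1 / dwell
  f
}

#' Fourier transform a single-channel FID to a spectrum
#'
#' Negative-exponent forward DFT, normalized by `1/sqrt(N)` so that Parseval's
#' identity holds exactly; the ppm axis is derived from the dwell time,
#' transmitter frequency, and carrier position and stored monotone decreasing
#' (downfield on the left). Inverted losslessly by [to_fid()].
#'
#' @param fid Single-channel [fid_series()].
#' @return An [mrs_spectrum()].
#' @export
to_spectrum <- function(fid) {
  stopifnot(inherits(fid, "fid_series"))
  if (n_channels(fid) != 1) stop("to_spectrum expects a combined single-channel FID")
  x <- fid$samples[1, ]
  n <- length(x)
  raw <- stats::fft(x) / sqrt(n)
  f <- fft_freqs(n, fid$dwell_time)
  ord <- order(f, decreasing = TRUE)
  spec <- mrs_spectrum(raw[ord], hz_to_ppm(f[ord], fid),
                       provenance = c(fid$meta$provenance %||% character(), "fft"))
  attr(spec, "dwell_time") <- fid$dwell_time
  attr(spec, "transmitter_freq") <- fid$transmitter_freq
  attr(spec, "reference_shift") <- fid$reference_shift
  attr(spec, "unshift_order") <- order(ord)
  attr(spec, "meta") <- fid$meta
  spec
}

#' Inverse transform a spectrum back to the FID
#'
#' @param spec An [mrs_spectrum()] produced by [to_spectrum()].
#' @return Single-channel [fid_series()].
#' @export
to_fid <- function(spec) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  n <- length(spec$values)
  raw <- spec$values[attr(spec, "unshift_order")]
  x <- stats::fft(raw, inverse = TRUE) / sqrt(n)
  fid_series(x, attr(spec, "dwell_time"), attr(spec, "transmitter_freq"),
             attr(spec, "reference_shift"), meta = attr(spec, "meta") %||% list())
}

band_index <- function(spec, ppm_range) {
  which(spec$ppm_axis >= min(ppm_range) & spec$ppm_axis <= max(ppm_range))
}

#' Align channels to the array average and reject dissimilar channels
#'
#' Each channel is frequency-shifted (integer spectral bins within
#' `max_shift`) to maximize the normalized cross-correlation of its
#' lightly-smoothed magnitude spectrum with the channel-average magnitude
#' spectrum over the downfield band; channels whose best similarity stays
#' below `similarity_min` are removed. The smoothing (boxcar, `smooth_bins`
#' bins, narrower than any linewidth) keeps the metric from being degraded by
#' single-channel noise while leaving a pure-noise channel uncorrelated.
#' Corrections are meant to be estimated on the highest-SNR scan of a subject
#' (the no-saturation scan) and applied to its other scans.
#'
#' @param fid Multi-channel [fid_series()].
#' @param max_shift Largest correction magnitude, Hz.
#' @param similarity_min Rejection threshold for the normalized
#'   cross-correlation (default 0.7).
#' @param band ppm band over which similarity is computed.
#' @param smooth_bins Boxcar width (spectral bins) used before correlating.
#' @return List: `fid` (aligned, surviving channels), `shifts_hz` (applied
#'   corrections, all channels), `similarity`, `rejected` (channel indices).
#' @export
align_and_reject_channels <- function(fid, max_shift = 20, similarity_min = 0.7,
                                      band = c(8.5, 10.5), smooth_bins = 9) {
  stopifnot(inherits(fid, "fid_series"), n_channels(fid) >= 1)
  n <- n_points(fid)
  df <- 1 / (n * fid$dwell_time)
  f <- fft_freqs(n, fid$dwell_time)
  ord <- order(f, decreasing = TRUE)
  smooth <- function(x) {
    if (smooth_bins <= 1) return(x)
    as.numeric(stats::filter(x, rep(1 / smooth_bins, smooth_bins), sides = 2))
  }
  mags <- t(apply(fid$samples, 1, function(ch) smooth(Mod(stats::fft(ch))[ord])))
  ppm <- hz_to_ppm(f[ord], fid)
  idx <- which(ppm >= band[1] & ppm <= band[2])
  if (length(idx) < 4) stop("similarity band contains too few points")
  ref <- colMeans(mags)
  max_bins <- floor(max_shift / df)
  shifts <- numeric(n_channels(fid))
  sims <- numeric(n_channels(fid))
  for (c in seq_len(n_channels(fid))) {
    best <- c(sim = -Inf, bins = 0)
    for (b in -max_bins:max_bins) {
      # shifting the channel spectrum by b bins toward the reference
      src <- idx + b
      ok <- src >= 1 & src <= n
      if (sum(ok) < 4) next
      s <- suppressWarnings(stats::cor(ref[idx[ok]], mags[c, src[ok]],
                                       use = "complete.obs"))
      if (is.finite(s) && s > best["sim"]) best <- c(sim = s, bins = b)
    }
    # axis is decreasing in ppm: +b bins along the stored axis = -b*df in Hz
    shifts[c] <- best[["bins"]] * df
    sims[c] <- best[["sim"]]
  }
  rejected <- which(sims < similarity_min)
  if (length(rejected) == n_channels(fid)) {
    stop("all channels rejected by the similarity criterion")
  }
  fid <- apply_channel_corrections(fid, shifts, rejected)
  list(fid = fid, shifts_hz = shifts, similarity = sims, rejected = rejected)
}

# apply per-channel frequency corrections and drop rejected channels
apply_channel_corrections <- function(fid, shifts_hz, rejected = integer(0)) {
  t_ax <- fid_time(fid)
  for (c in seq_len(n_channels(fid))) {
    if (shifts_hz[c] != 0) {
      fid$samples[c, ] <- fid$samples[c, ] * exp(1i * 2 * pi * shifts_hz[c] * t_ax)
    }
  }
  if (length(rejected)) {
    fid$samples <- fid$samples[-rejected, , drop = FALSE]
  }
  fid
}

#' Spectral signal-to-noise ratio
#'
#' Peak magnitude near `peak_ppm` divided by the noise standard deviation of
#' the real part of a signal-free window, after zeroth-order phasing that
#' makes the peak real-positive. The window is detrended with a quadratic
#' polynomial before taking the SD, so the slowly varying tails of downfield
#' Lorentzians do not inflate the noise estimate. Defaults follow the in-vivo
#' convention: NAD+ H2 at 9.3 ppm against the 10.8-11.8 ppm region upfield
#' (in frequency) of tryptophan. A noiseless spectrum returns `Inf`.
#'
#' @param spec An [mrs_spectrum()].
#' @param peak_ppm Nominal peak position, ppm.
#' @param noise_window Signal-free ppm range.
#' @param search_ppm Half-width of the peak search window, ppm.
#' @return Dimensionless SNR.
#' @export
measure_snr <- function(spec, peak_ppm = 9.3, noise_window = c(10.8, 11.8),
                        search_ppm = 0.15) {
  pk_idx <- band_index(spec, peak_ppm + c(-1, 1) * search_ppm)
  nz_idx <- band_index(spec, noise_window)
  if (!length(pk_idx)) stop("peak window falls outside the spectral axis")
  if (length(nz_idx) < 8) stop("noise window falls outside the spectral axis")
  pk <- spec$values[pk_idx[which.max(Mod(spec$values[pk_idx]))]]
  phase <- Arg(pk)
  w <- Re(spec$values[nz_idx] * exp(-1i * phase))
  x <- seq_along(w)
  noise_sd <- stats::sd(stats::resid(stats::lm(w ~ x + I(x^2))))
  # degenerate (effectively noiseless) input: +Inf sentinel. Above ~10^3 the
  # window residual is lineshape-tail curvature, not thermal noise, so no
  # meaningful finite SNR exists.
  if (noise_sd <= 1e-3 * Mod(pk)) return(Inf)
  Mod(pk) / noise_sd
}

#' Full width at half maximum of a spectral peak
#'
#' Locates the local maximum of the magnitude spectrum within `search_ppm` of
#' the nominal position, applies zeroth-order phasing so the peak is real
#' positive, and measures the FWHM of the absorption (real) lineshape in Hz
#' with linear interpolation of the half-maximum crossings between grid
#' points. (The magnitude of a complex Lorentzian mixes in the dispersion
#' component and would read sqrt(3) times too wide.)
#'
#' @param spec An [mrs_spectrum()].
#' @param peak_ppm Nominal peak position, ppm.
#' @param search_ppm Half-width of the peak search window, ppm.
#' @return Linewidth, Hz.
#' @export
measure_linewidth <- function(spec, peak_ppm, search_ppm = 0.15) {
  idx <- band_index(spec, peak_ppm + c(-1, 1) * search_ppm)
  if (length(idx) < 3) stop("peak search window too narrow for the axis")
  i_max <- idx[which.max(Mod(spec$values[idx]))]
  mag <- Re(spec$values * exp(-1i * Arg(spec$values[i_max])))
  i_pk <- idx[which.max(mag[idx])]
  if (i_pk <= 1 || i_pk >= length(mag) ||
      !(mag[i_pk] > mag[i_pk - 1] || mag[i_pk] > mag[i_pk + 1])) {
    stop("no local maximum near ", peak_ppm, " ppm")
  }
  half <- mag[i_pk] / 2
  tf <- attr(spec, "transmitter_freq")
  hz <- (spec$ppm_axis - attr(spec, "reference_shift")) * tf
  cross <- function(dir) {
    i <- i_pk
    while (i + dir >= 1 && i + dir <= length(mag) && mag[i + dir] > half) i <- i + dir
    j <- i + dir
    if (j < 1 || j > length(mag)) stop("half-maximum crossing falls off the axis")
    frac <- (mag[i] - half) / (mag[i] - mag[j])
    hz[i] + frac * (hz[j] - hz[i])
  }
  abs(cross(-1) - cross(1))
}
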