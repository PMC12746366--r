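# Shared fixtures: small protocols and an independent brute-force oracle for
# damped-exponential fitting (variable projection over frequency/damping,
# amplitudes by linear least squares), used to cross-check HSVD.

quiet_protocol <- function(...) {
  acquisition_protocol(n_channels = 1, noise_sigma = 0, ...)
}

# exact damped complex exponential sum on a protocol grid
make_exponential_fid <- function(freq_hz, damping, amplitude, protocol,
                                 meta = list()) {
  t <- (seq_len(protocol$n_points) - 1) * protocol$dwell_time
  x <- Reduce(`+`, lapply(seq_along(freq_hz), function(k) {
    amplitude[k] * exp((1i * 2 * pi * freq_hz[k] - damping[k]) * t)
  }))
  fid_series(x, protocol$dwell_time, protocol$transmitter_freq,
             protocol$reference_shift, meta = meta)
}

# brute-force nonlinear least squares oracle: optimizes (freq, damping) of K
# lines with amplitudes profiled out; multi-start from spectral peak picking.
oracle_fit_exponentials <- function(fid, k) {
  x <- fid$samples[1, ]
  n <- length(x)
  t <- (seq_len(n) - 1) * fid$dwell_time
  design <- function(fd) {
    vapply(seq_len(k), function(j) {
      exp((1i * 2 * pi * fd[j] - fd[k + j]) * t)
    }, complex(n))
  }
  rss <- function(fd) {
    if (any(fd[(k + 1):(2 * k)] <= 0)) return(1e12)
    X <- design(fd)
    a <- tryCatch(qr.coef(qr(X), x), error = function(e) NULL)
    if (is.null(a) || anyNA(a)) return(1e12)
    sum(Mod(x - X %*% a)^2)
  }
  # peak-pick starting frequencies from the magnitude spectrum
  sp <- Mod(stats::fft(x))
  f_axis <- dfmx:::fft_freqs(n, fid$dwell_time)
  ord <- order(sp, decreasing = TRUE)
  starts_f <- unique(round(f_axis[ord[1:(4 * k)]]))[1:k]
  best <- NULL
  for (d0 in c(50, 120, 250)) {
    fit <- stats::nlminb(c(starts_f, rep(d0, k)), rss,
                         control = list(iter.max = 800, eval.max = 1600,
                                        rel.tol = 1e-15))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  fd <- best$par
  X <- design(fd)
  a <- qr.coef(qr(X), x)
  o <- order(fd[1:k])
  list(frequency_hz = fd[1:k][o], damping_per_s = fd[(k + 1):(2 * k)][o],
       amplitude = a[o], rss = best$objective)
}

# two-resonance singlet truth for lightweight end-to-end fixtures
small_truth <- function(...) {
  args <- list(
    T1_A_ms = c(TRP = 622.3, NAD_H2 = 924.9),
    sigma_AB_hz = c(TRP = 12.3, NAD_H2 = 5.7),
    k_sel = c(TRP = 0.85, NAD_H2 = 0.85),
    k_broad = c(TRP = 0.85, NAD_H2 = 0.85)
  )
  do.call(subject_truth, utils::modifyList(args, list(...)))
}

small_resonances <- function() default_resonances()[c("TRP", "NAD_H2")]
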