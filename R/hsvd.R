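#' Hankel SVD decomposition of a FID
#'
#' Models the time-domain signal as a sum of damped complex exponentials. A
#' Hankel matrix with `floor(N/2)` rows is built from the samples; the
#' truncated SVD's left singular subspace is propagated one sample forward
#' (shift invariance), and the eigenvalues of the resulting map give the
#' signal poles `z_k = exp((2 pi i f_k - d_k) dt)`. Growing components
#' (damping <= 0) are discarded; complex amplitudes follow by linear least
#' squares of the FID onto the retained poles.
#'
#' @param fid Single-channel [fid_series()].
#' @param n_components Number of singular components retained (default 60).
#' @return Data frame of class `hsvd_components` with columns `frequency_hz`
#'   (relative to the carrier), `damping_per_s` (> 0), and complex
#'   `amplitude`, sorted by frequency; acquisition attributes are attached for
#'   ppm conversion and reconstruction. All-zero input yields zero rows.
#' @export
hsvd_decompose <- function(fid, n_components = 60) {
  stopifnot(inherits(fid, "fid_series"))
  if (n_channels(fid) != 1) stop("hsvd_decompose expects a combined single-channel FID")
  x <- fid$samples[1, ]
  n <- length(x)
  if (n < 2 * n_components) stop("need at least 2 * n_components samples")
  empty <- data.frame(frequency_hz = numeric(0), damping_per_s = numeric(0),
                      amplitude = complex(0))
  if (all(x == 0)) return(hsvd_result(empty, fid))
  L <- floor(n / 2)
  K <- min(n_components, L - 1)
  H <- matrix(0i, L, n - L + 1)
  for (j in seq_len(n - L + 1)) H[, j] <- x[j:(j + L - 1)]
  sv <- svd(H, nu = K, nv = 0)
  # truncate at the numerical rank: singular vectors below it carry no signal
  # and would emit spurious poles with large mutually-cancelling amplitudes
  K <- min(K, sum(sv$d > 1e-10 * sv$d[1]))
  U <- sv$u[, seq_len(K), drop = FALSE]
  # shift-invariance eigenproblem on the signal subspace
  Fm <- qr.coef(qr(U[1:(L - 1), , drop = FALSE]), U[2:L, , drop = FALSE])
  z <- eigen(Fm, only.values = TRUE)$values
  dt <- fid$dwell_time
  damping <- -log(Mod(z)) / dt
  freq <- Arg(z) / (2 * pi * dt)
  keep <- is.finite(damping) & damping > 0
  if (!any(keep)) return(hsvd_result(empty, fid))
  z <- z[keep]; damping <- damping[keep]; freq <- freq[keep]
  V <- outer(seq_len(n) - 1, seq_along(z), function(nn, kk) z[kk]^nn)
  amp <- qr.coef(qr(V), x)
  comps <- data.frame(frequency_hz = freq, damping_per_s = damping)
  comps$amplitude <- amp
  comps <- comps[order(comps$frequency_hz), , drop = FALSE]
  rownames(comps) <- NULL
  hsvd_result(comps, fid)
}

hsvd_result <- function(comps, fid) {
  class(comps) <- c("hsvd_components", "data.frame")
  attr(comps, "dwell_time") <- fid$dwell_time
  attr(comps, "transmitter_freq") <- fid$transmitter_freq
  attr(comps, "reference_shift") <- fid$reference_shift
  attr(comps, "n_points") <- n_points(fid)
  comps
}

#' Reconstruct the time-domain signal of a component set
#'
#' @param components `hsvd_components` (or data frame with `frequency_hz`,
#'   `damping_per_s`, `amplitude`).
#' @param n_points,dwell_time Grid; defaults from the component attributes.
#' @return Complex vector of length `n_points`.
#' @export
hsvd_reconstruct <- function(components, n_points = attr(components, "n_points"),
                             dwell_time = attr(components, "dwell_time")) {
  t <- (seq_len(n_points) - 1) * dwell_time
  out <- complex(real = numeric(n_points), imaginary = numeric(n_points))
  for (i in seq_len(nrow(components))) {
    out <- out + components$amplitude[i] *
      exp((1i * 2 * pi * components$frequency_hz[i] - components$damping_per_s[i]) * t)
  }
  out
}

#' Default assignment windows around the nominal shifts
#'
#' @param resonances Target resonances.
#' @param half_width Window half-width, ppm (default 0.08).
#' @return Named list of ppm intervals.
#' @export
default_windows <- function(resonances = default_resonances(), half_width = 0.08) {
  lapply(resonances, function(r) r$chemical_shift + c(-1, 1) * half_width)
}

#' Assign HSVD components to target resonances
#'
#' Within each (disjoint) ppm window the single largest-magnitude component is
#' assigned to that resonance; every unassigned component is labeled baseline.
#' A window with no component marks that resonance missing (it is dropped from
#' downstream fitting rather than raising an error, mirroring failed peak fits
#' in low-SNR subjects).
#'
#' @param components `hsvd_components` from [hsvd_decompose()].
#' @param windows Named list of ppm intervals (default [default_windows()]).
#' @return List: `peaks` (named list of one-row component data frames, `NULL`
#'   where missing) and `baseline` (data frame of the remaining components).
#' @export
assign_components <- function(components, windows = default_windows()) {
  ppm <- attr(components, "reference_shift") +
    components$frequency_hz / attr(components, "transmitter_freq")
  for (i in seq_along(windows)) {
    for (j in seq_along(windows)) {
      if (i < j && min(windows[[i]][2], windows[[j]][2]) >
          max(windows[[i]][1], windows[[j]][1])) {
        stop("assignment windows overlap: ", names(windows)[i], " / ",
             names(windows)[j])
      }
    }
  }
  taken <- rep(FALSE, nrow(components))
  peaks <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    idx <- which(ppm >= w[1] & ppm <= w[2] & !taken)
    if (!length(idx)) return(NULL)
    best <- idx[which.max(Mod(components$amplitude[idx]))]
    taken[best] <<- TRUE
    components[best, , drop = FALSE]
  })
  names(peaks) <- names(windows)
  baseline <- components[!taken, , drop = FALSE]
  attr(baseline, "dwell_time") <- attr(components, "dwell_time")
  attr(baseline, "transmitter_freq") <- attr(components, "transmitter_freq")
  attr(baseline, "reference_shift") <- attr(components, "reference_shift")
  attr(baseline, "n_points") <- attr(components, "n_points")
  list(peaks = peaks, baseline = baseline)
}

#' Subtract the reconstructed baseline from a FID
#'
#' Time-domain subtraction of the summed baseline components; no other
#' baseline correction is applied.
#'
#' @param fid Single-channel [fid_series()].
#' @param baseline Baseline component set (from [assign_components()]).
#' @return [fid_series()] with the baseline removed.
#' @export
subtract_baseline <- function(fid, baseline) {
  stopifnot(inherits(fid, "fid_series"), n_channels(fid) == 1)
  if (!nrow(baseline)) return(fid)
  recon <- hsvd_reconstruct(baseline, n_points = n_points(fid),
                            dwell_time = fid$dwell_time)
  fid$samples[1, ] <- fid$samples[1, ] - recon
  fid
}

#' Fixed frequency/linewidth basis for complex regression
#'
#' Collects the components assigned to the target resonances into a basis
#' whose frequencies and dampings are frozen; only complex amplitudes remain
#' free when saturation-recovery scans are regressed onto it. Missing
#' resonances are recorded and skipped.
#'
#' @param assigned Result of [assign_components()].
#' @param include_baseline If `TRUE` (default), baseline components falling in
#'   `baseline_band` ride along as nuisance regressors (their amplitudes are
#'   refit per scan but not reported), absorbing the partially excited upfield
#'   complex, whose amplitude evolves with saturation. Unassigned components
#'   outside that band (mostly noise fragments) are excluded from the design
#'   so they cannot siphon signal from the target resonances.
#' @param baseline_band ppm interval of the upfield baseline complex.
#' @return Object of class `peak_basis`.
#' @export
peak_basis <- function(assigned, include_baseline = TRUE,
                       baseline_band = c(7.9, 8.85)) {
  present <- !vapply(assigned$peaks, is.null, logical(1))
  rows <- do.call(rbind, lapply(which(present), function(i) {
    data.frame(resonance = names(assigned$peaks)[i],
               frequency_hz = assigned$peaks[[i]]$frequency_hz,
               damping_per_s = assigned$peaks[[i]]$damping_per_s)
  }))
  nuisance <- data.frame(frequency_hz = numeric(0), damping_per_s = numeric(0))
  if (include_baseline && nrow(assigned$baseline)) {
    ppm <- attr(assigned$baseline, "reference_shift") +
      assigned$baseline$frequency_hz / attr(assigned$baseline, "transmitter_freq")
    keep <- ppm >= baseline_band[1] & ppm <= baseline_band[2]
    nuisance <- assigned$baseline[keep, c("frequency_hz", "damping_per_s"),
                                  drop = FALSE]
  }
  structure(list(components = rows,
                 missing = names(assigned$peaks)[!present],
                 nuisance = nuisance),
            class = "peak_basis")
}

#' @export
print.peak_basis <- function(x, ...) {
  cat(sprintf("<peak_basis> %d resonance component(s), %d nuisance; missing: %s\n",
              nrow(x$components), nrow(x$nuisance),
              if (length(x$missing)) paste(x$missing, collapse = ", ") else "none"))
  invisible(x)
}

basis_design <- function(basis, n, dwell) {
  comp <- rbind(basis$components[, c("frequency_hz", "damping_per_s")],
                basis$nuisance)
  t <- (seq_len(n) - 1) * dwell
  X <- vapply(seq_len(nrow(comp)), function(k) {
    exp((1i * 2 * pi * comp$frequency_hz[k] - comp$damping_per_s[k]) * t)
  }, complex(n))
  X
}

#' Complex linear regression of a scan onto the fixed basis
#'
#' Solves the time-domain least-squares problem with frequencies and dampings
#' frozen; only the complex amplitudes are free. The coefficient of
#' determination is reported over the fitted downfield band: fit and residual
#' are taken to the frequency domain (unitary transform) and compared on the
#' `band` interval where the basis lives, so R2 reflects how well the modeled
#' region is explained rather than being diluted by out-of-band noise.
#'
#' @param fid Single-channel [fid_series()] (processed like the scan the
#'   basis came from).
#' @param basis A [peak_basis()].
#' @param band ppm interval over which R2 is evaluated.
#' @return List: `amplitude` (named complex, one per resonance; doublet
#'   variants fitted with several components report the component sum),
#'   `r_squared`.
#' @export
regress_amplitudes <- function(fid, basis, band = c(7.9, 10.6)) {
  stopifnot(inherits(fid, "fid_series"), n_channels(fid) == 1,
            inherits(basis, "peak_basis"))
  if (!nrow(basis$components)) stop("empty basis: no resonance components")
  y <- fid$samples[1, ]
  n <- length(y)
  X <- basis_design(basis, n, fid$dwell_time)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) stop("rank-deficient basis")
  coefs <- qr.coef(qr(X), y)
  resid <- as.vector(y - X %*% coefs)
  f <- fft_freqs(n, fid$dwell_time)
  ppm <- hz_to_ppm(f, fid)
  in_band <- ppm >= band[1] & ppm <= band[2]
  yf <- stats::fft(y)[in_band] / sqrt(n)
  rf <- stats::fft(resid)[in_band] / sqrt(n)
  sst <- sum(Mod(yf - mean(yf))^2)
  r2 <- 1 - sum(Mod(rf)^2) / sst
  # coefficient standard errors (complex LS; collinearity with neighbouring
  # and baseline columns is captured by the Gram inverse)
  k <- ncol(X)
  sigma2 <- sum(Mod(resid)^2) / (2 * (n - k))
  gram_inv_diag <- Re(diag(solve(Conj(t(X)) %*% X)))
  se <- sqrt(2 * sigma2 * gram_inv_diag)
  labels <- basis$components$resonance
  amp <- vapply(unique(labels), function(r) {
    sum(coefs[seq_along(labels)][labels == r])
  }, complex(1))
  amp_se <- vapply(unique(labels), function(r) {
    sqrt(sum(se[seq_along(labels)][labels == r]^2))
  }, numeric(1))
  list(amplitude = amp, amplitude_se = amp_se, r_squared = r2)
}

#' Extract peak amplitude series from all saturation-recovery scans
#'
#' Regresses every scan onto the fixed basis and phases each resonance by its
#' equilibrium (no-saturation) amplitude, so the reported amplitude is the
#' real part along the equilibrium phase and the TS = 10 s point is positive
#' real. The equilibrium point is appended to both experiments.
#'
#' Peak-fit quality control: a resonance whose equilibrium amplitude falls
#' below `qc_min_snr` times its regression standard error is dropped from the
#' output (reported missing), mirroring the omission of poorly fitted peaks
#' in low-SNR subjects.
#'
#' @param scans List with `selective` and `broadband` (lists of processed
#'   single-channel [fid_series()] carrying `TS_ms`/`experiment` metadata)
#'   and `m0` (the processed no-saturation scan). An absent `m0` is an error.
#' @param basis A [peak_basis()].
#' @param ts_m0 Nominal TS assigned to the equilibrium scan, ms.
#' @param qc_min_snr Detection threshold for the equilibrium amplitude
#'   (amplitude over its standard error); 0 disables the QC.
#' @return Data frame of class `peak_amplitude_series`: `resonance`,
#'   `experiment`, `ts_ms`, `amplitude`, `r_squared`. Attribute
#'   `qc_dropped` lists resonances removed by quality control.
#' @export
extract_series <- function(scans, basis, ts_m0 = 10000, qc_min_snr = 5) {
  if (is.null(scans$m0)) stop("missing m0 (no-saturation) scan")
  m0_fit <- regress_amplitudes(scans$m0, basis)
  amp_snr <- Mod(m0_fit$amplitude) / m0_fit$amplitude_se
  dropped <- names(m0_fit$amplitude)[amp_snr < qc_min_snr]
  phase_ref <- m0_fit$amplitude / Mod(m0_fit$amplitude)
  phase_ref[Mod(m0_fit$amplitude) == 0] <- 1 + 0i
  score <- function(fit) Re(fit$amplitude * Conj(phase_ref))
  rows <- list()
  for (exp_name in c("selective", "broadband")) {
    for (scan in scans[[exp_name]]) {
      fit <- regress_amplitudes(scan, basis)
      rows[[length(rows) + 1]] <- data.frame(
        resonance = names(fit$amplitude), experiment = exp_name,
        ts_ms = scan$meta$TS_ms, amplitude = score(fit),
        r_squared = fit$r_squared, row.names = NULL
      )
    }
    rows[[length(rows) + 1]] <- data.frame(
      resonance = names(m0_fit$amplitude), experiment = exp_name,
      ts_ms = ts_m0, amplitude = score(m0_fit),
      r_squared = m0_fit$r_squared, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  out <- out[!(out$resonance %in% dropped), ]
  out <- out[order(out$resonance, out$experiment, out$ts_ms), ]
  rownames(out) <- NULL
  class(out) <- c("peak_amplitude_series", "data.frame")
  attr(out, "qc_dropped") <- dropped
  out
}

#' Pull one resonance/experiment series
#'
#' @param series Result of [extract_series()] (or the tidy amplitudes table).
#' @param resonance,experiment Selection.
#' @return Data frame with attributes `resonance` and `experiment`.
#' @export
amplitude_series <- function(series, resonance, experiment) {
  out <- series[series$resonance == resonance & series$experiment == experiment, ]
  rownames(out) <- NULL
  attr(out, "resonance") <- resonance
  attr(out, "experiment") <- experiment
  out
}
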