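#' Multi-channel FID container
#'
#' A free-induction decay: complex samples per receive channel, plus the
#' acquisition metadata needed to reconstruct a calibrated ppm axis. The
#' carrier (`reference_shift`) is the chemical shift at zero frequency offset;
#' frequencies are stored relative to it, with larger ppm (more downfield)
#' mapping to larger Hz.
#'
#' @param samples Complex matrix, channels x time (a vector is treated as one
#'   channel).
#' @param dwell_time Sampling interval, seconds.
#' @param transmitter_freq Transmitter frequency, MHz (ppm -> Hz scale).
#' @param reference_shift Carrier position, ppm.
#' @param meta Named list of scan metadata (`TS_ms`, `experiment`, `TR_ms`,
#'   `TE_ms`, `NEX`, ...).
#' @return Object of class `fid_series`.
#' @export
fid_series <- function(samples, dwell_time, transmitter_freq,
                       reference_shift = 9.7, meta = list()) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), dwell_time > 0, nrow(samples) >= 1,
            transmitter_freq > 0)
  storage.mode(samples) <- "complex"
  structure(list(
    samples = samples, dwell_time = dwell_time,
    transmitter_freq = transmitter_freq, reference_shift = reference_shift,
    meta = meta
  ), class = "fid_series")
}

#' @export
print.fid_series <- function(x, ...) {
  cat(sprintf("<fid_series> %d channel(s) x %d points, dwell %.3g s, %s MHz, carrier %.2f ppm\n",
              nrow(x$samples), ncol(x$samples), x$dwell_time,
              format(x$transmitter_freq), x$reference_shift))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

n_channels <- function(fid) nrow(fid$samples)
n_points <- function(fid) ncol(fid$samples)

# time axis in seconds, starting at t = 0
fid_time <- function(fid) (seq_len(n_points(fid)) - 1) * fid$dwell_time

# ppm -> frequency offset from carrier (Hz)
ppm_to_hz <- function(ppm, fid) (ppm - fid$reference_shift) * fid$transmitter_freq

# frequency offset (Hz) -> ppm
hz_to_ppm <- function(hz, fid) fid$reference_shift + hz / fid$transmitter_freq

#' Frequency-domain spectrum
#'
#' @param values Complex spectrum values, ordered to match `ppm_axis`.
#' @param ppm_axis Monotone decreasing ppm axis (display convention: downfield
#'   on the left).
#' @param provenance Character vector of processing steps applied.
#' @return Object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(values, ppm_axis, provenance = character()) {
  stopifnot(length(values) == length(ppm_axis), !is.unsorted(rev(ppm_axis)))
  structure(list(values = as.complex(values), ppm_axis = as.numeric(ppm_axis),
                 provenance = provenance),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.2f .. %.2f ppm\n",
              length(x$values), x$ppm_axis[1], x$ppm_axis[length(x$ppm_axis)]))
  invisible(x)
}

# Evaluate an expression with a temporarily-seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and stream index, staying < 2^31.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 9973 * as.numeric(index)) %% 2147483647
}
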