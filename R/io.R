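CONTAINER_SCHEMA <- "dfmx-spectra/1"

REQUIRED_SCAN_ATTRS <- c("dwell_time_s", "transmitter_freq_mhz",
                         "reference_shift_ppm", "experiment", "n_channels",
                         "n_points")

scan_key <- function(meta) {
  if (identical(meta$experiment, "selective") ||
      identical(meta$experiment, "broadband")) {
    sprintf("%s_TS%05d", meta$experiment, as.integer(meta$TS_ms))
  } else {
    meta$experiment
  }
}

num17 <- function(x) {
  # full-precision decimal encoding so doubles survive the JSON round trip
  if (is.null(x) || !is.finite(x)) "NA" else sprintf("%.17g", x)
}

write_scan <- function(fid, dir, key) {
  attrs <- list(
    schema = CONTAINER_SCHEMA,
    dwell_time_s = num17(fid$dwell_time),
    transmitter_freq_mhz = num17(fid$transmitter_freq),
    reference_shift_ppm = num17(fid$reference_shift),
    experiment = fid$meta$experiment,
    TS_ms = num17(fid$meta$TS_ms %||% NA_real_),
    TR_ms = num17(fid$meta$TR_ms %||% NA_real_),
    TE_ms = num17(fid$meta$TE_ms %||% NA_real_),
    NEX = num17(fid$meta$NEX %||% NA_real_),
    n_channels = n_channels(fid),
    n_points = n_points(fid)
  )
  jsonlite::write_json(attrs, file.path(dir, paste0(key, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  nc <- n_channels(fid)
  cols <- vector("list", 2 * nc)
  nms <- character(2 * nc)
  for (c in seq_len(nc)) {
    cols[[2 * c - 1]] <- sprintf("%.17g", Re(fid$samples[c, ]))
    cols[[2 * c]] <- sprintf("%.17g", Im(fid$samples[c, ]))
    nms[2 * c - 1] <- sprintf("ch%d_re", c)
    nms[2 * c] <- sprintf("ch%d_im", c)
  }
  df <- as.data.frame(cols, col.names = nms, check.names = FALSE)
  utils::write.csv(df, file.path(dir, paste0(key, ".csv")),
                   row.names = FALSE, quote = FALSE)
}

read_scan <- function(dir, key) {
  attrs <- jsonlite::read_json(file.path(dir, paste0(key, ".json")),
                               simplifyVector = TRUE)
  if (!identical(attrs$schema, CONTAINER_SCHEMA)) {
    stop("unknown container schema version: ", attrs$schema %||% "<absent>")
  }
  miss <- REQUIRED_SCAN_ATTRS[vapply(REQUIRED_SCAN_ATTRS,
                                     function(m) is.null(attrs[[m]]),
                                     logical(1))]
  if (length(miss)) stop("scan ", key, " is missing required attribute(s): ",
                         paste(miss, collapse = ", "))
  num <- function(nm) {
    v <- attrs[[nm]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  tab <- utils::read.csv(file.path(dir, paste0(key, ".csv")),
                         check.names = FALSE, colClasses = "numeric")
  nc <- attrs$n_channels
  np <- attrs$n_points
  if (nrow(tab) != np || ncol(tab) != 2 * nc) {
    stop("scan ", key, ": sample table does not match declared dimensions")
  }
  samples <- matrix(0i, nc, np)
  for (c in seq_len(nc)) {
    samples[c, ] <- complex(real = tab[[sprintf("ch%d_re", c)]],
                            imaginary = tab[[sprintf("ch%d_im", c)]])
  }
  fid_series(samples, num("dwell_time_s"), num("transmitter_freq_mhz"),
             num("reference_shift_ppm"),
             meta = list(TS_ms = num("TS_ms"),
                         experiment = attrs$experiment,
                         TR_ms = num("TR_ms"),
                         TE_ms = num("TE_ms"),
                         NEX = num("NEX")))
}

#' Write a cohort of spectra to the plain-directory container
#'
#' Hierarchical plain-text layout: a `manifest.json` with the schema version
#' and subject listing, and per subject one JSON attribute file plus one CSV
#' of complex samples (channels as re/im column pairs, `%.17g` so doubles
#' round-trip bit-exactly) per scan under `subjects/<id>/`.
#'
#' @param datasets Named list of subject datasets as produced by
#'   [generate_saturation_series()] (elements `selective`, `broadband`, `m0`,
#'   `water_ref`).
#' @param path Output directory (created; must not already contain a
#'   manifest).
#' @return `path`, invisibly.
#' @export
write_container <- function(datasets, path) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema = CONTAINER_SCHEMA, subjects = list())
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    sdir <- file.path(path, "subjects", id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    keys <- character(0)
    for (scan in c(ds$selective, ds$broadband, list(m0 = ds$m0),
                   list(water_ref = ds$water_ref))) {
      if (is.null(scan)) next
      key <- scan_key(scan$meta)
      write_scan(scan, sdir, key)
      keys <- c(keys, key)
    }
    manifest$subjects[[id]] <- keys
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort of spectra from the plain-directory container
#'
#' Lossless inverse of [write_container()]: samples and attributes round-trip
#' bit-exactly; subjects with missing scans are read with the missingness
#' intact. An unknown schema version or a scan missing a required attribute
#' is an explicit error.
#'
#' @param path Container directory.
#' @return Named list of subject datasets (`selective`, `broadband`, `m0`,
#'   `water_ref`).
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema, CONTAINER_SCHEMA)) {
    stop("unknown container schema version: ", manifest$schema %||% "<absent>")
  }
  datasets <- lapply(names(manifest$subjects), function(id) {
    sdir <- file.path(path, "subjects", id)
    keys <- manifest$subjects[[id]]
    scans <- lapply(keys, function(k) read_scan(sdir, k))
    names(scans) <- keys
    exps <- vapply(scans, function(s) s$meta$experiment, character(1))
    sel <- scans[exps == "selective"]
    bro <- scans[exps == "broadband"]
    ord <- function(l) l[order(vapply(l, function(s) s$meta$TS_ms, numeric(1)))]
    list(selective = ord(sel), broadband = ord(bro),
         m0 = if (any(exps == "m0")) scans[exps == "m0"][[1]] else NULL,
         water_ref = if (any(exps == "water_ref")) scans[exps == "water_ref"][[1]] else NULL)
  })
  names(datasets) <- names(manifest$subjects)
  datasets
}
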