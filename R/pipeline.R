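#' Process one subject's raw dataset into combined, apodized scans
#'
#' Channel frequency corrections and similarity-based rejection are estimated
#' once per subject on the no-saturation scan (the highest-SNR scan; channel
#' frequency offsets are a property of the session, not of one scan) and
#' applied to every scan, followed by matched-filter coil combination against
#' the water reference and exponential line broadening.
#'
#' @param dataset Subject dataset (`selective`, `broadband`, `m0`,
#'   `water_ref`).
#' @param lb Line broadening, Hz (default 5).
#' @param max_shift,similarity_min Channel alignment/rejection settings
#'   (see [align_and_reject_channels()]); alignment is skipped for
#'   single-channel data.
#' @return List with `selective`, `broadband`, `m0` (processed single-channel
#'   [fid_series()]), `rejected` (channel indices), `shifts_hz`.
#' @export
process_dataset <- function(dataset, lb = 5, max_shift = 20,
                            similarity_min = 0.7) {
  if (is.null(dataset$m0)) stop("dataset has no m0 (no-saturation) scan")
  if (is.null(dataset$water_ref)) stop("dataset has no water reference scan")
  multi <- n_channels(dataset$m0) > 1
  if (multi) {
    al <- align_and_reject_channels(dataset$m0, max_shift, similarity_min)
    shifts <- al$shifts_hz
    rejected <- al$rejected
  } else {
    shifts <- numeric(1)
    rejected <- integer(0)
  }
  water <- apply_channel_corrections(dataset$water_ref, shifts, rejected)
  one <- function(fid) {
    if (multi) fid <- apply_channel_corrections(fid, shifts, rejected)
    apodize(combine_channels(fid, water), lb = lb)
  }
  sel <- lapply(dataset$selective, one)
  bro <- lapply(dataset$broadband, one)
  list(selective = sel, broadband = bro, m0 = one(dataset$m0),
       rejected = rejected, shifts_hz = shifts)
}

#' Fit one subject end to end: HSVD, regression, Model 1 and Model 2
#'
#' Decomposes the no-saturation scan (HSVD, default 60 components), assigns
#' one component per target resonance, removes the baseline, regresses every
#' scan onto the fixed basis, fits the three-parameter recovery per
#' experiment, and fits the two-pool exchange model jointly to both
#' experiments with the Model 1 saturation efficiencies held fixed. Fit
#' failures degrade to `NA` rows, never errors.
#'
#' @param processed Output of [process_dataset()].
#' @param windows Assignment windows (default [default_windows()]).
#' @param n_components HSVD model order.
#' @param ts_m0 Nominal TS of the equilibrium scan, ms.
#' @param seed Seed for the Model 2 basin hopping.
#' @param n_hops Basin-hopping iterations.
#' @return List: `amplitudes` (tidy series), `model1`, `model2` (tidy data
#'   frames), `basis`.
#' @export
fit_subject <- function(processed, windows = default_windows(),
                        n_components = 60, ts_m0 = 10000, seed = 1L,
                        n_hops = 10) {
  comps <- hsvd_decompose(processed$m0, n_components = n_components)
  assigned <- assign_components(comps, windows)
  basis <- peak_basis(assigned)
  scans <- list(
    selective = processed$selective,
    broadband = processed$broadband,
    m0 = processed$m0
  )
  # the upfield baseline rides along as nuisance regressors with per-scan
  # amplitudes, so every scan (m0 included) is fit by one consistent design
  amps <- extract_series(scans, basis, ts_m0 = ts_m0)

  resonances <- unique(amps$resonance)
  m1_rows <- list(); m2_rows <- list()
  for (r in resonances) {
    f_sel <- fit_model1(amplitude_series(amps, r, "selective"), "selective")
    f_bro <- fit_model1(amplitude_series(amps, r, "broadband"), "broadband")
    for (f in list(f_sel, f_bro)) {
      m1_rows[[length(m1_rows) + 1]] <- data.frame(
        resonance = r, experiment = f$experiment,
        M0 = if (isTRUE(f$valid)) f$M0 else NA_real_,
        k = if (isTRUE(f$valid)) f$k else NA_real_,
        T1_ms = if (isTRUE(f$valid)) f$T1_ms else NA_real_,
        r_squared = if (isTRUE(f$valid)) f$r_squared else NA_real_
      )
    }
    ok1 <- isTRUE(f_sel$valid) && isTRUE(f_bro$valid) &&
      is.finite(f_sel$T1_ms) && is.finite(f_bro$T1_ms)
    f2 <- if (ok1) {
      tryCatch(
        fit_model2(amplitude_series(amps, r, "selective"),
                   amplitude_series(amps, r, "broadband"),
                   k_sel = f_sel$k, k_broad = f_bro$k,
                   seed = child_seed(seed, match(r, resonances)),
                   n_hops = n_hops),
        error = function(e) NULL
      )
    }
    good2 <- !is.null(f2) && isTRUE(f2$valid)
    m2_rows[[length(m2_rows) + 1]] <- data.frame(
      resonance = r,
      T1_A_ms = if (good2) f2$T1_A_ms else NA_real_,
      sigma_AB_hz = if (good2) f2$sigma_AB_hz else NA_real_,
      M0_A = if (good2) f2$M0_A else NA_real_,
      r_squared = if (good2) f2$r_squared else NA_real_
    )
  }
  list(amplitudes = amps, model1 = do.call(rbind, m1_rows),
       model2 = do.call(rbind, m2_rows), basis = basis)
}

#' Default pipeline configuration
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param lb Line broadening, Hz.
#' @param n_components HSVD model order.
#' @param n_hops Model 2 basin-hopping iterations.
#' @return Named list of settings.
#' @export
default_config <- function(n_subjects = 8, seed = 1L, lb = 5,
                           n_components = 60, n_hops = 10) {
  list(n_subjects = n_subjects, seed = seed, lb = lb,
       n_components = n_components, n_hops = n_hops,
       max_shift = 20, similarity_min = 0.7, window_half_width = 0.08,
       ts_m0 = 10000)
}

#' Run the full pipeline: simulate, process, fit, aggregate
#'
#' Executes simulate -> process -> fit-peaks -> fit-t1 -> fit-exchange ->
#' cohort for a synthetic cohort (or a cohort read from a container) and
#' writes tidy CSV result tables. Identical config and seed give identical
#' result tables. Per-subject failures at any fitting stage degrade to
#' missing values; a failing stage raises an error naming the stage.
#'
#' @param config Settings list (see [default_config()]); unset entries take
#'   their defaults.
#' @param out_dir Result directory (created).
#' @param container Optional path to an existing spectra container; if `NULL`,
#'   a cohort is simulated and written under `out_dir/spectra`.
#' @return Invisible list with the result tables (`amplitudes`, `model1`,
#'   `model2`, `summary`, `stats`) and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, container = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  run_id <- sprintf("dfmx-%s-seed%d",
                    format(Sys.time(), "%Y%m%d%H%M%S"), cfg$seed)
  logf("run_id=%s", run_id)
  logf("config=%s", jsonlite::toJSON(cfg, auto_unbox = TRUE))

  stage <- function(name, expr) {
    logf("stage=%s start", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  datasets <- if (is.null(container)) {
    stage("simulate", {
      cohort <- make_cohort(cfg$n_subjects, seed = cfg$seed)
      write_container(cohort$datasets, file.path(out_dir, "spectra"))
      utils::write.csv(cohort$truth_table, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      cohort$datasets
    })
  } else {
    stage("read", read_container(container))
  }

  windows <- default_windows(half_width = cfg$window_half_width)
  amp_rows <- list(); m1_rows <- list(); m2_rows <- list()
  for (id in names(datasets)) {
    res <- tryCatch({
      processed <- stage(paste0("process:", id),
                         process_dataset(datasets[[id]], lb = cfg$lb,
                                         max_shift = cfg$max_shift,
                                         similarity_min = cfg$similarity_min))
      fit_subject(processed, windows = windows,
                  n_components = cfg$n_components, ts_m0 = cfg$ts_m0,
                  seed = child_seed(cfg$seed, match(id, names(datasets))),
                  n_hops = cfg$n_hops)
    }, error = function(e) {
      logf("subject=%s failed: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    res$amplitudes$subject <- id
    res$model1$subject <- id
    res$model2$subject <- id
    amp_rows[[id]] <- res$amplitudes
    m1_rows[[id]] <- res$model1
    m2_rows[[id]] <- res$model2
  }
  if (!length(m1_rows)) stop("stage 'fit' failed: no subject could be fitted")
  amplitudes <- do.call(rbind, amp_rows)
  model1 <- do.call(rbind, m1_rows)
  model2 <- do.call(rbind, m2_rows)

  tab <- stage("cohort", cohort_table(model1, model2))
  summary_rows <- do.call(rbind, lapply(
    unique(tab$quantity), function(q) {
      do.call(rbind, lapply(unique(tab$resonance), function(r) {
        s <- aggregate_cohort(tab, q, r)
        data.frame(quantity = q, resonance = r, mean = s$mean, sd = s$sd,
                   n = s$n)
      }))
    }))

  stats_rows <- list()
  for (r in unique(tab$resonance)) {
    sel <- tab$value[tab$quantity == "T1_selective" & tab$resonance == r]
    bro <- tab$value[tab$quantity == "T1_broadband" & tab$resonance == r]
    tt <- tryCatch(paired_compare(sel, bro), error = function(e) NULL)
    if (!is.null(tt)) {
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        test = "t_sel_vs_broad", group = r, statistic = tt$statistic,
        p_value = tt$p_value)
    }
  }
  for (q in c("ratio", "T1_corrected", "sigma")) {
    sub <- tab[tab$quantity == q & !tab$missing, ]
    av <- tryCatch(anova_tukey(sub$value, sub$resonance),
                   error = function(e) NULL)
    if (is.null(av)) next
    stats_rows[[length(stats_rows) + 1]] <- data.frame(
      test = paste0("anova_", q), group = "omnibus",
      statistic = av$f_statistic, p_value = av$omnibus_p)
    stats_rows[[length(stats_rows) + 1]] <- data.frame(
      test = paste0("tukey_", q), group = av$pairwise$comparison,
      statistic = av$pairwise$diff, p_value = av$pairwise$p_adj)
  }
  stats <- do.call(rbind, stats_rows)

  wcsv <- function(x, name, units) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# units: ", units), con)
    utils::write.csv(x, con, row.names = FALSE)
    close(con)
  }
  wcsv(amplitudes, "amplitudes.csv",
       "ts_ms=ms amplitude=arb r_squared=dimensionless")
  wcsv(model1, "model1.csv", "T1_ms=ms k=dimensionless M0=arb")
  wcsv(model2, "model2.csv", "T1_A_ms=ms sigma_AB_hz=Hz M0_A=arb")
  wcsv(summary_rows, "summary.csv", "T1*=ms sigma=Hz ratio=dimensionless")
  wcsv(stats, "stats.csv", "p_value=dimensionless")
  logf("done")
  invisible(list(amplitudes = amplitudes, model1 = model1, model2 = model2,
                 summary = summary_rows, stats = stats, out_dir = out_dir))
}
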