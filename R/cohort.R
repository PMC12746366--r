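#' Reference cohort of in-vivo two-spin fits
#'
#' Per-subject exchange-corrected T1 and magnetization-exchange rates for
#' tryptophan and the three NAD+ resonances from the published 7 T human-brain
#' cohort (eight healthy volunteers); entries where peak fitting failed are
#' `NA`. Used to validate the cohort aggregation against the published
#' summary statistics and to center the synthetic-cohort sampler.
#'
#' @return Data frame: `subject`, `resonance`, `T1_corrected_ms`, `sigma_hz`.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "two_spin_reference_fits.csv", package = "dfmx")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a tidy cohort table from per-subject fits
#'
#' One row per subject x resonance x quantity, with explicit `NA` for missing
#' (never zero-filled). Quantities: `T1_selective`, `T1_broadband`, `ratio`
#' (broadband/selective apparent T1), `T1_corrected`, `sigma`.
#'
#' @param model1 Data frame with `subject`, `resonance`, `experiment`,
#'   `T1_ms` (apparent T1; `NA` where the fit failed).
#' @param model2 Data frame with `subject`, `resonance`, `T1_A_ms`,
#'   `sigma_AB_hz`.
#' @return Data frame of class `cohort_table`: `subject`, `resonance`,
#'   `quantity`, `value`, `missing`.
#' @export
cohort_table <- function(model1, model2) {
  sel <- model1[model1$experiment == "selective", c("subject", "resonance", "T1_ms")]
  bro <- model1[model1$experiment == "broadband", c("subject", "resonance", "T1_ms")]
  m <- merge(sel, bro, by = c("subject", "resonance"),
             suffixes = c("_sel", "_broad"), all = TRUE)
  m$ratio <- m$T1_ms_broad / m$T1_ms_sel
  rows <- rbind(
    data.frame(subject = m$subject, resonance = m$resonance,
               quantity = "T1_selective", value = m$T1_ms_sel),
    data.frame(subject = m$subject, resonance = m$resonance,
               quantity = "T1_broadband", value = m$T1_ms_broad),
    data.frame(subject = m$subject, resonance = m$resonance,
               quantity = "ratio", value = m$ratio),
    data.frame(subject = model2$subject, resonance = model2$resonance,
               quantity = "T1_corrected", value = model2$T1_A_ms),
    data.frame(subject = model2$subject, resonance = model2$resonance,
               quantity = "sigma", value = model2$sigma_AB_hz)
  )
  rows$missing <- !is.finite(rows$value)
  rows <- rows[order(rows$quantity, rows$resonance, rows$subject), ]
  rownames(rows) <- NULL
  class(rows) <- c("cohort_table", "data.frame")
  rows
}

#' Cohort summary: mean, sample SD, n over non-missing values
#'
#' Arithmetic mean and sample (n-1 denominator) standard deviation over the
#' non-missing entries of one quantity for one resonance; `n` counts the
#' values used. A single value yields an `NA` SD; all-missing yields an
#' all-`NA` summary.
#'
#' @param table A [cohort_table()] (or any data frame with `resonance`,
#'   `quantity`, `value`).
#' @param quantity,resonance Cell selectors.
#' @return List: `mean`, `sd`, `n`.
#' @export
aggregate_cohort <- function(table, quantity, resonance) {
  v <- table$value[table$quantity == quantity & table$resonance == resonance]
  v <- v[is.finite(v)]
  if (!length(v)) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Compare selective vs broadband apparent T1 (t-test)
#'
#' Two-sided t-test on per-subject apparent T1 under the two saturation
#' conditions. Paired by default (same subjects measured under both
#' conditions); pairs with any missing value are dropped. Identical samples
#' (zero variance of the differences) are reported as `t = 0`, `p = 1`.
#'
#' @param sel,broad Numeric vectors, paired by subject.
#' @param paired Paired test (default) or Welch two-sample.
#' @return List: `statistic`, `p_value`, `df`, `n`, `paired`.
#' @export
paired_compare <- function(sel, broad, paired = TRUE) {
  if (paired) {
    stopifnot(length(sel) == length(broad))
    ok <- is.finite(sel) & is.finite(broad)
    sel <- sel[ok]; broad <- broad[ok]
    if (length(sel) < 2) stop("fewer than 2 complete pairs")
    d <- sel - broad
    if (stats::sd(d) == 0) {
      # zero variance of the differences: t.test would error
      return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p_value = if (mean(d) == 0) 1 else 0,
                  df = length(d) - 1, n = length(d), paired = TRUE))
    }
    tt <- stats::t.test(sel, broad, paired = TRUE)
  } else {
    sel <- sel[is.finite(sel)]; broad <- broad[is.finite(broad)]
    if (length(sel) < 2 || length(broad) < 2) stop("fewer than 2 values per group")
    tt <- stats::t.test(sel, broad)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n = length(sel), paired = paired)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus one-way ANOVA across resonance groups followed by Tukey
#' honestly-significant-difference pairwise comparisons (multiplicity
#' adjusted). Degenerate input where every value is identical returns the
#' boundary `p = 1` for all tests.
#'
#' @param values Numeric vector (`NA` dropped).
#' @param groups Factor/character of group labels, same length.
#' @return List: `omnibus_p`, `f_statistic`, `pairwise` (data frame:
#'   `comparison`, `diff`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  ok <- is.finite(values)
  values <- values[ok]
  groups <- factor(as.character(groups)[ok])
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  if (stats::sd(values) == 0) {
    prs <- utils::combn(levels(groups), 2)
    return(list(omnibus_p = 1, f_statistic = 0,
                pairwise = data.frame(
                  comparison = paste(prs[2, ], prs[1, ], sep = "-"),
                  diff = 0, p_adj = 1)))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(omnibus_p = an[["Pr(>F)"]][1],
       f_statistic = an[["F value"]][1],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adj = tk[, "p adj"],
                             row.names = NULL))
}
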