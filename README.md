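# dfmx — magnetization exchange analysis for downfield ¹H MRS

Tryptophan (indole NH, 10.1 ppm) and NAD⁺ (nicotinamide H2/H6/H4 at 9.3,
9.1, 8.9 ppm) are detectable in the downfield ¹H spectrum of the human brain
at 7 T, but their protons exchange longitudinal magnetization with water —
chemical exchange for the labile tryptophan NH, dipole–dipole
cross-relaxation for the non-labile NAD⁺ protons. `dfmx` quantifies that
exchange from paired saturation-recovery experiments: one with *selective*
saturation of the metabolite band only, one with *broadband* saturation of
metabolites and water together.

Two models are fit to each resonance's amplitude-vs-delay series:

* **Model 1** — the three-parameter recovery
  `S(TS) = M0 (1 − k e^(−TS/T1))`, giving an *apparent* T₁ per experiment
  (exchange included implicitly) and the saturation efficiency `k`;
* **Model 2** — the two-pool Solomon system for metabolite (A) and water (B),

  ```
  dMz_A/dt = −(Mz_A − M0_A)/T1_A − σ_AB (Mz_A − M0_A) + σ_BA (Mz_B − M0_B)
  dMz_B/dt = −(Mz_B − M0_B)/T1_B − σ_BA (Mz_B − M0_B) + σ_AB (Mz_A − M0_A)
  ```

  with `σ_BA = σ_AB · M0_A/M0_B`, water T₁ fixed at 1800 ms and
  `M0_B/M0_A = (2·55 M)/(0.3 mM)`, fit jointly to both experiments by
  basin-hopping least squares. This yields the exchange-corrected `T1_A` and
  the magnetization-exchange rate `σ_AB` (Hz).

The package covers the whole chain: a ground-truth simulator of
multi-channel saturation-recovery FIDs (no in-vivo raw data are publicly
deposited), spectral processing (channel alignment/rejection, water-referenced
matched-filter coil combination, 5 Hz apodization), time-domain peak fitting
(Hankel SVD with 60 components, one component per resonance, baseline
removal, fixed-basis complex regression), both relaxation models, and
cohort-level statistics (mean ± SD tables, paired t-tests, ANOVA + Tukey
HSD). A plain-directory JSON+CSV container stores spectra losslessly.

## Worked example

Simulate one subject at the default study conditions (7 T acquisition
emulation, noise calibrated so the NAD⁺ H2 spectral SNR ≈ 27), process, and
fit both models:

```r
library(dfmx)
truth <- subject_truth()                      # ground truth at cohort means
ds    <- generate_saturation_series(truth, acquisition_protocol(), seed = 11)
proc  <- process_dataset(ds)                  # align, combine, apodize
measure_snr(to_spectrum(proc$m0))
#> [1] 23.0
fit <- fit_subject(proc, seed = 11)
fit$model1[, c("resonance", "experiment", "k", "T1_ms", "r_squared")]
#>   resonance experiment     k  T1_ms r_squared
#> 1    NAD_H2  selective 0.811  201.3     0.977
#> 2    NAD_H2  broadband 0.881 1887.2     0.954
#> 3    NAD_H6  selective 1.000  171.2     0.973
#> 4    NAD_H6  broadband 0.836 1985.2     0.958
#> 5       TRP  selective 1.000   58.4     0.995
#> 6       TRP  broadband 0.848 1204.0     0.955
fit$model2
#>   resonance T1_A_ms sigma_AB_hz M0_A r_squared
#> 1    NAD_H2    2028        4.44 2.02     0.968
#> 2    NAD_H6    2558        5.38 1.60     0.969
#> 3       TRP     314       13.85 1.87     0.973
```

Reading the output: under broadband saturation every apparent T₁ is an order
of magnitude longer than under selective saturation — recovering water feeds
the metabolite pool, so recovery is dragged toward the water T₁ — and the
fitted exchange rate of tryptophan (13.9 Hz here, truth 12.3) is roughly
twice the NAD⁺ rates, the signature of chemical exchange versus
cross-relaxation. NAD⁺ H4 is absent from this subject's tables: its
equilibrium amplitude failed the 5-standard-error detection check (it sits
on the excitation transition band on the shoulder of the upfield baseline
complex), the same failure mode that removes H4 subjects from the in-vivo
cohort. `run_pipeline(default_config(n_subjects = 8), "out/")` runs the
whole chain for a cohort and writes tidy CSV tables plus Table-1-style
summaries and group statistics.

The per-subject two-spin fits published for the eight-volunteer 7 T cohort
ship with the package (`reference_cohort()`); `aggregate_cohort()` reproduces
their summary row, e.g. corrected T₁ of tryptophan 622.3 ± 405.5 ms (n = 7)
and σ_TRP 12.3 ± 3.1 Hz.

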