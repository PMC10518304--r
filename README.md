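# oddballp300

Clinical ERP groups routinely compare the P300 — the positive
event-related-potential deflection elicited 300–600 ms after a
task-relevant stimulus — between patients with mild cognitive impairment
(MCI) and matched healthy controls (HC), because prolonged P300 latency
during target detection is a candidate marker of slowed high-order
processing. `oddballp300` packages that entire analysis as reusable,
tested R code, together with a synthetic-data generator, so the
MCI-vs-control latency analysis can be exercised end to end when the
original recordings are unavailable.

The package covers:

* **Synthesis** — visual oddball sessions (120 stimuli, target probability
  0.33, inter-stimulus intervals uniform on 3–7 s, 500 Hz, midline
  Fz/Cz/Pz plus EOG) with per-subject ground-truth P300 latency/amplitude,
  1/f background noise, 10 Hz alpha, Poisson blink artifacts, and cohort
  tables whose neuropsychological scores follow configurable group
  marginals with Gaussian-copula coupling to the latent P300 factors.
* **I/O** — BrainVision (`.vhdr`/`.vmrk`/`.eeg`) reader and writer
  (IEEE float32 multiplexed; INT_16-with-resolution also read), and TSV
  cohort tables.
* **Preprocessing** — zero-phase Butterworth filtering (0.1 Hz high-pass,
  0.5–30 Hz band), 50 Hz IIR notch, extended-Infomax ICA with
  EOG-correlation component removal, 1000 ms epochs with 200 ms
  pre-stimulus baseline, the four-criterion automatic artifact rejection
  (±70 µV amplitude, 50 µV/ms step, 50 µV range in 200 ms,
  0.5 µV minimum activity in 100 ms), random epoch-count equalization,
  and the minimum-20-epochs check.
* **Measurement** — subject and grand-average ERPs; maximum peak amplitude
  and latency in the closed 300–600 ms window at Fz, Cz, Pz.
* **Statistics** — pooled two-sample t-tests (from raw samples or printed
  summaries: `t = (m_1-m_2)/\sqrt{s_p^2(1/n_1+1/n_2)}`, df `n_1+n_2-2`),
  Pearson chi-square on 2×2 tables, the 2 (group) × 2 (condition) ×
  3 (anterior–posterior electrode) mixed-design repeated-measures ANOVA
  with Greenhouse–Geisser epsilon and partial eta squared, the four
  Bonferroni-corrected simple-effect post-hocs, and Benjamini–Hochberg
  FDR-corrected brain–behavior correlation matrices per
  population × condition family.

## Worked example

```r
library(oddballp300)

cfg <- run_config(seed = 42, model = group_model(n_subjects = c(HC = 6, MCI = 6)))
res <- run_pipeline(cfg)

head(res$peaks, 4)
#>   subject_id condition channel amplitude latency
#> 1       hc01 nontarget      Fz  3.193002     420
#> 2       hc01 nontarget      Cz  5.449466     350
#> 3       hc01 nontarget      Pz  3.586529     392
#> 4       hc01    target      Fz  4.078798     438

res$anova_latency[, c("effect", "df", "df_error", "F", "p")]
#>                    effect df df_error      F      p
#> 1                   group  1       10 2.5928 0.1384
#> 2               condition  1       10 0.0928 0.7669
#> 3         group:condition  1       10 5.3022 0.0441
#> 4                 channel  2       20 0.4350 0.6533
#> 5           group:channel  2       20 1.8908 0.1770
#> 6       condition:channel  2       20 1.9894 0.1629
#> 7 group:condition:channel  2       20 4.4347 0.0255

res$posthoc_latency
#>                     contrast     t df      p p_bonferroni
#> 1  target_vs_nontarget_in_HC -1.10  5 0.3222        1.000
#> 2 target_vs_nontarget_in_MCI  3.14  5 0.0256        0.103
#> 3        HC_vs_MCI_in_target  1.05 10 0.3203        1.000
#> 4     HC_vs_MCI_in_nontarget  1.94 10 0.0811        0.325
```

Even at this toy size (6 subjects per group) the condition-by-group
latency interaction — the generator injects a ~30 ms prolongation of
target-processing latency in the MCI group, while controls trend the
opposite way — reaches `p = 0.044`; the post-hoc target-vs-non-target
contrast within MCI is the strongest simple effect, as expected from the
injected structure. `res$correlations` holds the 360-row FDR-corrected
correlation battery (here, with the default uncoupled cohort, no row is
flagged), and `res$grand_averages` the per-group grand-average waveforms.
Peak measures are in µV and ms. At the study's full size
(`group_model()` defaults: 20 + 20 subjects calibrated to the published
group means) the interaction is detected in essentially every seeded
cohort.

A thin command-line wrapper is installed as `exec/oddball-p300`
(`oddball-p300 run --seed 7 --out out/`), and `read_run_config()` accepts
a YAML config that overrides any default.

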