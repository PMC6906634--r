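# purkinje

Simulation and statistical analysis of in vivo cerebellar spike trains:
Purkinje cells (simple + complex spikes) and cerebellar nuclear neurons, in
the setting of the mdx (dystrophin-null) mouse model of Duchenne muscular
dystrophy, where simple-spike rates drop (~19% awake, ~13% anesthetized),
complex-spike variability drops (CV ~17%) and nuclear local irregularity
rises (CV2 ~19%).

The package provides, as testable replacements for a manual recording /
Spike2-sorting / spreadsheet workflow:

* **Simulators** — gamma-renewal spike trains with specified rate and ISI CV;
  a two-state Markov-modulated gamma process whose CV2 is calibrated
  independently of rate and CV; the ~20 ms post-complex-spike pause; whole
  genotype-structured cohorts with deterministic per-cell seeds; and
  band-passed (0.3–13 kHz, zero-phase Butterworth) extracellular voltage
  traces built from spike templates with ground truth attached.
* **Spike detection and sorting** — robust (MAD-scaled) threshold detection,
  trough alignment, refractory merging, spikelet absorption, and an
  unsupervised two-stage simple/complex classifier (post-trough energy
  outliers verified by spikelet-depth minima), with the pause-verification
  statistic as a sorting sanity check.
* **ISI statistics** — rate (spikes/s over the analysed window),
  CV = sd(ISI)/mean(ISI), CV2 = mean of 2|ISI(n+1)−ISI(n)|/(ISI(n+1)+ISI(n)),
  per-cell and per-group summaries (mean ± SEM).
* **Hierarchical inference** — per predictor (genotype; median-split
  covariates): a two-group Wilks' lambda MANOVA on (rate, CV, CV2) with the
  exact F conversion F = ((1−λ)/λ)((N−p−1)/p); if the omnibus p < 0.05,
  per-response Wilcoxon rank-sum tests (midranks, tie-corrected variance, no
  continuity correction) gated through Benjamini–Hochberg at FDR 0.2; plus
  two-sample t tests computed directly from printed mean/SEM/n.
* **Anatomy arithmetic** — 8-connected particle counting on binary masks,
  region areas, and counts per 50 µm unit.

## Worked example

Simulate the awake Purkinje cohort (24 cells per genotype, 71 s per cell,
control simple spikes 85.3 Hz, mdx rate ×0.81), compute per-cell metrics and
run the gated analysis:

```r
library(purkinje)
co      <- gen_cohort(study_cohort_spec("awake_purkinje", master_seed = 1))
metrics <- cohort_metrics(co)
cohort_summary(metrics)[, c("genotype", "unit_type", "rate_hz_mean",
                            "rate_hz_sem", "cv_mean", "cv2_mean")]
#>   genotype unit_type rate_hz_mean rate_hz_sem cv_mean cv2_mean
#> 1  control        cs         1.24      0.0177   0.915    0.952
#> 2      mdx        cs         1.18      0.0207   0.749    0.794
#> 3  control        ss        85.08      0.1013   0.543    0.562
#> 4      mdx        ss        69.09      0.0882   0.533    0.560

analysis_workflow(metrics, unit_type = "ss", predictors = "genotype")
#> Hierarchical analysis (ss): 48 cells (0 dropped), gate alpha = 0.05, BH FDR = 0.20
#>   genotype: Wilks' lambda(1,46) = 0.0032, P = 8.006e-55 -> pairwise tests
#>     rate_hz  |z| = 5.94, P = 2.849e-09, BH crit 0.067: rejected (significant)
#>     cv       |z| = 5.22, P = 1.821e-07, BH crit 0.133: rejected (significant)
#>     cv2      |z| = 1.22, P = 0.2238, BH crit 0.200: not rejected
```

The recovered group rates (85.08 vs 69.09 Hz) match the specification
(85.3 vs 69.1) to within the cohort SEM, and the genotype gate passes with
the simple-spike rate comparison rejected under BH. Note the omnibus p is
astronomically small because default cohorts are homogeneous within group —
cell-to-cell spread is pure sampling noise, so even a 0.01 difference in CV
(a side effect of the pause at different rates) is detectable; real cohorts
have ~40-fold larger biological spread (see the vignette's discussion of the
`dispersion` argument).

Statistics reproduced from printed summary inputs:

```r
percent_difference(85.3, 69.1, digits = 0)   # awake SS rate drop
#> [1] 19
t_from_summary(152.3, 3.7, 3, 155.7, 4.0, 3) # molecular layer thickness
#> t(4) = -0.624, P = 0.566
manova_p_from_lambda(0.9028, 94, 3)$p        # anesthetized SS omnibus
#> [1] 0.02610553
```

A command-line driver over the same functions is installed at
`inst/scripts/pipeline.R` (subcommands `simulate`, `detect`, `metrics`,
`stats`, `anatomy`, `run`), configured by YAML (`read_pipeline_config`).

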