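# megfocus

Interictal MEG metrics for epileptogenic-zone localization: a tested R
implementation of a source-space analysis pipeline for epilepsy-surgery
cohorts.

## The problem

After resective epilepsy surgery, roughly one third of patients keep
having seizures — the resected tissue did not (fully) contain the
*epileptogenic zone* (EZ). A long-standing question is whether simple
quantitative markers computed from routine *interictal* (between-seizure)
MEG recordings point at the tissue that was eventually resected, and
whether they can go further and predict who becomes seizure free.
`megfocus` implements that analysis for source-space recordings on the
90-region AAL atlas, for methodologists and clinical researchers who want
a reproducible, fully tested reference pipeline plus a synthetic cohort
generator to validate it against known ground truth.

## What it computes

Per patient, from an ROI × samples matrix cut into epochs (reference
geometry: 174 epochs × 4096 samples at 1250 Hz):

1. **Relative delta power** — DFT band power in delta (0.5–4 Hz) as a
   share of total 0.5–48 Hz power, averaged over epochs;
2. **Low-to-high frequency power ratio** — (delta + theta) / lower alpha;
3. **Mean phase lag index** — PLI(a, b) = |⟨sign sin(φₐ − φᵦ)⟩| over
   broadband instantaneous phases, averaged over all partner ROIs;
   insensitive to the zero-lag coupling produced by field spread;
4. **MST betweenness centrality** — hub score on the minimum spanning
   tree of the 1/PLI-weighted network: the fraction of the
   (N−1)(N−2)/2 node pairs whose unique tree path crosses the node.

Group level: does one of each patient's k highest-valued ROIs (k = 1…5)
fall inside the resection mask more often than the hypergeometric chance
level P(≥1 hit) = 1 − C(N−m, k)/C(N, k) (exact binomial test)? Does the
overlap differ between outcome groups (Pearson χ², no continuity
correction)? Do six resection-referenced metric averages differ between
groups (pooled-variance t-tests)? All families are Benjamini–Hochberg
FDR-adjusted.

Individual level: linear SVM (cost 1) and random forest (500 trees,
√p features per split) classify resection vs non-resection ROIs
(4 features) and seizure-free vs not (384 features), with 100× balanced
majority-class subsampling and leave-one-out cross-validation.

Because the underlying clinical recordings are not publicly available,
the package ships a seeded synthetic cohort generator that reproduces the
cohort's structure — 1/f background with an alpha bump, a focal set of
ROIs with elevated delta power and lagged phase coupling, resection masks
of 1–12 ROIs (median 7) that cover the focus preferentially in
seizure-free patients — so every stage is testable end to end. See the
methods vignette (`vignettes/megfocus-methods.Rmd`) for the model,
conventions, calibration results and known limitations.

## Worked example

```r
library(megfocus)

spec <- cohort_spec(n_patients = 12, n_seizure_free = 8,
                    n_epochs = 8, epoch_samples = 1024,
                    delta_gain = 3, coupling_strength = 0.6,
                    resection_focus_overlap_sf = 1,
                    resection_focus_overlap_nsf = 0.2, seed = 7)
mt <- simulate_metric_cohort(spec)     # 12 patients x 90 ROIs x 4 metrics

ov <- overlap_table(mt)                # top-k overlap vs chance
head(subset(ov, metric == "delta_power"), 5)
#>        metric k n_overlap n_patients chance_p0 binomial_p    fdr_p
#> 1 delta_power 1         8         12    0.0889   1.39e-06 3.97e-06
#> 2 delta_power 2         9         12    0.1708   1.65e-05 3.00e-05
#> 3 delta_power 3        10         12    0.2462   3.25e-05 4.34e-05
#> 4 delta_power 4        11         12    0.3155   2.63e-05 4.34e-05
#> 5 delta_power 5        11         12    0.3792   1.82e-04 2.19e-04

am <- averaged_measures_table(mt)      # six averages, outcome contrast
subset(am, metric == "betweenness" & measure == "resection_lobe")
#>         metric        measure mean_sf  sd_sf mean_nsf sd_nsf     t df     p fdr_p
#> 20 betweenness resection_lobe  0.0749 0.0114   0.0693 0.0105 0.824 10 0.429 0.498

fm <- zscore_features(build_roi_features(mt))
rounds <- subsample_balanced(fm, n_rounds = 3, seed = 7)
loocv_evaluate(fm, rounds, classifier = "svm", seed = 7)
#> svm (full LOOCV, 3 rounds): accuracy 81.60% (95% CI 81.26-81.94%),
#>   sensitivity 65.97%, specificity 97.22%
```

Reading the output: with a strong injected focus effect, the ROI with the
single highest delta power already lands in the resection in 8 of 12
patients against a chance level of 0.089 (binomial p ≈ 1.4e-6), and the
ROI-level classifier separates resected from spared regions at ~82%
accuracy. The outcome contrast of the betweenness resection-lobe average
is not significant in this tiny cohort (p = 0.43), as expected at n = 12.

`run_pipeline(config, out_dir)` orchestrates the same steps from a config
list or JSON file and writes `metrics.csv`, `overlap.csv`,
`group_overlap.csv`, `averaged_measures.csv`, `classification.json` and a
`provenance.json` (config hash, seed, versions); re-running a config
reproduces byte-identical outputs. A thin CLI over the same functions is
in `inst/cli/megfocus.R`.

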