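---
title: "Methods: interictal MEG metrics and resection-overlap statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interictal MEG metrics and resection-overlap statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megfocus)
```

## The analysis problem

In presurgical evaluation of drug-resistant focal epilepsy, the
*epileptogenic zone* (EZ) is the cortical territory whose removal is
necessary and sufficient for seizure freedom; it can only be verified
after surgery, by whether the patient became seizure free. `megfocus`
implements an interictal (between-seizure) analysis of source-space MEG:
each patient contributes a matrix of *virtual electrode* time series, one
per region of the 90-region AAL atlas (78 cortical + 12 subcortical), a
*resection mask* (the atlas regions overlapping the surgical cavity on
post-operative MRI) and a binary surgery outcome. The package asks, at the
group level, whether regions with extreme metric values coincide with the
resection more often than chance, and whether that coincidence
discriminates surgery outcomes; at the individual level, whether
classifiers trained on the metrics can recover the resection or the
outcome.

The pipeline deliberately starts at ROI time series: sensor-level
artifact suppression, beamformer source reconstruction and resection-mask
delineation are upstream of this package and are treated as given inputs.

## The four metrics

Recordings are cut into contiguous, non-overlapping epochs taken from the
start of the recording, with no artifact rejection (epoch selection must
not be able to bias the metrics). The reference geometry is 174 epochs of
4096 samples at 1250 Hz (3.28 s per epoch).

**Relative delta power.** Per epoch and ROI, the discrete Fourier
periodogram (no taper, no detrending) is summed over bins in each of six
bands -- delta (0.5--4 Hz), theta (4--8), lower alpha (8--10), upper alpha
(10--13), beta (13--30), gamma (30--48) -- and divided by the total over
the union (0.5--48 Hz). Band membership uses half-open intervals
`[f_low, f_high)`, so contiguous bands never double-count an edge bin.
With this denominator the six relative powers sum to one per ROI. The
per-epoch shares are averaged over epochs (the epoch is the unit of
analysis; the average of per-epoch ratios is not the ratio of averaged
powers, and we use the former consistently). Focal slow-wave activity is
a classical marker of epileptogenic tissue, which motivates relative
delta power as the first metric.

**Low-to-high frequency power ratio.** `(delta + theta) / lower alpha`
per ROI, a spectral-slowing index. It is undefined when lower-alpha power
is exactly zero; the package raises an error in that degenerate case
rather than returning infinities.

**Mean phase lag index (PLI).** For two phase series, PLI is
`|mean(sign(sin(phi_a - phi_b)))|`: the asymmetry of the phase-difference
distribution around zero. Phase differences of exactly 0 or pi contribute
nothing, which makes the PLI blind to the zero-lag synchronization
produced by volume conduction and beamformer field spread -- the reason it
is the connectivity measure of choice in source-space MEG. Per epoch,
each ROI series is restricted to the broadband range (0.5--48 Hz) and its
instantaneous phase extracted from the analytic signal; PLI is computed
for all ROI pairs and averaged across epochs. The per-ROI metric is the
row mean of the PLI matrix excluding the diagonal.

**MST betweenness centrality.** The ROIs form a complete graph weighted
by inverted PLI (1/PLI); its minimum spanning tree is the
highest-connectivity backbone of the network, insensitive to any
monotone rescaling of the PLI values (a property the test suite checks
explicitly). On the tree, the betweenness centrality of a node is the
fraction of the `(N-1)(N-2)/2` unordered pairs of other nodes whose
unique path crosses it -- 1 for a star centre, 0 for every leaf. Hubs of
the interictal network have repeatedly been associated with the EZ,
motivating this as the fourth metric.

### Numerical choices

* **Band-limiting and phase extraction** are done by frequency-domain
  selection: in-band positive-frequency bins are doubled, all others
  zeroed, and the inverse transform yields the analytic signal directly.
  This is exactly zero-phase by construction. A linear-phase FIR filter
  reaching down to 0.5 Hz at 1250 Hz sampling would need a filter longer
  than the 4096-sample epoch itself, so a time-domain design is not an
  option at this epoch length.
* **MST determinism.** Edges enter the graph in lexicographic (i, j)
  order and the tree is computed on those weights, so results are
  reproducible across runs and platforms, including under ties (ties
  have measure zero for continuous PLI values but occur in tests).
  Pairs with PLI exactly 0 receive a surrogate weight far above every
  real weight so they are used only if nothing else connects the graph;
  an all-zero matrix is rejected as degenerate.
* **Top-k ties** are broken toward the lower ROI index after sorting by
  value, for the same reproducibility reason.
* **Betweenness normalization** uses `(N-1)(N-2)/2`, which makes a star
  centre score exactly 1.

## Group-level statistics

For each metric and each `k` in 1..5, a patient counts as *overlapping*
when at least one of the `k` highest-valued ROIs lies in the resection
mask. The chance probability of that event under uniform drawing without
replacement is hypergeometric: `1 - C(N-m, n)/C(N, n)` with `N = 90`
ROIs, `m` resection ROIs and `n = k` draws. Because mask size varies
across patients (1--12, median 7), the default chance level uses the
cohort-median `m` (the per-patient average is available as an option).
The observed count of overlapping patients is tested against that chance
level with an exact binomial test. The package default is the two-sided
exact test: on the reference cohort counts (46 of 94 at the top-5 chance
level 0.3394) the two-sided test reproduces the published value 0.003,
while the one-sided upper tail gives 0.002; both sidedness options are
exposed.

Outcome-group contrasts use the Pearson chi-square test of independence
on the 2x2 overlap-by-outcome table *without* continuity correction --
the uncorrected statistic reproduces the published chi-square of 3.97 on
the reconstructed PLI top-1 table, whereas the Yates-corrected one would
give about 3.04. Group comparisons of the six resection-referenced
averages (resection mean; resection-lobe mean; contralateral-homolog
mean; non-resection mean; and the two differences) use Student's
unpaired t-test with pooled variance: the published degrees of freedom
(92 = 64 + 30 - 2) identify the pooled rather than the Welch form. When
a resection touches several lobes, the lobe average is taken over the
union of touched lobes. Each statistical family (20 overlap tests, 20
chi-square tests, 24 t-tests) is adjusted with Benjamini-Hochberg FDR
within the family.

The lobe assignment and left/right homolog pairing for the AAL-90 atlas
ship as an editable CSV (`inst/extdata/aal90_atlas.csv`) with lobes
frontal, central, parietal, occipital, temporal, limbic and
insula+subcortical, and homologs paired by the standard odd/even AAL
ordering. This grouping is a convention of this package, not a published
table; analyses that depend on lobe boundaries should treat it as a
configurable input. ROI indices are 1-based throughout, matching R's
indexing; user-facing tables carry AAL names alongside indices so no
off-by-one ambiguity against 1-based atlas conventions can arise.

## Individual-level classification

Two tasks are supported. *Task 1* (resection vs non-resection): one
instance per (patient, ROI) with the four metrics as features. *Task 2*
(surgery outcome): one instance per patient with all 4 x 90 ROI metrics
plus the 24 averaged measures, 384 features. Features are z-scored using
mean and SD over all instances; note this lets test-set statistics
influence the scaling. It is nevertheless the order used by several
published pipelines and is the default here; a leakage-free per-fold
variant (`rescale_per_fold = TRUE`) is provided. Class imbalance is
handled by repeatedly subsampling the majority class to the minority
size (100 rounds by default, all from one seeded stream). Classifiers
are a linear SVM (cost fixed at 1; no tuning is performed anywhere) and
a random forest (500 trees, sqrt(p) candidate features per split, no
depth limit).

Evaluation is leave-one-out cross-validation. Two modes are implemented
because the one-test-instance-per-round protocol described in some
flowcharts is ambiguous: the default (`mode = "full"`) holds out every
instance of every balanced round once, aggregates confusion counts per
round, and averages accuracy/sensitivity/specificity across rounds with
a normal-approximation 95% CI (`mean +/- 1.96 SD/sqrt(rounds)`); the
literal alternative (`mode = "single"`) holds out one randomly chosen
instance per round. Neither is asserted to be the historical protocol;
the full mode uses the data far more efficiently. Sensitivity treats the
resection class (task 1) and the seizure-free class (task 2) as
positive.

## The synthetic cohort generator

No patient-level MEG data of this kind are publicly available, so the
package ships a generator that emulates the *structure* the analysis
assumes, with the reference cohort geometry as defaults: 90 ROIs,
174 epochs x 4096 samples at 1250 Hz, 64 of 94 patients seizure-free,
resection masks of 1--12 ROIs with median 7 (sizes drawn as
`1 + Binomial(11, 0.55)`, which has exactly that support and median).

Each ROI's background is Gaussian noise shaped to a 1/f-like amplitude
decay (flattened below 0.5 Hz) plus an alpha bump at 10 Hz, giving
realistic nonzero power in all six bands. A designated focus of
`focus_size` ROIs (default 7, matching the median resection extent)
carries two injectable effects:

* a **delta amplitude gain** (`delta_gain`, default 2) applied in the
  frequency domain to the 0.5--4 Hz bins of the focus signals; and
* **lagged phase coupling** (`coupling_strength` c, default 0.3): a
  common broadband signal with the same spectrum as the background is
  mixed into each focus ROI as `sqrt(1-c^2) * background + c * shared`,
  with a distinct constant phase rotation per focus ROI in multiples of
  one ninth of a cycle. Odd-denominator spacing guarantees every
  pairwise lag is strictly between 0 and pi -- PLI is blind at exactly 0
  and pi -- and spectrum matching guarantees the injection does not
  distort relative band powers, so the two effects can be dialled
  independently.

The resection mask includes each focus ROI with probability
`resection_focus_overlap_sf` (default 0.9) for seizure-free patients and
`resection_focus_overlap_nsf` (default 0.25) otherwise, topped up with
random non-focus ROIs to the drawn size: not-seizure-free patients have
resections displaced off the focus, encoding the premise that persistent
seizures mean the EZ was not (fully) removed. The effect sizes are free
parameters of the simulation, chosen once to give clearly detectable but
not trivial effects at desk scale; they are not estimates of any real
cohort's effect sizes, which the source publications do not provide.
Determinism is strict: per-patient RNG streams are derived by hashing
the cohort seed with the patient index, so any patient can be
regenerated independently and identical specs yield bit-identical
cohorts.

What the generator does *not* emulate: sensor-space MEG, field spread
(beyond what PLI's zero-lag blindness makes irrelevant), epileptiform
discharge morphology, spatially smooth inter-ROI correlation outside the
focus, and non-stationarity across epochs. Passing tests on synthetic
cohorts therefore demonstrate correctness and calibration of the
*pipeline*, not clinical performance on real recordings.

## Problem sizes for reproducible runs

The shipped tests and the acceptance script exercise the pipeline at a
desk scale chosen to keep a full run in minutes on one CPU: recovery
cohorts of 50 patients x 30 epochs x 1024 samples (effect cohort:
`delta_gain = 3`, `coupling_strength = 0.6`, focus fully covered by the
resection in the seizure-free arm), a 200-patient spectral-only null
cohort for overlap calibration, and 3 balanced subsampling rounds with
full LOOCV for the ROI classifier. At 1024 samples per epoch the
spectral resolution is 1.22 Hz, still finer than the narrowest analysis
band. The full-size geometry (174 x 4096) is the default of
`cohort_spec()` and runs the same code paths, only longer;
`simulate_metric_cohort()` streams patients so memory does not grow with
cohort size.

## Calibration results and a known limitation

On null cohorts (no injected effects) the top-1 overlap frequency is
consistent with the hypergeometric chance level (within sampling error
over 200 patients), and with injected effects the overlap test and the
ROI classifier both detect the focus easily -- these are exercised by the
test suite and recomputed by `scripts/acceptance.R`.

One calibration property does **not** hold and users should know about
it: the ROI-task classifier evaluated by LOOCV on a *null* cohort is not
centred on 50% accuracy. It is systematically biased below chance, by an
amount that varies between cohort realizations and can exceed a naive
3-SE band by several points. Two mechanisms combine. First, LOOCV on
exactly balanced data is mildly pessimistic, because removing the
held-out instance leaves its own class in the training minority. Second,
and dominant, metric instances are correlated *within* a patient: all
mean-PLI and betweenness values of one patient derive from the same
connectivity matrix. A classifier can partially encode patient identity
from the features, and the held-out instance's class is underrepresented
among its own patient's training instances, producing systematic
misclassification ("anti-learning"). The test suite demonstrates the
mechanism directly: on a null cohort, independently permuting each
feature column -- which destroys the within-patient correlation while
keeping marginals and labels -- raises the LOOCV accuracy back to the
mildly-pessimistic iid level. This is a property of running non-patient-stratified
LOOCV on clustered instances, i.e. of the evaluated protocol itself; it
is consistent with published below-chance SVM accuracies on the
analogous outcome task, and it is one more reason to interpret absolute
accuracies from such protocols with care. A leave-one-*patient*-out
scheme would remove it but would be a different protocol from the one
this package sets out to evaluate.

## Limitations

* EDF input is not supported; time series are exchanged as plain TSV
  matrices (ROIs x rows) plus a JSON manifest. The TSV writer emits
  `%.17g`, so round-trips are bit exact.
* The pipeline neither performs nor emulates source reconstruction;
  everything upstream of ROI time series is out of scope.
* The lobe table and homolog pairing are package conventions; swap in
  your own atlas CSV if your parcellation or grouping differs.
* Chance levels assume the resection mask is a uniformly random ROI set,
  which ignores spatial contiguity of real resections; this is the
  standard simplification for this family of overlap tests.
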