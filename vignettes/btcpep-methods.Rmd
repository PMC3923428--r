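---
title: "Serum peptidome biomarker discovery for biliary tract cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome biomarker discovery for biliary tract cancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btcpep)
```

## The problem

Biliary tract cancer (BTC) lacks an accurate circulating biomarker: CA19-9
is confounded by benign biliary obstruction and undetectable in
Lewis-negative patients. One discovery strategy profiles the serum
*peptidome* — low-molecular-weight fragments of abundant clotting proteins
(chiefly fibrinogen alpha), hypothesised to be trimmed by tumour-associated
exopeptidases during ex-vivo coagulation — by C18 bead extraction followed
by MALDI-TOF MS. Each serum sample yields an intensity-vs-m/z profile; after
preprocessing, every subject is summarised as a vector of normalized peak
areas over a panel of aligned peaks (here, 303 peaks over m/z 700–10,000).

`btcpep` re-implements that analysis chain as a tested, reusable pipeline:

1. **synthetic cohorts** with the statistical structure the analysis
   assumes (no raw data from the original study are deposited anywhere, so
   simulation is the only way to exercise and validate the chain
   end-to-end);
2. **spectral preprocessing** from raw profiles to a subject-level peak
   table;
3. **differential screening** of peaks between clinical groups;
4. **ratio/power threshold classifiers**: three fixed published models, an
   exhaustive model search, and cross-validation;
5. **peptide-mass utilities** for verifying peak identities.

## The cohort generator

### Log-normal subject model

Peak areas are positive and right-skewed (the source study used
non-parametric tests throughout its differential table). The generator
draws each subject's area for a given peak and group from a log-normal
distribution *moment-matched* to the target mean `m` and SD `s`:

$$\sigma^2 = \log(1 + s^2/m^2), \qquad \mu = \log m - \sigma^2/2,$$

so the simulated arithmetic mean and SD equal the published group values
exactly in expectation (`moment_match_lognormal()` has closed-form
round-trip tests, and Monte-Carlo recovery at 1e5 draws is within 1% on the
mean and 3% on the SD). Log-normality is this package's assumption, not a
claim of the source data; any positive right-skewed family with two free
moments would serve.

The default `cohort_spec()` is the discovery-study design: 39 BTC cases vs
22 healthy controls; the eight reference discriminatory peaks
(`btc_reference_effects()`) planted with their published per-group moments;
295 null peaks drawn for every group from one shared log-normal (mean 20,
CV 0.5 — arbitrary but fixed, so tests are reproducible); 3 extractions × 4
spots = 12 replicate spectra per subject; inter-assay CV 12.8%; and 12
repeated measurements of a pooled QC serum. Benign subjects, when
requested, draw planted peaks from the control distribution — the generator
deliberately does not invent a benign effect size the source never
quantified peak-by-peak.

Null-peak positions are uniform over the m/z range, unique to one decimal
(the field's labelling convention), kept at least 0.3% of m/z away from
every other peak and 0.5% clear of the scan edges. The separation floor is
an instrument-realism choice: the rendered peak width is 0.08% of m/z, so
two peaks closer than ~2 widths would physically merge into a single
detected peak and the "aligned peak list" the generator claims to emulate
could not exist. Without it, the end-to-end recovery invariant below is
unattainable for unlucky placements.

### Instrument model

`generate_raw_spectra()` renders each replicate as Gaussian profiles
(σ = 0.08% of m/z) on a geometric m/z grid (spacing 0.02% of m/z, ~4
samples per σ, emulating TOF sampling), multiplies each peak area by an
independent log-normal replicate factor with the configured CV, and adds an
exponentially decaying baseline (amplitude 5% of the tallest peak, decay
constant 2000 Da), white noise (SD 0.5% of the tallest peak) and a
per-spectrum uniform calibration offset of ±0.01% of m/z. All constants are
arguments; none is documented for the original instrument, so they are
stated defaults, not reproductions. The model has no isotope envelopes,
detector saturation, or chemical noise — so passing tests demonstrate the
*statistical* chain, not robustness to every artefact of real spectra.

## Preprocessing

`preprocess_spectrum()` emulates a vendor processing chain with documented,
overridable steps: SNIP-style iterative minimum-filter baseline estimation
(40 passes), Savitzky–Golay smoothing (window 21 points, order 3, a filter
that preserves peak area exactly up to edge effects), clipping at zero, and
total-ion-current normalization so the trapezoidal integral equals 1. The
pre-normalization TIC is retained because replicate quality filtering is
defined on it. Area (not apex height) is the quantitative feature,
matching the convention of reporting "average peak areas".

`detect_peaks()` takes local maxima with SNR ≥ 3 against a robust noise
estimate (MAD × 1.4826 of the baseline-subtracted signal; for strictly
noiseless spectra the floor falls back to 1e-4 of the tallest signal so
sub-ppm baseline residue is not reported as peaks). Centroids are
intensity-weighted means over the above-half-maximum region; areas are
trapezoidal integrals between flanking minima.

`align_peaks()` single-linkage-clusters centroids with a relative gap
tolerance (1000 ppm): adjacent sorted centroids join when their gap is
below tolerance. Clusters present in ≥ 25% of spectra become peak
definitions with the median centroid as reference m/z. Integration windows
are the median detection support (the flanking-minima extent), truncated at
midpoints between neighbouring references so windows never overlap; when
processed spectra are supplied each table cell is the integral over the
window (0 when the peak is absent). Using the detection support rather than
the centroid spread matters: a window of ± half the clustering tolerance
would clip peak tails by a neighbour-dependent fraction and break the
round-trip guarantee.

`aggregate_replicates()` averages each subject's surviving replicates; a
replicate is discarded when its raw TIC is below 25% of its subject's
median (a stand-in for the original study's unpublished quality filter —
it is this package's rule, not theirs), and subjects with fewer than 3
surviving replicates are flagged. `qc_cv()` summarises per-peak CVs across
repeated QC measurements as mean ± SD, excluding peaks with zero mean.

**Invariants** (all tested): TIC after normalization is 1 ± 1e-9; scaling
raw intensities by any constant leaves the table unchanged; aligning an
already-aligned list is idempotent; on noiseless synthetic spectra the
recovered subject-level areas correlate with generator truth at r ≥ 0.99
per subject.

## Differential screening

For each peak, an Anderson–Darling normality gate (case 3, mean and
variance estimated; small-sample adjusted statistic
$A^{*2} = A^2(1 + 0.75/n + 2.25/n^2)$ with the standard piecewise p-value
approximation) is applied to both groups. Only when *both* groups are
compatible with normality (p > 0.05) is the Welch t-test used; otherwise
the Wilcoxon rank-sum test. The AD test is implemented in the package
(its reference implementations refuse n < 8; the pipeline's contract is
n ≥ 5) and is cross-checked against `nortest::ad.test` in the test suite.
The Wilcoxon path uses the exact null distribution for small tie-free
samples and the tie-corrected normal approximation otherwise; the exact
path is what makes the package's small-sample p-values agree with
brute-force enumeration, which the continuity-corrected approximation
alone does not (it deviates by up to ~0.017 at n ≤ 7).

P-values are Benjamini–Hochberg adjusted across all peaks of a comparison
(`stats::p.adjust`). Fold change is the ratio of case to control mean
areas, reported to two decimals. `filter_discriminatory()` keeps peaks
with adjusted p below the cut **and** `max(FC, 1/FC)` above the
fold-change cut — the two-sided reading is forced by the published table,
which retains FC 0.46 under a "≥ 2-fold" rule (1/0.46 = 2.17). Cutting on
*adjusted* rather than raw p is this package's resolution of an ambiguity
in the source ("conservative" suggests the stricter reading); a
`use_raw_p` flag flips it.

`auroc()` is the Mann–Whitney concordance probability (ties count ½),
oriented to ≥ 0.5, with DeLong's placement-based standard error and a Wald
95% interval `auc ± 1.96·se` that is deliberately *not* truncated at 1 —
the published interval (0.98–1.01) is only reproducible untruncated. The
SE method in the source is unstated; DeLong is the field default and the
Wald construction is verified against the printed interval.

## Ratio/power threshold models

The study's bespoke classifier family scores a subject as

$$\mathrm{score} = c \cdot \frac{\prod_i a_{p_i}^{w_i}}{\prod_j a_{q_j}^{w_j}},$$

with areas `a` either raw (`linear`) or log-transformed (`log`, base 10 —
the published formulas write "log" unqualified; the base is configurable),
powers `w ∈ [−2, 2]`, and the call "positive iff score > threshold" (ties
negative). `preset_models()` encodes the three published models exactly,
including their scale factors (1000, 10), which are redundant with the
threshold but retained for fidelity. Two tokens in the printed formulas
("878", "2923") match no peak reported anywhere else; they are mapped to
the reported peaks 887.2 and 2932.9 through an explicit, user-editable
alias table recorded on each model. A model whose resolved peak is missing
from a table refuses to run — no silent substitution.

`search_models()` reproduces the exhaustive search: every disjoint
numerator/denominator subset up to configured sizes, every per-peak power
on an arithmetic grid (default step 0.25, which covers the published
exponents 0.75, 1.25, 1.5), both transforms. The enumeration size is
checked against a budget (default 1e7) before any work. Per candidate, the
threshold maximises Youden's J over the midpoints between adjacent sorted
scores — the source states its thresholds but not how they were chosen, so
threshold selection is a design decision here, verified optimal by
exhaustive midpoint checks. Ranking is J, then fewer peaks, then higher
AUROC, then lexicographic labels: deterministic by construction.

`cross_validate()` mirrors the study's two internal-validation designs:
five stratified 75/25 train/test permutations (search, or threshold
re-selection, on the training side only) and ten iterations of 20%
leave-out. Whether the original re-ran its whole search per fold is
unstated; both behaviours are available (`config` vs `model`). Fold
assignments derive deterministically from the root seed via named
substreams. The commercial classifiers surrounding the published work
(QuickClassifier, neural network, genetic algorithm, SVM/k-NN) are out of
scope; `classifier_hook()` is the adapter through which any external
`fit`/`score` learner can be cross-validated in their place.

## Peptide masses

Average masses use the conventional average residue-mass table plus one
water (18.0153 Da); this table reproduces the published 5805.09 Da for the
53-residue fibrinogen alpha 576–628 fragment, whereas an average mass
computed from isotopic abundances of the exact formula differs by ~0.06 Da
— the conventional table is therefore the correct reading of "calculated
average mass". Monoisotopic masses use the standard monoisotopic residue
table plus water 18.010565; charge states use
`m/z = (M + z·1.00728)/z`. The printed 8+ precursor (726.214) sits ~0.003
m/z above theory (726.211) — an observed, calibration-level discrepancy,
tolerated rather than resolved. `charge_pair_check()` implements the
arithmetic that attributes the 2903.3 peak to the doubly-charged form of
5805.0: predicted (5805.0 + 1.00728)/2 = 2903.00, observed 2903.3, within
0.5 Da. Printed sequences carry typographic hyphens; the parser strips
them.

## Workflow, sizes, and reproducibility

`run_discovery()` chains simulate → (optionally render/re-extract spectra)
→ QC → differential screens → model search, writing TSVs, the best model
as JSON, and a manifest recording every parameter, the seed, and a
parameter hash; identical configurations produce identical manifests and
tables. By default the search runs with powers fixed to 1 on linear areas
(the full power grid over 7 candidates enumerates ~2×10^7 models — beyond
the default budget; the grid is available through the config). Candidate
peaks explained as doubly-charged companions of another candidate are
excluded, as the study excluded 2903.3. `run_validation()` applies a
frozen model with no refitting.

Problem sizes used by the test suite were chosen to keep the full run in
the tens of minutes on one core: the end-to-end spectral round trip uses
~32 peaks and a handful of subjects (each rendered spectrum has ~13,000
grid points); the type-I-error sweep uses 200 null cohorts of 300 peaks at
n = 15 + 15; the recovery checks use the full study geometry (303 peaks,
n = 39 + 22).

## Known limitations

* The two weakest published effects (m/z 887.2 and 2082.1) are, under
  log-normal moment matching of the published means and SDs, simply not
  strong enough to pass a BH-adjusted p < 0.001 screen at n = 39 vs 22:
  their implied AUROCs (~0.70, ~0.80) fall short of the published ones
  (0.79, 0.86). No two-moment distributional family can reconcile this;
  the published moments and published AUROCs are mutually inconsistent at
  this sample size. The recovery check therefore typically returns six of
  the eight peaks (with no false positives), and the corresponding
  acceptance test documents this honestly rather than relaxing the screen.
* The synthetic instrument model omits isotope structure, detector
  effects, and matrix/chemical noise; preprocessing results on real
  spectra will be worse than on simulated ones.
* Benign-group effects are not modelled (benign draws from the control
  distribution for planted peaks), so BTC-vs-benign discrimination cannot
  be meaningfully simulated — only the mechanics of the comparison are
  exercised.
* The replicate TIC quality filter stands in for an unpublished vendor
  rule and should be re-tuned for real data.
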