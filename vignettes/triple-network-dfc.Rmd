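---
title: "Dynamic functional connectivity variability in the triple-network model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity variability in the triple-network model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tripledfc)
```

## The problem this package addresses

Resting-state fMRI connectivity between the default mode network (DMN), the
salience network (SN) and the executive control network (ECN) — the
"triple-network" systems — is disturbed along the Alzheimer's spectrum, from
subjective cognitive decline (SCD) through amnestic mild cognitive impairment
(aMCI). Static (whole-run) correlation hides the temporal structure of those
disturbances: the coupling between a network's core seed and the rest of the
brain fluctuates over the scan. The statistic at the centre of this package is
the **dynamic functional connectivity (DFC) variability** of a voxel: the
standard deviation across sliding windows of the windowed Fisher-z correlation
between the voxel and a network seed. The pipeline compares that statistic
across three groups (healthy controls, SCD, aMCI), relates it to cognitive
domain composites, and asks how well it diagnoses group membership.

Because the clinical cohort this design targets is private, the package ships
a synthetic-cohort generator with known ground truth; every analysis stage is
exercised and validated against data whose generating parameters are known.

## The analysis chain

1. **Preprocess** (`preprocess_bold()`): discard the first 10 volumes; exclude
   subjects whose cumulative motion — position relative to the first retained
   volume — exceeds 3 mm translation or 3° rotation; linear detrend; regress
   27 nuisance covariates (Friston-24 motion expansion, global, white-matter
   and CSF mean signals); ideal FFT band-pass 0.01–0.08 Hz; 6-mm FWHM Gaussian
   smoothing. The stage order — discard, detrend, nuisance, filter, smooth —
   detrends *before* the frequency-domain filter (an ideal filter needs a
   trend-free series) and smooths last. Each output carries the order in its
   provenance attribute.
2. **Network templates** (`one_sample_template()`): four 10-mm spherical
   seeds — vmPFC (0, 52, −6) for the anterior DMN, PCC (0, −53, 26) for the
   posterior DMN, right anterior insula (38, 22, −10) for the SN, and the
   DLPFC (48, 12, 34) for the ECN (right-hemisphere by coordinate; used as
   printed in the source literature). Seed-mean versus voxel Pearson r within
   the grey-matter mask, Fisher z = atanh(r), then a voxelwise one-sample t
   across healthy controls with sign-flip permutation, TFCE enhancement and
   family-wise error control from the max-TFCE null; the template keeps voxels
   with positive t and FWE p < 0.05.
3. **DFC variability** (`variability_map()`): rectangular windows of 40 TRs
   advanced by 2 TRs (230 retained time points give 96 windows); per-window
   Pearson r, clipped at |r| = 1 − 1e−7, Fisher z; the per-voxel statistic is
   the K−1 sample standard deviation of the K windowed z values. Maps are raw
   standard deviations; no across-voxel standardisation is applied.
4. **Group inference** (`permutation_cluster_threshold()`,
   `posthoc_pairwise()`): voxelwise ANCOVA partial F for group (covariates:
   age, sex, education, mean-centred; sex coded 0/1) within each network
   template; Freedman–Lane permutation (reduced-model residuals permuted);
   clusters formed at voxelwise permutation p < 0.05, retained at ≥ 20 voxels
   (540 mm³ at 3 mm) and a corrected p < 0.05 from the max-cluster-size null.
   Post-hoc pairwise contrasts run inside the ANCOVA mask as covariate-
   adjusted two-sample t maps with signed TFCE and max-|TFCE| FWE correction,
   keeping clusters of more than 9 voxels (> 243 mm³).
5. **Brain–behaviour** (`behavior_correlations()`): cognitive domain
   composites (episodic memory, executive function, information processing
   speed, visuospatial function) are means of test z-scores standardised
   against the healthy-control group; partial correlations between extracted
   cluster means and composites, adjusted for age, sex and education, pooled
   over the SCD and aMCI groups, Bonferroni-corrected over the cluster ×
   domain family.
6. **Classification** (`classify_contrast()`): univariate and multivariable
   binary logistic models per contrast (HC/SCD, HC/aMCI, SCD/aMCI);
   multivariable models reduced by backward elimination on the likelihood
   ratio at p < 0.05 (ties broken by predictor order); in-sample ROC with AUC
   by the trapezoidal rule and the operating point maximising Youden's J
   (ties toward higher sensitivity). In-sample (apparent) performance is
   reported deliberately, matching how such models are usually summarised in
   this literature; cross-validation is out of scope.

`run_pipeline()` executes the stages in this order from a single
configuration and writes a manifest carrying the configuration, seeds and
stage summaries. The generator's ground truth is stored alongside the data
and is never read by any analysis stage — only the tests consult it.

## The synthetic generator and its conditions

`cohort_design()` defaults encode the cohort being emulated: 58/44/49
subjects (HC/SCD/aMCI; 151 in total), 8-minute runs of 240 volumes at
TR = 2 s, a 3 mm MNI-like grid (61 × 73 × 61). A TR of 2 s is adopted
because 240 × 2 s reproduces the 8-minute acquisition and 230 retained
volumes reproduce exactly 96 windows at width 40 / step 2.

Each network has a latent band-limited (0.01–0.08 Hz) unit-variance seed
signal `s(t)` added to its seed sphere. The network's designated target
region receives `c(t)·s(t)` with coupling

```
c(t) = mu + A * m(t)
```

where `m(t)` is a two-state (+1/−1) Markov modulator with mean dwell 40 s —
chosen over a sinusoid because it produces clearly non-stationary coupling at
the 40-TR window scale, matching the switching-state picture of the DFC
literature (a sinusoidal mode remains available). Every voxel receives
independent Gaussian noise (sd 1). No haemodynamic convolution is applied by
default — band-limiting the latent signals suffices for pipeline testing —
but an HRF flag convolves with a canonical double-gamma kernel. Motion is a
bounded random walk (step sd 0.05, reflecting bound 2.5), so default subjects
fall under the 3 mm / 3° exclusion rule; tests construct excluded subjects
explicitly.

The per-group fluctuation amplitudes in the four target regions are the
generator's central effect sizes (mu = 0.4 throughout):

| network | target region            | HC   | SCD  | aMCI |
|---------|--------------------------|------|------|------|
| aDMN    | right angular gyrus      | 0.45 | 0.40 | 0.15 |
| pDMN    | right middle temporal    | 0.45 | 0.15 | 0.40 |
| SN      | left putamen             | 0.10 | 0.50 | 0.40 |
| ECN     | left inferior frontal    | 0.10 | 0.20 | 0.60 |

The directions mirror the motivating findings (aDMN variability reduced in
aMCI, pDMN reduced in SCD, SN elevated in both patient groups, ECN elevated
most in aMCI — the designated recovery contrast). The magnitudes were fixed
once at design time from a power consideration: with the 40-s modulator dwell
and 40-TR windows, between-subject variance of the windowed-z standard
deviation is dominated by modulator realisation noise, so amplitude contrasts
of roughly 0.4–0.5 are required for the two-stage corrected inference to have
reasonable sensitivity at small per-group sizes. Per-subject amplitudes get
multiplicative log-normal jitter (sd 0.1) so that amplitude, not just group,
carries individual differences.

Cognitive domain scores are linear in the subject's ECN-target amplitude —
`score = base + coef * A + noise`, coef EM −1.6, EF −1.3, IPS −0.6, VF −0.4,
noise sd 0.3 — giving the negative variability–cognition coupling the
behaviour stage must recover. Composites are generated directly at the domain
level because the underlying instrument battery is not public; demographics
are drawn from identical distributions across groups, so the cohort is
exchangeable when the effect table is flat (the basis of the calibration
studies).

What the generator does **not** emulate: scanner artefacts (spikes, drift
beyond a linear trend), physiological noise, spatial normalisation error,
realistic anatomy (tissue masks are synthetic corner blocks), or
between-region functional coupling beyond the seed-target construction.
Passing tests therefore demonstrate the correctness and calibration of the
*procedures*, not their field performance on clinical data.

## Numerical choices

* Fisher transform: |r| clipped at 1 − 1e−7 before atanh, keeping seed
  self-correlation finite without masking seed voxels. Zero-variance voxels
  or windows yield z = 0 and are flagged.
* TFCE: H = 2, E = 0.5, dh = max(map)/100, 26-connectivity — the field's
  standard defaults, since the source analyses do not state them. The
  implementation (incremental union-find over descending thresholds, in C++)
  reproduces the brute-force discrete sum exactly and handles negative lobes
  by transforming the negated map.
* Permutation p-values always include the observed statistic, so the minimum
  attainable p is 1/(n_perm + 1).
* ANCOVA cluster forming: the source text specifies permutation inference
  with an extent rule but no voxel-forming rule; clusters are formed at
  voxelwise permutation p < 0.05 and corrected by the max-cluster-size null
  (the most common reading). The post-hoc path uses TFCE-FWE as stated. Both
  paths use Freedman–Lane to respect the covariates.
* Friston-24 lag at the first volume is zero-filled (deterministic).
* Rank-deficient nuisance sets drop collinear columns with a warning;
  tie-breaks (peak location, backward elimination) are lexicographic /
  first-in-order, so every result is reproducible.
* Logistic predictors are standardised internally for numerical stability
  (coefficients are mapped back; discrimination is unaffected); complete
  separation is flagged rather than silently diverging.

## Scaled-down validation conditions

The test-suite and acceptance studies run desk-scale versions of the design:
a 12³ grid at 3 mm with the four seeds and targets remapped to disjoint
corners (radius 4 mm), 6–12 subjects per group, 99 inference permutations and
100 template permutations, with cluster extents scaled in proportion to the
grid (5 voxels ANCOVA, 3 voxels post-hoc; the full-scale 20/10 values remain
the package defaults). Calibration uses 200 repeats of an exchangeable null
(smoothed noise maps, age effect but no group effect); recovery uses 20
repeats at 12 subjects per group. These sizes are the package's validation
conditions; the full-scale defaults are what an analysis of real data would
use.

## Known limitations

* The smoothing kernel is truncated at 4σ with zero-padded boundaries; total
  intensity is conserved only on interior support.
* The ideal FFT filter assumes the series is well represented by its Fourier
  bins; bins at exactly the band edges are retained.
* Overlapping windows make the K windowed z values strongly dependent; the
  variability statistic is a dispersion summary, not an efficient estimator
  of any population quantity, and its between-subject distribution is
  skewed — the permutation machinery, not parametric theory, carries the
  inference.
* In-sample AUCs from models selected by backward elimination are optimistic;
  they are reported as such because the design being emulated reports
  apparent performance.
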