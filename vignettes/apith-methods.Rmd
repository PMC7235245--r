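---
title: "Quantifying intratumor heterogeneity with APITH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity with APITH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-region sampling of a tumor reveals how much its regions differ in
somatic copy number alterations (SCNAs) and DNA methylation — the
intratumor heterogeneity (ITH) that complicates single-biopsy diagnostics
and has prognostic value. Two statistical obstacles stand in the way of
using ITH in cross-patient analyses:

1. indices defined as "the fraction of the genome altered in some but not
   all samples" grow mechanically with the number of samples k taken from
   the tumor, so patients sampled more densely look more heterogeneous;
2. even an unbiased index is estimated with a precision that depends on
   k, so regressing outcomes on it with equal patient weights wastes
   power.

`apith` implements an index and an inference pipeline that address both.

## The APITH index

For a patient with k tumor samples and a pairwise distance $d_{ij}$
between samples i and j,

$$\mathrm{APITH} = \frac{2}{k(k-1)} \sum_{1 \le i < j \le k} d_{ij},$$

the average over all sample pairs. If the sampled regions are
exchangeable draws from the tumor, APITH is a U-statistic of degree 2 and
its expectation does not depend on k. The package supports three
distances:

* **SCNA**: the proportion of array probes whose 4-level copy-number
  status (DEL / LOH / NEUTRAL / AMP) differs between the two samples;
* **methylation**: the Euclidean distance between purity-adjusted beta
  profiles over a chosen probe set;
* **methylation, scaled**: the root-mean-square variant (Euclidean
  divided by the square root of the probe count), used whenever regions
  with different probe counts are compared.

The contrasting *naive* index — the fraction of the genome disrupted by
SCNAs not shared by all samples — is provided (`naive_ith()`) precisely to
demonstrate its upward drift in k; enumerating all K-subsets of one
simulated 12-sample patient shows a flat APITH mean (the subset mean is
*algebraically* equal to the full-sample APITH) against a strictly
increasing naive index.

## Variance of APITH and inverse-variance weights

Write $\sigma^2_d = \mathrm{Var}(d_{ij})$ and
$c = \mathrm{Cov}(d_{ij}, d_{il})$ for two distances sharing one sample.
Under within-patient exchangeability, with $m = k(k-1)/2$,

$$\mathrm{Var}(\mathrm{APITH} \mid k) = \frac{\sigma^2_d + 2(k-2)\,c}{m},$$

strictly decreasing in k. The package assumes $(\sigma^2_d, c)$ shared
across patients and estimates them by pooled method of moments
(`estimate_variance_model()`): for each patient, the within-centered sum
of squares of the distances and the sum of cross-products over distance
pairs sharing a sample have expectations that are *exactly* linear in
$(\sigma^2_d, c)$ — including the finite-sample distortion introduced by
centering at the patient mean — so stacking the per-patient equations and
solving by least squares gives an unbiased estimator. Patients with k = 2
carry no information about the within-patient moments; if no patient has
k ≥ 3 the model falls back to the between-patient distance variance with
c = 0 (and a warning), which still yields the correct *equal* weights.

Association weights are, by default, inverse *total*-variance weights

$$w_i \propto \frac{1}{V_{between} + \mathrm{Var}(\mathrm{APITH}_i \mid k_i)},$$

normalized to mean 1, with $V_{between}$ the between-patient variance of
true ITH (cohort variance of the APITH values minus the mean sampling
variance). This is the efficient weighting for a covariate measured with
heteroscedastic error — the exact analogue of random-effects
meta-analysis weights. The distinction from the naive
$w_i \propto 1/\mathrm{Var}(\mathrm{APITH}_i)$ matters: once a patient's
sampling noise is small relative to the biological spread of ITH, extra
precision adds almost no information, so efficient weights flatten out;
the naive weights keep growing with k, concentrate the analysis on the
densely sampled patients, inflate the sandwich variance, and in our
simulations lose the power advantage over the unweighted fit that
weighting exists to provide. The naive form remains available
(`between = "none"`). Two further numerical guards, documented in
`apith_variance()` / `apith_weights()`: the variance formula is floored
at 5% of its $\sigma^2_d/m$ term (a noisy negative $c$ estimate could
otherwise turn it nonpositive at large k), and weights above 10× the
mean are trimmed, as in survey practice, before renormalization.

### The jackknife cross-check

A delete-one-sample jackknife of APITH is provided as an independent check
of the formula. The textbook jackknife is *structurally* biased for a
degree-2 U-statistic at these k: its expectation works out to
$4(\sigma^2_d + (k-4)c)/(k(k-2))$, roughly twice the true variance when
$\sigma^2_d$ dominates. `apith_variance_jackknife()` therefore combines
the jackknife value with the within-patient distance variance — two
linear equations in $(\sigma^2_d, c)$ — and plugs the solution into the
exact formula; this corrected estimator is unbiased for k ≥ 4 (at k = 3
the two moments are collinear and c is set to 0, leaving a residual bias
of order c). The raw jackknife remains available via `correct = FALSE`.
At cohort level, `estimate_variance_model_jackknife()` pools the
jackknife and within-patient variance moments across patients with mixed
k, which identifies both parameters — including the k = 3 contribution —
and serves as the independent cross-check of the pooled moment model.

## Survival association

`fit_cox()` regresses overall survival (or distant metastasis) on APITH —
standardized to unit variance by default, so hazard ratios are per sd —
adjusted for stage, age and smoking, via the weighted Cox partial
likelihood (`survival::coxph` with case weights, Efron ties, and a robust
sandwich variance whenever the weights are non-uniform).
`km_stratify()` produces the median-split Kaplan–Meier analysis, with an
option to restrict to patients with at least 3 samples;
`compare_weighted_unweighted()` and `power_comparison()` run the
weighted/unweighted contrast, in simulation mode reporting empirical
power.

Why weighting helps: the hazard in the simulated cohorts depends on the
patient's *latent* expected ITH (the expectation of the pairwise distance
over the sampling of regions), while the analysis can only use the APITH
*estimate* from the k drawn samples. Estimates from few samples carry
more noise; down-weighting them both sharpens power and reduces the
attenuation of the estimated hazard ratio. This is also why the simulator
drives hazards with the latent quantity (`theta`) rather than the
realized sample average: with the realized value driving hazards there
would be no estimation error, the unweighted maximum-likelihood fit would
be efficient, and weighting could only lose power — contradicting the
premise the weighting is designed for. Both quantities are recorded per
simulated patient.

Because the covariate is a noisy estimate of the latent trait, the raw
hazard-ratio estimate is attenuated even in the weighted fit. For effect
*estimation* the package provides regression calibration
(`calibrate_apith()`): each APITH value is shrunk toward the cohort mean
by its reliability
$\lambda_i = V_{between}/(V_{between} + \mathrm{Var}(\mathrm{APITH}_i
\mid k_i))$ and scaled by the estimated sd of true ITH, so the fitted
coefficient is a log hazard ratio per sd of *true* ITH, approximately
free of attenuation — the standard errors-in-variables remedy. The
weighted-vs-unweighted *power* contrast is run on the uncalibrated
covariate: calibration itself acts as a soft down-weighting of noisy
patients and would saturate both arms, erasing the contrast under study.

In repeated null simulations (no ITH effect, n = 300, k ∈ 2..8) the
weighted test's empirical size sits near 0.055 at a nominal 0.05 — the
usual mild finite-sample behavior of sandwich variances; under a hazard
ratio of 1.5 per sd, the calibrated weighted fit recovers the effect
essentially unbiased (mean HR ≈ 1.51 with ≈ 92% CI coverage over 200
replicates) while the uncalibrated, unweighted fit is visibly attenuated
(these are the quantities `scripts/acceptance.R` recomputes).

## SCNA calling from BAF/LRR

Segmentation uses **only** B-allele frequencies, which is robust to the
wave and level artifacts that plague total-intensity segmentation in
heavily rearranged genomes: the mirrored BAF $|BAF - 0.5|$ of germline
heterozygous probes is segmented per chromosome by recursive binary
splitting under a squared-error cost with a BIC-like penalty
(`penalty * sigma^2 * log n`, noise estimated from the median absolute
successive difference). Homozygous probes carry no allelic information
and inherit the surrounding segment. The minimum segment length (15
heterozygous probes by default) sets the resolution; true boundaries
closer than that to another boundary or a chromosome end cannot be
placed exactly.

Classification then compares each allelically imbalanced segment's LRR
against the pooled LRR of the allele-balanced segments with a two-sided
Student's t-test, Benjamini–Hochberg adjusted: significantly higher →
AMP, lower → DEL, neither → copy-neutral LOH. Three numerical choices
matter and are worth stating:

* the BAF-deviation threshold is median + 3×MAD of mirrored BAF taken
  *within the most allele-balanced segment* (a genome-wide MAD would be
  inflated exactly in the heavily altered genomes the method targets);
* AMP/DEL additionally require a minimal LRR shift (default 0.1, about
  half a one-copy shift at 50% purity): with hundreds of probes per
  segment the t-test is significant for practically irrelevant
  differences, which would otherwise relabel LOH;
* the neutral LRR reference is trimmed of outlying probes before testing,
  because homozygous deletions are allele-*balanced* (all allelic signal
  comes from contaminating normal cells) and would drag the reference
  down.

Copy number is estimated per segment from mean LRR as
$\mathrm{CN} = \mathrm{round}(2 \cdot 2^{LRR/\gamma})$ with
$\gamma = 0.55$, floored at 0; when purity is known the normal-cell
contribution is removed first,
$\mathrm{CN} = ((2 \cdot 2^{LRR/\gamma}) - 2(1-\pi))/\pi$ — without this,
a contaminated homozygous deletion rounds to CN 1 and a CN 4 gain to CN
3, and the driver rules below could never fire exactly. A BAF-neutral
segment whose estimated CN is 0 is relabelled DEL: homozygous deletions
have no allelic signal, and only the copy number identifies them.

Driver SCNA events are called per gene: oncogene with CN ≥ 4 →
amplification event; tumor suppressor with CN = 0 → deletion event.

## Methylation processing

Observed tumor beta values are a purity-weighted mixture of tumor and
normal signal; `adjust_purity()` inverts it,
$\beta_t = (\beta_{obs} - (1-\pi)\beta_n)/\pi$, clipped to [0, 1], and all
downstream methylation analysis uses adjusted betas. Purity itself is an
input (the simulator's truth, or an estimate from an external tool);
estimating purity from 450K intensities is out of scope. A missing
matched normal is imputed by the per-probe mean over all normals
(`mean_normal_beta()`).

CIMP status is called by hierarchical clustering (Euclidean, average
linkage — both configurable, neither canonical) of tumor samples on the
5000 most variable promoter CpG-island probes, cut into two groups; the
group hypermethylated relative to the normal reference is CIMP-H. The
two-group cut is an operationalization choice: no quantitative CIMP-H
threshold is standard. "Most variable" is computed over tumor samples
only. Driver methylation events use the promoter-island mean beta per
driver gene with an absolute difference cutoff of 0.3 against the
normal reference.

Region-restricted methylation ITH (`region_apith()`) selects the top 10%
most variable probes within a region class (CpG context, gene context, or
driver class), uses the scaled (RMS) distance so regions of different
sizes are comparable, and compares region groups by unpaired two-sided
t-tests.

## Phylogenies and congruence

Per-patient trees are built from distance matrices by balanced minimum
evolution (`ape::fastme.bal`, with NNI/SPR refinement; neighbor joining
available as a fallback engine), negative branch lengths clamped to 0,
optionally rooted on a normal reference leaf treated as aberration-free.
SCNA and methylation matrices are combined by max-normalizing each and
averaging,
$d^0_{ij} = 0.5\,(d^1_{ij}/\max d^1 + d^2_{ij}/\max d^2)$, falling back
to the normalized SCNA term for samples lacking methylation data.
Congruence between the two data types pools *within-patient* sample pairs
only (cross-patient pairs would be dominated by between-tumor
differences), computes Spearman's rank correlation, and assesses
significance by permuting sample labels within each patient.
Robinson–Foulds distances (raw and normalized by 2(n−3)) quantify
topological agreement between SCNA-only and methylation-only trees.

## The synthetic cohort generator

Every stage above is exercised against `simulate_cohort()` /
`simulate_patient()`, which generate multi-region tumors with known
truth: a random rooted clone tree per patient (founder events public,
per-branch private events), probe-level BAF/LRR tracks around germline
genotypes (allelic phase drawn once per patient, so samples of one clone
are identical at noise 0), purity-mixed methylation betas over a
450K-like bimodal normal profile, and survival/metastasis times from an
exponential proportional-hazards model with stage, age and smoking
effects and censoring uniform over an interval calibrated to the target
censoring rate.

Defaults were fixed once to emulate the study conditions the package
targets: 2–11 samples per patient; purity uniform on (0.5, 0.95) —
tumor specimens are typically required to have at least 50% tumor
nuclei; 20,000 probes by default (APITH is a proportion, so it is
scale-free in probe count; segment lengths are specified as genome
*fractions* for the same reason, and desk-scale analyses here use 4,000
probes); per-patient branch event rates uniform on (0, 12) events with
mean segment fraction 5%, chosen so the cohort's latent SCNA ITH has
mean ≈ 0.19 and sd ≈ 0.12, matching the reported distribution of SCNA
APITH in multi-region lung adenocarcinoma (mean 0.184, sd 0.153); a
hazard ratio of 1.5 per sd of ITH as the canonical effect size. TSG
homozygous deletions are nested inside a wider hemizygous loss — their
focal real-world configuration — which also gives the BAF-only
segmentation boundaries to find. The number of samples k is drawn
independently of the true ITH by default; `corr_k_ith = TRUE` couples
them to probe confounding by sampling intensity.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: array wave artifacts and GC effects,
subclonal mixtures within one sample (each sample is one clone's profile
at a given purity), SNV-level clonal structure beyond presence/absence,
probe-level spatial correlation of methylation noise, and informative
censoring. Clone-level exchangeability of samples is exactly true in the
generator; in real tumors spatially adjacent samples are correlated, so
the variance model's `c` absorbs only part of that structure.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
make Monte-Carlo error small relative to the tolerances they check:
4,000-probe genomes; 2,000 replicate patients per k for variance
calibration; cohorts of n = 300 patients with k ∈ 2..8 and 500 (power) /
1,000 (size) / 200 (recovery) replicates; 30 replicate cohorts for
congruence. All randomness flows from a single seed argument.

## Known limitations

* BAF-only segmentation cannot separate adjacent events with equal
  allelic imbalance but different total copy number (e.g. a CN 4 gain
  abutting a hemizygous loss at ~60% purity); such junctions are merged
  and classified by the dominant signal.
* The status of a homozygous deletion is recovered only through the LRR
  copy-number estimate; at purity near 1 its BAF is undefined (no
  alleles) and only noise is observed there.
* The variance model assumes $(\sigma^2_d, c)$ shared across patients;
  strong patient-specific distance scales violate this and push the
  weights toward misspecification (the trimming guard bounds the
  damage).
* The weighted sandwich test is mildly liberal in finite samples
  (empirical size ≈ 0.06 at n = 300).
* Purity is taken as known; errors in purity propagate linearly into
  adjusted betas and copy-number back-correction.
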