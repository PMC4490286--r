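---
title: "Joint SNP-EEG component analysis: models, parameters and design choices"
author: "paricaeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint SNP-EEG component analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paricaeeg)
```

## The problem

Psychotic disorders such as schizophrenia and psychotic bipolar disorder
are polygenic: risk is spread over many common variants of small effect.
Resting-state EEG oscillations (delta, theta, alpha, beta activity) are
heritable intermediate phenotypes that sit closer to the underlying biology
than the diagnosis itself. `paricaeeg` implements a multivariate
genotype-phenotype analysis for this setting: instead of testing each SNP
against each phenotype, it decomposes both data blocks into a small number
of components and asks whether a *weighted combination of SNPs* covaries
with a *weighted combination of spatio-spectral EEG features* across
subjects.

The pipeline is: SNP quality control and univariate prefiltering; spectral
compression of EEG (optional, when raw epochs are supplied); model-order
selection; a coupled two-modality ICA ("parallel ICA"); covariate-adjusted
association testing over all component pairs; group and clinical
comparisons; and leave-one-out reliability. A synthetic-cohort generator
with known latent truth makes every stage testable end to end.

## Data model

Both modalities are subjects-by-features matrices decomposed as
$X \approx A S$: the *loading coefficients* $A$ (subjects $\times$ k) give
each subject's expression of each component, and the *source maps* $S$
(k $\times$ features) give each component's weight on each SNP or each
channel-frequency feature. Independence is sought along the feature axis,
which suits sparse genetic components (a component concentrates on a small
set of SNPs) and localized spatio-spectral patterns.

## SNP quality control

The SNP side follows standard GWAS practice, in this order, with these
defaults:

| step | statistic | default |
|---|---|---|
| subject missingness | per-subject missing rate | > 3% removed |
| heterozygosity | het fraction z-score | beyond 3 sd removed |
| relatedness | moment estimator (GRM off-diagonal) | > 0.1875, higher-missingness member removed |
| MAF | minor allele frequency | < 5% removed |
| call rate | per-SNP call rate | < 98% removed |
| HWE | exact test in controls | P < 1e-5 removed |
| differential missingness | Fisher exact, case vs control | P < 1e-5 removed |
| LD pruning | dosage $r^2$ in 10 kb windows | $r^2$ > 0.8, later SNP removed |

The Hardy-Weinberg test is the exact conditional (Levene-Haldane) test
rather than the chi-square approximation: at thresholds like $10^{-5}$ the
chi-square tail is unreliable for rare genotype classes, and the exact
distribution admits a direct enumeration oracle, which the test suite
exploits (the implementation is checked against full enumeration for
*every* genotype configuration with up to 50 diploids).

Relatedness is the allele-frequency-standardized genetic covariance
(GRM off-diagonal, a PI-HAT analogue): approximately 1 for duplicates, 0.5
for first-degree relatives, 0 for unrelateds. Which member of a related
pair is dropped is decided by the higher missing rate.

Population stratification is handled eigenstrat-style: PCA on standardized,
mean-imputed dosages; the top 10 subject-score vectors are each tested
against self-reported ethnicity by one-way ANOVA; components with P < 0.05
are regressed out of every SNP vector. The report also verifies that the
scanned components do not separate cases from controls. Residualization is
idempotent (re-adjusting with the same components is a no-op), which the
suite asserts to $10^{-10}$.

The univariate prefilter then fits, per SNP, a logistic regression of case
status on the adjusted dosage, separately for each case group against
controls, and keeps the union of SNPs with uncorrected Wald P < 0.025 in
either contrast. The threshold deliberately trades specificity for an
adequate SNP-to-sample ratio in the multivariate stage. Perfectly
separating SNPs fall back to the score test and are flagged. Genomic
inflation ($\lambda_{GC}$) and q-q tables are emitted per contrast;
on null simulations $\lambda_{GC}$ stays within [0.95, 1.05] at 5000 SNPs.
No covariates enter the logistic model because stratification has already
been residualized out of the dosages; this ordering is a design choice.

Missing dosages are mean-imputed for PCA and correlation computations and
dropped casewise in the logistic fits. A sex-discordance check is out of
scope (it needs X-chromosome intensity data the pipeline does not model);
positions are 1-based and LD windows are closed intervals.

## EEG spectral stage

When raw epochs are supplied, each epoch/channel series is Hamming-windowed
and Fourier-transformed; amplitude is the square root of the one-sided,
window-power-normalized periodogram, so summed squared amplitudes equal the
windowed mean-square power exactly (this makes the Parseval check in the
suite exact rather than approximate). Bins below 1.5 Hz are discarded to
guard against slow eye-movement artifacts. All subjects' spectra are
stacked (channels within epochs within subjects) into one matrix over
frequency bins, PCA-reduced to 8 components by default and unmixed by
Infomax. Per-subject weights are back-reconstructed by averaging epoch
weights within subject and channel, and flattened channel-major, so a
64-channel montage with 8 components yields 512 columns. Component spectra
are unit-normalized with positive peaks; the subject weights carry the
magnitude. The stacking order and back-reconstruction rule are design
choices (several schemes produce the same output shape); the column order
is recorded in the object metadata. A precomputed feature matrix can be
supplied instead, skipping this stage.

## Model-order selection

Two estimators are provided. The *MDL* estimator minimizes the Wax-Kailath
criterion over the eigenvalues of the sample covariance, with the i.i.d.
sample count set to the number of subjects and only the non-null
eigenvalues (at most subjects minus one) entering the criterion. The
*stability* (consistency) estimator reruns ICA on feature-subsampled
replicates (default 80% of features, 10 runs) for each candidate order,
matches components between every pair of runs by the Hungarian algorithm
on absolute loading correlations, and picks the order with the highest
mean matched correlation, breaking ties toward the smaller order; a flat
or uniformly low profile is flagged low-confidence. In the
standard configuration the EEG side uses MDL and the SNP side uses
stability.

## Parallel ICA

Each modality runs full-batch natural-gradient Infomax with the logistic
nonlinearity: PCA whitening to k dimensions, updates
$\Delta W \propto (I + (1-2y)u^\top) W$, learning rate 0.1 halved whenever
the angle between successive updates exceeds 60 degrees (floor $10^{-6}$),
stopping when the relative update norm falls below `tol` ($10^{-7}$).
Full-batch updates make runs deterministic given the seed. An extended
(tanh, kurtosis-sign) variant is available via a flag for sub-Gaussian
sources; the default logistic variant is appropriate because the latent
components of interest are sparse and super-Gaussian.

The coupling objective adds, after every joint iteration, a gradient-ascent
step on the squared Pearson correlation of paired loading columns. Pairs
enter when their absolute loading correlation exceeds 0.3, are made
disjoint greedily by |r| (each component joins at most one enhanced pair,
preventing competing gradients on one component), and the coupling weight
grows linearly from 0 to 0.5 over the first half of training. Each side's
coupling step is capped at half that side's most recent Infomax update
norm. Two consequences are worth stating plainly:

* with the coupling weight set to 0 the algorithm is *bit-identical* to
  two independent Infomax runs (the suite asserts this), and
* because the cap ties the coupling force to the Infomax step size, the
  coupling decays as the ICAs converge; its role is to steer the
  optimization toward basins where paired components align, not to inflate
  the final correlation. On well-identified synthetic sources the coupled
  and decoupled solutions essentially coincide, and under the global null
  the family-wise error of the corrected association test stays at its
  nominal level (checked over 200 null cohorts) -- the coupling does not
  manufacture associations.

All coupling constants (entry threshold 0.3, peak weight 0.5, cap rule)
are exposed in `coupling_config()`.

## Association, selection, group tests

Every (EEG component, SNP component) pair is tested: raw Pearson
correlation of the loading columns, and partial correlation given age
(linear), sex, ethnicity and site (full-rank indicator contrasts), with
two-sided P from the t distribution on $n - 2 - q$ degrees of freedom.
Both raw and partial values are reported. Significance uses a Bonferroni
threshold of $\alpha / (k_{eeg} \cdot k_{snp})$ over the component grid
(0.05/45 in the 5-by-9 configuration). Component features are selected at
$|Z| \ge 2$ on the standardized source maps and reported with relative
weights $|Z| / \max |Z|$. Group comparisons use two-sided t-tests after a
Shapiro-Wilk normality check (failure switches to Mann-Whitney, flagged);
clinical scores are correlated with loadings over non-missing subjects.
These post-hoc tests are reported uncorrected by default, with an optional
FDR flag.

## Leave-one-out reliability

The decomposition is rerun once per left-out subject with identical seeds
and settings; each rerun's components are matched to the original by the
Hungarian algorithm and sign-aligned. Matching defaults to source maps
(feature space), which are invariant to the subject count; loading-space
matching is available and drops the left-out row from the reference. Reruns
reuse the original initialization so the perturbation measured is the data
perturbation, not restart noise. Non-convergent reruns are excluded from
the averages and counted. The reliability index per significant pair is the
mean matched absolute correlation per modality.

## The synthetic generator

`generate_cohort()` emulates a three-group multisite cohort (defaults:
56 controls, 105 and 145 probands; 2000 SNPs; 512 features). Latent subject
loadings are standard normal, with designated cross-modal pairs drawn
bivariate-normal at the designed r and per-group mean shifts added after
standardization. Source maps are sparse with (near-)disjoint supports and
*equal power per component* — without equal power, chance eigenvalue gaps
can make under-factored models spuriously stable, which defeats order
selection; equal-power components are also what "well-separated" should
mean for a fair recovery test. Genetic effects enter through the genotype
channel on the logit scale: the per-SNP minor-allele probability is
`plogis(qlogis(p) + effect * weight * loading)`, keeping dosages legal in
{0,1,2} and Hardy-Weinberg-distributed conditional on the subject.
Population structure uses the Balding-Nichols beta model at a given
F\_st with two subpopulations. Demographics (age, sex, site, ethnicity,
symptom scores) are drawn from realistic per-group distributions,
independent of the latent truth by default, with a confounding knob for
testing the partial-correlation stage under misspecification.

What the generator does *not* emulate: haplotype LD structure (only
optional duplicated-SNP blocks for pruning tests), non-random missingness,
genotyping batch effects, and realistic EEG noise spectra. Passing tests
therefore demonstrate algorithmic correctness and calibration, not
robustness to every artifact of real data. One consequence of the
loading-to-genotype effect direction: strongly affected SNPs are binomial
mixtures and can themselves deviate from Hardy-Weinberg equilibrium, so at
large effect sizes the HWE filter removes part of the signal support; the
default effect size keeps this modest, and it is a known property of the
design, not of real genotype-phenotype causation.

## Problem sizes and numerical choices

The validation suite uses reduced problem sizes chosen to exercise every
code path at desk scale: order-selection recovery at 306 x 512 (MDL, five
sources) and 300 x 2000 (stability, nine sparse components over candidates
5..12); coupled-recovery at 300 subjects with a designed r of 0.5 (median
recovered max cross-correlation over 20 seeds within 0.15 of the design);
family-wise error over 200 null cohorts of 150 subjects; leave-one-out
reliability on a 60-subject coupled cohort (60 reruns), where both
modalities' reliability for the significant pair exceeds 0.99. Full-size
runs (306 reruns, tens of thousands of SNPs) use identical code.

Degenerate inputs are handled explicitly: constant data gives MDL order 0;
monomorphic SNPs give HWE P = 1; zero-variance dosages give prefilter
P = 1; single-ethnicity cohorts adjust nothing and say so; rank-deficient
covariate designs drop aliased columns with a warning; ICA requested above
the data rank errors; non-convergent ICA returns a flagged partial result.
Gaussian sources are not identifiable by ICA (any rotation has equal
likelihood) and no test demands their recovery.

## Limitations

Logistic Wald P-values are slightly conservative at small per-contrast
sample sizes; the score-test fallback only covers separation. The LD
pruner is the greedy left-to-right scan, which matches common practice but
is order-dependent by construction. Three-way (or higher) modality fusion,
reference-panel imputation, X-chromosome handling and pathway enrichment
are out of scope.
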