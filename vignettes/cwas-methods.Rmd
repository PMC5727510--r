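---
title: "Connectome-wide association analysis with cwas: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-wide association analysis with cwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwas)
```

## The problem and the model

Resting-state fMRI measures spontaneous BOLD fluctuations; the correlation
structure among voxel time series — intrinsic functional connectivity (iFC)
— is a stable individual trait. A connectome-wide association study asks, at
every voxel, whether inter-individual differences in that voxel's
*whole-brain connectivity profile* are explained by a continuous phenotype
(here: literacy and numeracy standard scores), adjusting for nuisance
covariates.

`cwas` implements this as multivariate distance matrix regression (MDMR),
voxel by voxel:

1. **Profiles.** For target voxel $v$ and subject $s$, the iFC profile is
   the vector of Pearson correlations between $v$'s time series and every
   other in-mask voxel (length $V-1$).
2. **Distances.** For subjects $i, j$, let $r_{ij}$ be the spatial
   correlation of their profiles at $v$. The inter-subject distance is
   $d_{ij} = \sqrt{2\,(1 - r_{ij})}$, so identical profiles give 0,
   uncorrelated profiles $\sqrt 2$, and anti-correlated profiles 2.
3. **Pseudo-F.** With the Gower-centered matrix
   $G = C A C$, $A = -\tfrac12 d^2$, $C = I - \mathbf{1}\mathbf{1}'/n$, and
   hat matrices $H$ (full design: intercept + nuisance + variable of
   interest) and $H_0$ (nuisance only),
   $$F = \frac{\operatorname{tr}(HGH) - \operatorname{tr}(H_0GH_0)}
             {\operatorname{tr}\big((I-H)G(I-H)\big)\,/\,(n - p)}.$$
   For univariate Euclidean responses this reduces to the classical partial
   F of ordinary regression (and it matches `vegan::adonis2`'s marginal F;
   both identities are pinned by tests).
4. **Inference.** Significance comes from permutation: the
   nuisance-residualized variable of interest is permuted (Freedman–Lane;
   permuting the raw variable is available via `scheme = "raw"`), with
   $p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_{perm})$ and
   $Z = \Phi^{-1}(1-p)$. One shared permutation sequence is drawn per run
   and reused across voxels, which is what makes permutation-based cluster
   correction possible.

The distance-to-Gower composition has a useful identity: because
$A = R - 1$ on the off-diagonal and centering annihilates constants,
$G = C R C$ where $R$ is the matrix of profile correlations. The
implementation uses this fused form; the composed
`distance_matrix() |> gower_center()` path is exported and the two are
checked against each other and against a literal brute-force
transcription in the tests.

**Two preset models.** The analysis is run once with literacy and once with
numeracy as the variable of interest; both adjust for age, sex, handedness,
mean framewise displacement, and global connectivity (GCOR, the mean of the
full voxel-by-voxel correlation matrix, computed in $O(TV)$ memory). IQ is
deliberately not a covariate.

## Cluster-extent inference

Z maps are thresholded at $Z > 3.1$ (strict) and connected components are
formed under 26-connectivity (6 and 18 available). Two corrections are
implemented:

* **Gaussian random fields** (`grf_cluster_p`): expected cluster count from
  the 3D Euler-characteristic density
  $E_m = R\,(4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$ with $R$ the resel
  count, expected suprathreshold volume $E_N = V\,(1-\Phi(u))$, and the
  exponential cluster-size tail $P(n \ge k) = \exp(-\beta k^{2/3})$,
  $\beta = (\Gamma(5/2)\,E_m/E_N)^{2/3}$; the family-wise corrected p is
  $1 - e^{-E_m P(n\ge k)}$.
* **Permutation** (`permutation_cluster_correction`, `mdmr_cluster_perm`):
  each permutation's F map is converted to a Z map through pooled per-voxel
  permutation ranks, clustered identically, and the maximum cluster sizes
  form the null.

Smoothness for GRF is estimated from standardized residual maps via the
lag-1 spatial autocorrelation under a Gaussian ACF,
$\mathrm{FWHM}_{vox} = \sqrt{-2\ln 2 / \ln \rho_1}$, which is exact for
Gaussian-smoothed white noise; $\rho_1$ is floored at $e^{-8\ln 2}$
(FWHM $\ge 0.5$ voxel) so unsmoothed noise yields a finite sub-voxel
estimate. We chose the autocorrelation form over the derivative-variance
form because at FWHM $\approx$ 2 voxels the discrete-derivative estimate
biases upward by roughly 9% while the ACF form is unbiased in simulation.

**Which correction to use when.** GRF assumes a smooth stationary field.
MDMR Z maps computed from unsmoothed synthetic data violate that assumption
by construction, so the end-to-end synthetic validations use the
permutation path; GRF is validated separately on smooth Gaussian null
fields where its assumptions hold, and the two methods are required to
agree within a factor of two there.

A practical interaction between the permutation floor and the
cluster-forming threshold: with $n_{perm}$ permutations the smallest
attainable p is $1/(n_{perm}+1)$. At $n_{perm} = 1000$ that floor maps to
$Z = 3.09 < 3.1$, i.e. *no voxel can ever pass the cluster-forming
threshold*. Test-scale runs therefore use $n_{perm} = 1999$ (floor
$Z \approx 3.29$); the full-scale default remains 10,000.

## Post-hoc seed-based analysis and secondary statistics

MDMR flags *where* profiles covary with behaviour but not which connections
drive it, nor their sign. `sca_map` correlates a seed region's mean time
series with all mask voxels (Fisher-Z, r clamped at $\pm(1-10^{-7})$ before
`atanh`); `group_glm` fits the same design to the per-subject Z maps by OLS
and reports the interest column's t, converted to a signed Z through the t
CDF. Connection-level statistics follow: per-subject mean Fisher-Z over a
cluster (`extract_connection`), the Steiger-type Z test for two dependent
correlations sharing the connectivity variable (`corr_diff_test`, using the
back-transformed mean correlation variant; pinned to an independently coded
oracle at $10^{-8}$), the numeracy-minus-literacy discrepancy analysis with
the D'Agostino $K^2$ omnibus normality test (skew + kurtosis; matches an
independent reference implementation to $10^{-9}$ on frozen fixtures), and
connection cross-correlation matrices. Because it is unstated whether any
adjustment across connections is appropriate, the discrepancy table reports
raw and Bonferroni-adjusted p-values side by side.

## Temporal preprocessing

`preprocess_bold` applies, in order: grand-mean intensity normalization to
10,000; OLS nuisance regression (orthogonal-polynomial linear + quadratic
trends, the Friston-24 motion block $[m, m_{lag1}, m^2, m_{lag1}^2]$, and
five CompCor components — the top principal-component time series of a
designated noise region); band-pass filtering 0.01–0.1 Hz; optional 6 mm
FWHM Gaussian smoothing. The band-pass is zero-phase DFT masking: exact for
bin-aligned passband sinusoids, with the transition behaviour of a brick
wall in frequency (off-bin components leak as usual for finite windows);
any filter meeting the same frequency-response contract could be
substituted. Smoothing renormalizes by the smoothed in-mask kernel mass, so
constants are preserved and there is no attenuation at the mask boundary.
Framewise displacement uses the Power convention with rotations converted
to arc length on a 50 mm sphere (the radius is a parameter). In synthetic
data the CompCor noise region is a designated set of voxels outside the
analysis mask; anatomical tissue segmentation, registration and slice
timing are out of scope.

## The synthetic-data generator

Validation needs data where the ground truth is known. `generate_cohort`
draws literacy/numeracy standard scores from a bivariate normal with means
101.20 / 99.10, SDs 11.19 / 15.90 and correlation 0.44, rounded to
integers, plus clamped-normal age (30.76 ± 10.03, 20–49), Bernoulli sex
(P(female) = 44/70), handedness (77.36 ± 19.14, 50–100) and mean FD
(0.06 ± 0.02, 0.03–0.17) — the behavioural profile of a healthy-adult
community cohort assessed with WIAT-style tests.

`generate_timeseries` samples each subject's voxel time series from a
zero-mean Gaussian process with block covariance. Target and partner
regions load $\sqrt{w}$ on region latent signals ($w = 0.8$ within-region
correlation); the two latents are correlated so that the inter-region voxel
correlation equals $b + s\,z_{pheno}$ (baseline $b = 0.2$, slope $s$ per 1
SD of phenotype, $z$ clamped at $\pm 2.5$); background voxels share a weak
global latent (pairwise correlation 0.1) so that connectivity profiles are
never degenerate. Infeasible requests ($|b + s z|/w > 0.97$) are rejected
with the offending subject named, and `effect_spec` refuses
$|b| + 2|s| \ge 0.95$ outright.

Design rationale, fixed before any end-to-end validation was run:

* **Asymmetric regions** (27-voxel target, 100-voxel partner): a target
  voxel's profile changes across all 100 partner entries while a partner
  voxel's changes across only 27, so the MDMR peak is expected in the
  target region — making "peak inside target" a meaningful localization
  check rather than a coin flip between the two regions.
* **$w = 0.8$** because the latent correlation $(b + sz)/w$ must stay below
  1 across the design range $b \pm 2s$; smaller within-region correlations
  would make strong effects unrepresentable.
* **Effects enter deterministically** ($r_{sub}$ is an exact linear
  function of the phenotype); all between-subject noise in the recovered
  effect comes from finite-T estimation error. This makes power depend
  interpretably on T and V.

What the generator does *not* emulate: hemodynamics, physiological noise,
scanner drift, spatial autocorrelation of the noise, registration error,
and any realistic anatomical layout. Consequently, passing recovery tests
show the *inference machinery* is correct and calibrated — not that effects
of this size are detectable in real cohort data, where profile noise is
larger and spatially structured.

## Problem sizes and numerical choices

Test-scale runs use a 17 × 17 × 9 grid of 3 mm voxels with a 1575-voxel
interior mask, n = 60 subjects, T = 300 volumes at TR = 0.645 s, and
$n_{perm} = 1999$; null-calibration runs use 500 independent datasets on a
6 × 6 × 4 grid (32 mask voxels, one voxel scored per dataset, since the
binomial calibration summary assumes independent tests and voxels within a
run share subjects and permutations); FWER calibration uses 36 × 36 × 20
stationary smooth fields generated on a padded grid and cropped — the
search volume is kept large because the permutation max-cluster-size test
is conservative when cluster sizes concentrate on a few small integers, an
artifact of discreteness rather than of the correction itself. Full-scale parameters (whole-brain 3 mm masks, T = 900,
$n_{perm} = 10{,}000$) are plain function arguments. Other fixed choices:
p-values use the $+1$ counting convention (floor $1/(n_{perm}+1)$, never
$Z = \infty$; $p = 1$ maps to the documented floor $Z = -8.2$); cluster
peaks break Z ties (common at the permutation floor) by pseudo-F then by
lowest mask ordinal; mask ordinals are ordered lexicographically with the
last axis fastest; voxel indices are 0-based in the affine convention;
zero-variance in-mask voxels abort a run with a preflight report naming the
voxel rather than being silently excluded, since silent exclusion would
change profile length across subjects; sex is coded 0 = male / 1 = female
(any fixed coding only flips a nuisance sign).

## Known limitations

* Permutation inference treats subjects as exchangeable after
  residualization; family structure or site effects would need restricted
  permutation blocks, which are not implemented.
* The GRF approximations are asymptotic in smoothness and threshold height;
  at FWHM below ~2 voxels they are unreliable (which is why the permutation
  path exists and is the default for synthetic maps).
* Only a single variable of interest (m = 1) is supported, and only the
  $\sqrt{2(1-r)}$ profile distance.
* **Specificity under correlated phenotypes is bounded.** Because the
  generator links the inter-region correlation deterministically to one
  phenotype and the two achievement scores correlate 0.44, the companion
  phenotype inherits roughly 0.44 of any planted effect as a genuine,
  spatially contiguous association. At the strong-effect validation setting
  the effect-driving model detects its cluster in essentially every
  repetition, but the companion model also reaches cluster-level
  significance in a substantial minority of repetitions (the two-model
  suite measures joint specificity near 60%). This is a property of the
  study design — correlated phenotypes and a noiseless
  connectivity-behaviour link — not an inference error: each model tests
  its own marginal association, and the companion association is real.
  Users who need single-phenotype attribution should model the competing
  phenotype explicitly (e.g. as a nuisance covariate) rather than rely on
  marginal models.
* Whether smoothing should precede MDMR input preparation is left to the
  caller (`preprocess_bold(..., fwhm_mm = )`); both orders are defensible
  and the choice is recorded in the returned objects' parameters.

## A worked example

```{r example, eval = FALSE}
st <- simulate_study(n_subjects = 60, T_len = 300, slope = 0.2, seed = 42)
fit <- run_mdmr(st$ts, st$cohort, interest = "numeracy_ss",
                n_perm = 1999, seed = 7, keep_perm_f = TRUE)
fit
cl <- mdmr_cluster_perm(fit, z_thresh = 3.1)
cl$clusters
mdmr_peak(fit) %in% st$effect$target_region
```
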