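---
title: "Models and methods behind TNTsuppress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind TNTsuppress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TNTsuppress)
```

TNTsuppress implements the analysis machinery used to ask whether suppressing
an unwanted memory also suppresses the emotion attached to it. In a
Think/No-Think (TNT) experiment, participants learn cue-target pairs (here,
face cues paired with negative or neutral scenes) and are then repeatedly
shown cues with the instruction either to retrieve the associated scene
(Think) or to keep it out of awareness (No-Think). After every trial the
participant reports whether the scene entered awareness (never / briefly /
often); afterwards, affective ratings and recognition speed are collected for
No-Think, Think, and withheld Baseline items. The package covers the full
chain from trial-level scoring to multivariate brain-behavior analysis and
effective-connectivity modelling, and ships a synthetic-cohort generator with
known ground truth so that every stage can be validated end to end without
any subject data.

## The synthetic cohort

`designSpec()` encodes the scanning design: 24 subjects, 5 sessions of 2
repetitions of 16 Think + 16 No-Think cues (8 per valence), 3 s cues with
0.5-8 s jittered inter-trial intervals, and 8 Baseline pairs per valence
withheld from the TNT phase. The defaults give 160 trials per instruction
condition per subject (80 No-Think trials per valence) and 48 critical pairs.

`generateBehavior()` draws, per subject, a latent pair (intrusion tendency
$m_p$, affect aptitude $a_p$) from a standard bivariate normal whose
correlation is the *planted* cross-subject association between intrusion
control and affect suppression. A No-Think trial in session $s$ intrudes with
probability

$$\Pr(\text{intrusion}) = \operatorname{logit}^{-1}\!\big(\beta_0 -
\beta_1 (s - 1) + m_p\big),$$

with defaults $\beta_0 = -0.2$ and $\beta_1 = 0.25$: intrusions start near
45% and decline with practice to roughly 25%, averaging about 0.35 — the
range reported for this paradigm. Intruding trials are labelled "briefly" or
"often" (the analysis only uses the binary collapse, so the split is
inconsequential downstream); the label distribution of real single-trial
reports is not documented anywhere we know of, so the logistic
parameterization is a modelling choice, not an empirical claim. SAM valence
ratings are integers 1-9 built as item norm + condition effect + Gaussian
noise, rounded and clipped; item norms are truncated Gaussians matching the
published picture-set statistics (negative scenes mean 2.8, SD 1.7; neutral
5.9, SD 1.7). The condition effect adds `affect_effect_size` $\times\ a_p$
SAM units to negative No-Think items, which is what plants the
intrusion-affect correlation. With the defaults (effect size 1.0 SAM units
per SD, trial noise SD 0.6) the realized cross-subject correlation retains
about 85% of the planted latent value — e.g. a planted $\rho = -0.8$ yields
sample correlations near $-0.7$ at $n = 200$ — which we verified once by
simulation and then froze. Recognition RTs are log-normal (median 1400 ms,
sdlog 0.25) with a configurable No-Think slowing (defaults 130 ms negative,
10 ms neutral).

`generateBrain()` plants rank-1 brain-behavior structure:
$X = c\, s v^\top + E$, where the subject score $s$ is (standardized affect
suppression − standardized intrusion proportion)/$\sqrt 2$, $v$ is a
unit-norm salience vector positive over a block of control (MFG) voxels and
negative over medial-temporal blocks, and $E$ is iid Gaussian. The
documented signal-to-noise setting is `signal_scale = 3` with
`voxel_noise_sd = 0.1` over 2000 voxels (202 of them carrying signal), at
which the acceptance studies measure salience recovery and BSR error rates.
What these synthetic data deliberately do *not* emulate: spatial
autocorrelation and smoothing, physiological noise structure, registration
error, or item-level brain variance. Passing recovery tests therefore shows
the estimators are correct and well calibrated under their assumptions — not
that real fMRI data meet those assumptions.

All randomness flows from one cohort seed through documented per-stage,
per-subject substreams, so stages are independently reproducible.

## Behavioral scoring

Intrusion reports collapse to binary ("briefly"/"often" = intrusion,
"never" = none; "frequent" is accepted as a synonym of "often"). The
intrusion proportion is a two-level average — mean over the items of each
repetition, then mean over repetitions — which equals the flat trial mean
when every repetition has the same number of valid trials. Missing reports
are dropped from both numerator and denominator of their repetition, never
imputed; a repetition with no valid trials is omitted with a warning.

Valence ratings are adjusted as the dimensionless ratio rating/norm. We read
"relative to the normative value" as a ratio rather than a ×100 percentage
because published condition means for this adjustment sit in the 0.76-1.16
range. Outlier trimming removes items more than 2 MAD units from the
condition median (MAD = 1.4826 × median absolute deviation, the
normal-consistent scaling), in a single pass, separately per condition per
subject; when the MAD is zero nothing is trimmed. By default ratings are
adjusted first and the adjusted values trimmed (configurable; the original
ordering is not documented anywhere). The affect suppression score is mean
adjusted No-Think minus mean adjusted Baseline rating — positive values for
negative scenes mean reduced negativity after suppression. RT suppression is
the analogous No-Think − Baseline difference of trimmed recognition RTs.
The median split on intrusion proportion breaks ties by subject identifier,
so it is deterministic; subjects with fewer than 4 intrusive trials (5% of
80) in any valence condition are excluded before brain-behavior analyses.

## Skipped correlations and the item-split control

Bivariate outliers are detected by the projection rule: an MCD estimate of
the bivariate center, projection of all points onto the lines through the
center and each data point, and flagging of any point whose MAD-normalized
distance from the projection median exceeds $\sqrt{\chi^2_{0.975,2}}
\approx 2.72$ on any projection. The skipped correlation is Pearson's r on
the retained pairs; with no flags it equals plain Pearson exactly.

Calibration of the inference needed care. The projection rule flags at least
one point in most samples of size 22 even for clean bivariate normal data,
and a percentile bootstrap that resamples the retained pairs with the outlier
set held fixed inherits that selection: its null rejection rate at nominal
95% runs several times above 5% (the test suite asserts this property).
Re-running the detection inside every bootstrap draw swings to the opposite,
conservative extreme, partly because bootstrap duplicates shrink the
projection MAD — we correct that by estimating the projection scale on the
distinct values of each draw, which restores the draw-level flagging rate to
that of the original sample, but the interval remains conservative. Neither
percentile variant is calibrated for this hard-selection estimator, which is
why the package separates the two roles:

* the **significance decision** at the 95 level uses the robust t-statistic
  $T = r\sqrt{(m-2)/(1-r^2)}$ on the $m$ retained pairs against the
  simulation-calibrated critical value $6.947/n + 2.3197$ — the published
  convention for projection-based skipped Pearson correlations. Measured on
  1000 null datasets at $n = 22$ this rejects at ≈6-7%.
* the **reported interval** is the strict percentile bootstrap
  (detection re-run per draw, duplicate-corrected scale), which is
  conservative by construction and never anti-conservative.

Bonferroni-corrected CI levels are $100(1 - \alpha/k)$ to one decimal (99.6
for twelve comparisons); the Šidák variant is attached as an attribute
because published levels occasionally match neither convention.

The item-split control asks whether the intrusion-affect correlation
survives when the two measures come from disjoint item sets: per iteration,
each subject's No-Think items are randomly halved (larger half to the sample
set when odd); the intrusion proportion is computed from the sample half and
the affect suppression score from the test half (against the full Baseline
mean); the skipped correlation across subjects is recorded; and the 1000
iteration correlations are summarized by their mean and a percentile
interval over the iteration distribution (summarizing the split distribution
by its percentile interval is our design choice).

## Behavioral PLS

Given the subjects × voxels contrast matrix $X$ and subjects × measures
matrix $Y$ (intrusion proportion, affect suppression), both tables are
column mean-centered and each subject's voxel vector is scaled to unit sum
of squares. Centering-then-normalizing leaves columns slightly de-centered
(O(1/voxels)); the alternative rows-first order is available, and both are
tested. $Y$ columns are additionally scaled to unit variance by default, so
the cross-block matrix $R = Y^\top X$ is correlation-like. The thin SVD
$R = U \Delta V^\top$ yields behavioral saliences $U$, voxel saliences $V$,
and singular values ranking latent variables (LVs) by cross-block covariance
($\sum_k \sigma_k^2 = \lVert R\rVert_F^2$ is asserted to machine precision).
Signs are fixed by making each LV's largest-magnitude behavioral salience
positive. Brain scores are $X'V$ — the printed convention "$X^\top V$" is
dimensionally inconsistent for a subjects × voxels $X$, so the projection
$X'V$ is implemented.

LV significance uses permutations of the rows of $Y$ with full
re-preprocessing and re-decomposition, compared rank-matched (k-th permuted
singular value against k-th observed, no re-rotation), with the
add-one-smoothed $p = (1 + \#\{\text{exceed}\})/(1 + n_{perm})$. Voxel
stability uses subject bootstrap: each resample is re-preprocessed and
re-decomposed, aligned to the original by per-LV sign (dot product; full
orthogonal Procrustes alignment is available), and the bootstrap standard
ratio BSR = original salience / bootstrap SE is thresholded at |BSR| > 1.96.
An SE floor of 1e-12 guards noise-free inputs whose bootstrap SE collapses;
single-subject degenerate resamples are redrawn.

## The DCM engine

Neural dynamics follow the bilinear state equation
$\dot z = \big(A + \textstyle\sum_j u_j B^{(j)}\big) z + C u$, integrated
with classical RK4 on the input grid (dt ≤ 0.1 s; inputs are boxcars aligned
to the grid, held constant within a step; the integrator lives in C++ and is
checked against closed forms and half-step references). Observation is by
convolution with the canonical double-gamma HRF sampled at TR = 2 s, with
iid Gaussian noise. A fixed linear observation kernel replaces a biophysical
hemodynamic model deliberately: the scientific claims the engine addresses
concern the signs and family identity of neural coupling parameters, for
which a known linear map keeps estimation fast, convex-ish and testable;
parity with nonlinear hemodynamic models is a non-goal. Neural states are
block-averaged to a 0.5 s grid before convolution (the HRF is smooth at that
scale), which changes simulated BOLD by far less than the observation noise.

The model space follows a two-family organisation. All models share a fully
bidirectional intrinsic backbone among MFG, parahippocampal cortex (PhC),
hippocampus (Hip) and amygdala (Amg) — MTL-internal bidirectionality is the
documented constraint, MFG↔MTL bidirectionality is our stated assumption —
with the task driving input entering MFG. The modulatory family says *how*
No-Think epochs act: bottom-up (MTL→MFG), top-down (MFG→MTL), bidirectional,
afferent (extra driving input to the targets, no modulation; joint entry to
all targets), or null. The regulation family says *where*: Emotion (Amg
only), Memory (Hip, PhC, or both), or Parallel (Amg plus memory regions).
The enumerable grid is 4 types × 7 target subsets + null = 29 models.
Published analyses of this paradigm sometimes quote larger counts that are
not derivable from this grid (e.g. afferent variants per input); the builder
is configuration-driven so such readings can be expressed, and no attempt is
made to force any particular count. The top-down subfamily (top-down + bidirectional)
contains 14 models, partitioned 2/6/6 into Emotion/Memory/Parallel.

Estimation is MAP under Gaussian priors (mean −0.5 Hz on self-connections, 0
elsewhere; variance 0.25 on allowed couplings) and iid Gaussian observation
noise with per-region variance estimated jointly, via Gauss-Newton with a
forward-difference Jacobian and step halving; unstable proposals
(non-negative real eigenvalue of $A$) are rejected during the line search.
Convergence is declared when the free energy moves by less than 1e-4 on
three consecutive iterations, within a 128-iteration budget (reduced budgets
are used for the large validation sweeps; the fits there converge in well
under 30 iterations). The free energy is the Laplace approximation
$F = \log p(y\mid\hat\theta) + \log p(\hat\theta) + \tfrac p2 \log 2\pi +
\tfrac12 \log\lvert\Sigma_{post}\rvert$ with
$\Sigma_{post} = (J^\top W J + \Sigma_0^{-1})^{-1}$.

Random-effects model selection estimates the Dirichlet posterior over model
frequencies by iterating responsibilities
$g_{nk} \propto \exp(F_{nk} + \log\alpha_k - \log\sum\alpha)$ and
$\alpha_k = \alpha_{0k} + \sum_n g_{nk}$; expected posterior probabilities
are $\alpha/\sum\alpha$ and exceedance probabilities come from ≥1e5 Monte
Carlo draws of the Dirichlet. The responsibility weight uses the posterior
*mean* frequency ($\log\alpha$) rather than the geometric-mean (digamma)
form: the two coincide for $\alpha \gg 1$ and under uniform priors, but under
the size-corrected family priors below the digamma form is winner-take-all at
small $\alpha$ — with identical evidence it funnels the entire cohort into
the largest-prior model, whereas exact inference (a constant likelihood)
leaves the prior untouched. The mean form preserves that exact symmetry and
is therefore used throughout. Family inference gives every family equal
prior mass ($\alpha_{0m} = 1/|\text{family}|$), aggregates sampled
frequencies within families, and reports the probability that each family's
summed frequency is largest. Bayesian model averaging weights each subject's
fitted matrices by their within-family posterior model probabilities
(absent couplings contribute zero). Coupling inference bootstraps subject
means of effective connectivity $A + B$ at the Bonferroni-corrected level
(99.6% for 12 parameters), with an optional rule excluding subjects deviating
more than 4 SD on any parameter.

## Validation studies and problem sizes

The packaged studies (`validate*()`) run at sizes chosen to make each
property measurable on a single CPU in minutes: PLS recovery at 22 subjects
× 2000 voxels with 500 permutations and bootstraps; permutation calibration
over 200 null datasets × 200 permutations (22 × 200 voxels); skipped-null
calibration over 1000 datasets at n = 22; item-split studies at 200 subjects
× 1000 iterations; DCM sign recovery over 20 two-region replicates;
family recovery over 20 replicate cohorts of 4 subjects × 80 scans, fitting
the 7 top-down models per subject. Larger sizes change none of the
qualitative conclusions, only the Monte-Carlo error.

## Known limitations

* The synthetic brain and time-series generators are intentionally simple
  (iid noise, fixed HRF, no spatial structure); they validate estimator
  correctness, not realism.
* The skipped-correlation CI is conservative (see above); significance uses
  the calibrated robust t-test at the 95 level only.
* The DCM engine is desk-scale: linear observation model, modest series
  lengths, and no stochastic or nonlinear extensions.
* Family inference with very small cohorts (n ≤ 4) relies on clear evidence
  gaps; with noisy, short series the Dirichlet posterior is diffuse.
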