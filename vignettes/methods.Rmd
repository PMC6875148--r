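---
title: "Identifying lateralized language networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lateralized language networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latnet)
```

latnet implements a two-part region-of-interest analysis of language fMRI
built on a *homotopic-pair* atlas: every region of interest (hROI) has an
exact counterpart in the other hemisphere, so a left-minus-right contrast is
meaningful region by region. Part 1 selects, per hemisphere, the hROIs that
are jointly activated and jointly asymmetric across three word-list tasks
(covert production, listening, reading). Part 2 measures the intrinsic
(resting-state) connectivity among the selected regions and partitions them
into networks by agglomerative clustering, with multiscale-bootstrap support
values attached to every cluster.

This vignette explains the statistical model at each stage, the tunable
parameters and their defaults, what the synthetic-cohort generator does and
does not emulate, and the numerical choices made where the underlying
methodology leaves the implementation open.

## Part 1: conjunction selection

For each homotopic pair, each task contributes two per-subject quantities:
the *activation* (the mean BOLD contrast over the voxels of the hemisphere's
member region, in BOLD % units) and the *asymmetry* (left mean minus right
mean; positive values are leftward for both hemispheres' analyses, so
rightward asymmetries are negative).

Each quantity is tested against zero with a one-sample t test,
$t = \bar{x} / (s/\sqrt{n})$ on $n-1$ degrees of freedom, two-sided, plus an
explicit sign requirement (the mean must have the hypothesized direction).
At a per-test level $\alpha = 0.05$ this behaves like a one-sided test at
0.025 — a deliberately conservative reading of "significantly positive".
A left-hemisphere hROI is selected when its left activation is significantly
positive **and** its asymmetry significantly positive in *all three* tasks;
right-hemisphere selection mirrors this with a negative asymmetry
requirement. Under independence, the nominal significance of the three-task
conjunction is $\alpha^3 = 1.25\times10^{-4}$, and of the conjunction of the
two criteria $(\alpha^3)^2 = 1.56\times10^{-8}$; the operational rule is the
per-test $p<\alpha$ conjunction, and the products are reported as nominal
thresholds (`conjunction_threshold()`).

Shrinking $\alpha$ is monotone (a region can only drop out), and a pair can
never be selected in both hemispheres on the same data because the two
asymmetry sign requirements are mutually exclusive. `count_selection_steps()`
tabulates how many pairs pass each criterion per task and for the three-task
conjunction; the `"table1"` scheme applies a Bonferroni per-contrast alpha
(0.05/184) as an alternative to the default `"methods"` scheme (0.05).
Because the published analysis describes three non-equivalent threshold
schemes in different places, the scheme is an explicit, named parameter
rather than a guess: the Methods-text rule is the default.

Degenerate inputs follow one convention worth stating: a zero-variance
sample with zero mean returns $t=0,\ p=1$ (an all-zero region is simply
never significant), while a zero-variance sample with nonzero mean is an
error, since $t$ is undefined there.

## Task profiles

The selected regions are characterized with repeated-measures linear
mixed-effects models (`fit_mixed_model()`): fixed factors Task, ROI and Side
with all interactions, a random intercept per subject, fit by REML
(`lmerTest`), with Satterthwaite denominator degrees of freedom. For the
asymmetry response the Side factor is dropped — the asymmetry *is* the side
contrast. Factors with a single level are omitted automatically, which makes
the two-task, one-region special case collapse to the paired t test (the
Task F statistic equals the squared paired t; this is tested to 1e-8). The
exact covariance structure and df method of the original JMP analyses are
not recoverable from their description, so numerical equality with published
F values is not claimed; Satterthwaite is the documented, configurable
choice here.

Pairwise task differences use two-sided Tukey studentized-range tests
(`tukey_pairwise()`): each region is fit as a randomized block
(value ~ task + subject), and the three task means are compared with
`ptukey` on the block-model residual df. The family is the three task means
within one region; a Bonferroni factor across regions is available as a
toggle but off by default. With two tasks the range test reduces exactly to
the paired t test.

## Part 2: intrinsic connectivity and networks

Resting-state region series (one series per selected hROI, the average of
its voxels) are preprocessed in the fixed order: (1) regression of nuisance
series (white-matter and CSF means), an intercept and a linear trend —
ordinary least squares residuals, exactly idempotent; then (2) a bandpass
filter in 0.01–0.1 Hz. Per-subject Pearson correlation matrices over the
regions are Fisher-z transformed (`atanh`), averaged across subjects, and
back-transformed: `group_mean_r = tanh(mean(atanh(r)))`. The order matters —
averaging raw correlations is biased on skewed inputs, and a test asserts
the two disagree where they should.

### The bandpass filter

The filter is a least-squares linear-phase FIR design, built in-package
(`design_bandpass_fir()`): Type I (odd length, even-symmetric coefficients),
fit by weighted least squares of the amplitude response
$A(f) = g_0 + \sum_k 2 g_k \cos(2\pi f k)$ on a dense frequency grid.
Desired amplitude is 0 on $[0, \mathrm{low}/2]$, 1 on
$[\mathrm{low}, \mathrm{high}]$ and 0 on
$[(\mathrm{high}+f_{Nyq})/2, f_{Nyq}]$; stopbands are weighted 30:1 over the
passband, and the transition bands enter with linearly interpolated targets
at weight 0.02 purely to condition the normal equations (a pure don't-care
design at this length is ill-conditioned and produces useless coefficients).
An exact DC zero is imposed as an equality constraint, so constant input is
removed to machine precision. The default length is 65 taps at TR = 2 s —
the longest odd length at or below a third of a 240-volume series — applied
with reflect padding by one filter length and the $(N-1)/2$-sample group
delay compensated, so output aligns with input. At these settings the
measured response has mid-band gain within [0.93, 1.04], ≤0.07 at 0.005 Hz
and ≤0.01 above 0.175 Hz.

One consequence worth knowing: preprocessing is *approximately* idempotent
only. The nuisance projection is exactly idempotent, but re-filtering
rescales in-band content by the passband gain again, so a second pass
changes the series by several percent RMS — an unavoidable property of any
realizable FIR, tested at a 15% bound rather than pretended away.

### Clustering and AU support

Networks come from agglomerative clustering of $d = 1 - \bar r$ with average
linkage (UPGMA) — the conventional choice for correlation dissimilarities;
complete and Ward linkage are available by argument, and clustering operates
on the back-transformed $\bar r$ (so $d \in [0, 2]$) rather than on z,
which is unbounded.

Cluster stability uses multiscale bootstrap resampling
(`multiscale_bootstrap_au()`). *Participants* are resampled — they are the
exchangeable units behind the averaged matrix — at ratios
$\rho \in \{0.5, 0.6, \ldots, 1.4\}$ of the cohort size, $B$ replicates per
scale (default 1000; the validation runs use 200). Each replicate averages
the resampled subjects' z matrices, reclusters, and scores every reference
node by whether its exact member set reappears, giving $BP(\rho)$. The AU
value extrapolates via the signed-distance/curvature probit model
$\Phi^{-1}(1 - BP(\rho)) = v\sqrt{\rho} + c/\sqrt{\rho}$, fit by weighted
least squares with binomial-delta-method weights
$B\,\phi(y)^2 / (BP(1-BP))$, and $AU = 1 - \Phi(v - c)$. Edge cases are
explicit: a node recovered in every replicate at every scale has
$AU = BP = 1$ ("certain"); a node never recovered has $AU = 0$
("never_recovered"); fewer than two informative scales, or a non-finite
fit, fall back to BP with a flag.

`cut_partition()` extracts networks either at a fixed count (`fixed_k = 2`
is the replication-mode default) or as the maximal AU-supported clusters
covering all regions (`au_threshold`), with uncovered regions becoming
singletons. Network summaries report per-network volume (sum of the
selected-side region volumes, voxel count × voxel volume), and for each
network pair the mean inter-network correlation $R$ (each subject's mean
over all between-network region pairs, averaged over subjects), the
fraction of subjects with a negative mean, and a one-sided exact binomial
sign test of that fraction, Bonferroni-corrected over network pairs. The
sign test is one-sided toward negativity because that is the direction of
interest for anticorrelated networks (the two-sided variant is available).

## The synthetic-cohort generator

Every stage is validated against cohorts with planted ground truth, because
the original cohort data are not redistributable. The generator's defaults
*are* the study conditions: 144 task subjects, 138 resting subjects, three
tasks, 185 homotopic pairs, 240 volumes at TR = 2 s; 14 planted left + 7
planted right regions forming two resting-state networks with within-network
correlation 0.5 and between-network correlation −0.05.

Task maps (`simulate_task_maps()`): voxel value = planted
(pair, task, side) effect mean + per-subject random intercept + i.i.d.
Gaussian voxel noise; background voxels are pure noise. Default effects put
0.40 BOLD % on a planted pair's dominant side and 0.15 on the other
(asymmetry 0.25), with voxel noise SD 0.35 and intercept SD half that —
chosen once so that across-subject SDs of region means (≈0.39 for
activation, ≈0.49 for asymmetry) and the resulting t statistics sit in the
range typical of group hROI analyses of word-list tasks. The subject
intercept is shared across regions, tasks and sides, inducing the
repeated-measures correlation the mixed model assumes; it cancels exactly in
the asymmetry.

Resting series (`simulate_resting_series()`): region series are drawn from
the block-structured correlation matrix implied by the planted partition
(positive-definiteness checked by Cholesky, with the offending correlations
named on failure), with AR(1) innovations (ρ = 0.3) for minimal temporal
realism, plus a per-region random linear drift and loadings on two smooth
nuisance series (white-matter-like and CSF-like). The drift and nuisance
terms are exactly the components the preprocessing stage removes; the
correlated signal survives filtering because identical linear filtering of
all regions preserves cross-correlation.

What the generator does **not** emulate: hemodynamic response shape, head
motion, physiological artefacts, spatial autocorrelation of voxel noise,
inter-regional distance structure, or any departure from Gaussianity.
Passing recovery tests therefore demonstrates that the pipeline's logic and
statistics are correct under the assumed model — not that the pipeline is
robust to real-data artefacts those tests do not contain.

## Validation experiments and problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) runs:

- *Selection recovery*: 100 task cohorts at full scale (144 subjects, 185
  pairs, single-voxel regions); exact recovery of both planted sets is
  required in ≥95 of 100 seeds.
- *Null calibration*: the per-test rejection rate at α = 0.05 over 10,000
  independent null regions of 144 subjects, required within 0.05 ± 0.01.
  The regions are drawn with the subject intercept disabled so the tests
  are independent and the binomial band applies; the intercept changes
  each test's variance, not its validity.
- *Clustering recovery*: 100 resting cohorts (138 subjects, 21 regions, 240
  volumes) through the full preprocessing path; the fixed-k = 2 partition
  must match the planted partition (adjusted Rand index 1) in ≥95 of 100
  seeds, and the AU of both planted networks must be ≥0.95 at B = 200 per
  scale.
- *Oracle equivalences*: region means vs a brute-force voxel loop (1e-12),
  average-linkage merges vs a naive O(n³) agglomeration on n ≤ 8 (exact),
  the AU probit fit vs an independent weighted refit (1e-8), nuisance
  residuals vs the normal equations (1e-10), and the FIR contract measured
  by FFT-bin amplitude ratios.

Single-voxel regions are used in the large selection runs: the region mean
of i.i.d. noise over v voxels is Gaussian with SD $\sigma/\sqrt{v}$, so
region size only rescales the noise, and the per-voxel path is exercised
separately on multi-voxel atlases.

## Known limitations

- Published cohort-specific results (which particular hROIs are selected,
  the exact network memberships, published F and AU values) depend on the
  original data and are not reproduced; the package reproduces the
  *procedure* and its arithmetic anchors.
- The mixed-model df method (Satterthwaite) is a documented choice, not a
  claim about the original software's internals.
- The AU model is asymptotic in B and in the scale range; with very small
  B or clusters at the edge of stability the fallback-to-BP path can
  trigger, and is flagged when it does.
- The FIR transition band (0.005–0.01 Hz) is narrower than a 65-tap filter
  can fully resolve; the stated contract (mid-band gain, stopband bounds,
  DC zero) is what is guaranteed and tested.
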