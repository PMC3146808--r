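---
title: "Pathway-activity signatures across fresh-frozen and FFPE profiles: models and design"
author: "pathsig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-activity signatures across fresh-frozen and FFPE profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsig)
```

# Scope

`pathsig` implements a complete pathway-activity analysis for two-class
expression designs: signature construction (probe selection, SVD metagenes,
Bayesian probit regression by Gibbs sampling), posterior activity
prediction for new samples under several normalization schemes, array QC
metrics, matched/unmatched concordance analyses for paired
fresh-frozen/FFPE designs, and a synthetic-data generator that emulates
such a study end-to-end with known ground truth. This vignette documents
the models, the tunable parameters and their defaults, the numerical
conventions, and — because several design points were genuinely open — the
reasoning behind the choices made.

# The signature model

## Probe selection

Given a training matrix of positive linear-scale intensities (probes ×
samples) and a two-class design (control versus oncogene-perturbed
replicates), probes are ranked by the absolute pooled-variance two-sample
*t* statistic on log2 intensities and the top `nProbes` are kept. A floor
of $10^{-6}$ is added to the pooled SD so that a pathological zero-variance
probe produces a large finite statistic rather than NaN; ties are broken by
probe id, lexicographically, so selection is deterministic. The statistic
is the most reproducible default for this family of signatures; the
signature size is a free parameter (published signatures of this type use
anywhere from 200 to 500 genes; the simulated study uses 150, matching the
number of truly perturbed probes per pathway).

## Metagene factors

The selected submatrix is log2-transformed and centered per probe (the
means are retained). Its rank-$k$ truncated SVD $X \approx U D V^\top$
yields the metagene *loadings* $U$ (probes × $k$, orthonormal columns) and
training *factor scores* $F = U^\top X = D V^\top$ ($k$ × samples). The
sign of each loading column is fixed so that its largest-magnitude element
is positive, which makes signatures reproducible across linear-algebra
backends. $k$ defaults to 3: with 14–16 training samples, a small number
of factors captures the perturbation axis (factor 1, typically) plus the
dominant nuisance structure while keeping the regression well conditioned.

## Bayesian probit regression

Class labels are modelled as $P(y_i = 1 \mid f_i) = \Phi(\alpha + \beta^\top
f_i)$ with independent $\mathcal N(0, \sigma_0^2)$ priors on $\alpha$ and
each $\beta_j$. The posterior is sampled with the Albert–Chib
data-augmentation Gibbs sampler: latent $z_i \sim \mathcal N(\alpha +
\beta^\top f_i, 1)$ truncated to $(0,\infty)$ for $y_i = 1$ and
$(-\infty,0]$ for $y_i = 0$, followed by a conjugate multivariate-normal
draw of $(\alpha,\beta)$. Truncated normals are drawn by a log-space
inverse CDF, which remains exact even when the linear predictor is
hundreds of units from the truncation point — routine here because the
training classes are typically linearly separable in factor space.

Defaults: 11,000 iterations, 1,000 burn-in, a mandatory seed (fits are
bit-reproducible), and a Geweke diagnostic that warns (never fails) at
$|z| > 3$. The prior SD defaults to 1. This is a deliberate choice: with
separable training data a nearly flat prior (for example SD 10) lets
$\beta$ drift to the prior's scale, and every prediction saturates at 0 or
1. Saturated probabilities make downstream probability *differences*
binary, which defeats threshold-based concordance rules; the unit prior
keeps the posterior predictive calibrated (training samples score ~0.98 /
~0.02 rather than 1.0 / 0.0) without affecting rankings. The sampler
itself accepts any prior SD, and the package's oracle test validates it
against a dense 2-D quadrature of the exact posterior under a wide prior.

## Predicting new samples

A test sample is normalized against the training statistics, projected
onto the loadings ($\hat f = U^\top \tilde x$), and scored by the posterior
mean of $\Phi(\alpha + \beta^\top \hat f)$ over the stored draws, with a
95% credible interval from the per-draw probabilities. Three
normalization modes are provided because "normalized investigational
samples" is underdetermined for archival material:

* **standardize** — per-probe z-score against training mean and SD, mapped
  back onto the training spread (algebraically: the training-mean-centered
  log2 value). Exact on training samples; appropriate when test arrays
  come from the same protocol and are undamaged.
* **arrayscale** — each array is rescaled by one multiplicative constant so
  its mean log2 deviation from the training per-probe means is zero (the
  log2 analogue of MAS5 global scaling to a common target). With an
  `absentThreshold`, only probes called present enter the estimate, so a
  background floor cannot drag it, and absent signature probes are imputed
  at the training mean — centered value zero — so an undetected probe
  contributes no evidence for either class. This is the default in the
  end-to-end pipeline: degraded FFPE arrays lose several log2 units
  globally, which per-probe standardization misreads as biology.
* **quantile** — the sample's signature-probe values are replaced by
  pooled-training quantiles at their within-sample ranks; invariant to any
  monotone transform of the test sample.

The absent-call imputation deserves a note. Degraded arrays floor a large
fraction of probes at background. Keeping floored values in the projection
drags every damaged sample toward whichever class happens to look "low";
dropping them and re-estimating factors by least squares on the surviving
loading rows overcorrects in the other direction, because survival is
correlated with the probe's value (a selection effect). Mean imputation is
the symmetric middle ground: damaged samples shrink toward the factor
origin — toward an uninformative probability — rather than toward either
class. This matches the intuition that an array with little surviving
signal should produce an uncertain prediction, not a confident wrong one.

# The QC metrics

* **Percent present**: fraction of probes above a detection threshold
  (default 60, twice the simulator's background level). A plain intensity
  cutoff stands in for the MAS5 Wilcoxon detection call, which needs
  probe-level PM/MM data that summarized matrices no longer carry; the
  metric keeps its comparative meaning.
* **Scaling factor**: `target / trimmedMean` with target 500 and symmetric
  2% trimming — the closest standard reading of the MAS5 convention.
* **3′/5′ ratio**: intensity ratio of the 3′ to the 5′ control probe of
  β-actin- and GAPDH-style control pairs; values above 3 conventionally
  flag degraded RNA, because reverse transcription initiates at the 3′
  end of a transcript.
* **Distribution summary**: log2 of the 5th/25th/50th/75th/95th intensity
  percentiles divided by the array's scaling factor (the array box-plot
  statistic). Percentiles use linear interpolation between order
  statistics (`quantile` type 7), pinned so tests can be exact.

Average background is *not* computed: it requires probe-level background
estimation outside the scope of summarized matrices.

# Concordance machinery

Whole-genome agreement between two sample sets is measured by Pearson
correlation of log2 intensities over all shared probes, split into
*matched* (same tumor, linked by `pair_id`) and *unmatched* (all other
cross combinations — including same-line non-pairs, since excluding them
is an undocumented choice we avoid). P-values for prediction scatter use
the exact *t* transform of Pearson's r with $n-2$ degrees of freedom.

Clustering follows the Cluster 3.0 recipe: keep the 1,000 probes with the
highest across-sample log2 SD (ties by probe id), center genes then arrays
in a single pass, and agglomerate samples by average linkage on distances
$1 - \text{uncentered correlation}$ (the cosine-like similarity without
mean subtraction). Columns are pre-sorted lexicographically so merge order
is deterministic under ties; heights are clipped to $[0,2]$. PCA operates
on the probe-centered log2 matrix via SVD.

Patient-level concordance applies the rule used for in-transit melanoma
lesions: a patient is concordant when the FFPE lesion's predicted
probability differs by at most 0.3 from *at least one* of the patient's
fresh-frozen lesions (the minimum absolute difference). The mean absolute
difference is reported alongside because the two summaries genuinely
disagree in edge cases — a patient can be concordant by the minimum rule
while the mean difference exceeds 0.3. Rates are rounded to the nearest
integer percent (5 of 6 → 83%).

# The synthetic study generator

The generator exists so that every stage is testable against known ground
truth. It emulates, at reduced scale, a three-part design: perturbation
training sets (8 control vs 8 RAS, 8 vs 6 MYC replicates), 25 paired
fresh-frozen/FFPE xenografts from 5 tumor lines × 5 mice, and 6 patients
with 3 fresh lesions plus 1 FFPE lesion each, all sharing one probe
universe so signatures transfer across data sets.

## Expression model

Probe base abundances are $\log_2$-normal, $\mathcal N(7, 2)$. The SD of
2 reflects the dynamic range of MAS5-scale arrays, whose 5th–95th signal
percentiles span roughly seven log2 units; it also makes probe-abundance
variance dominate whole-genome correlations, so that correlations between
unrelated fresh-frozen profiles land in the low 0.9s, as observed between
arrays of distinct tumor lines. On top of the base abundance: a
line/patient baseline shift (SD 0.3 — between-group biology), a
per-replicate shift (SD 0.3 — tumor-level biology and assay), and, for
re-amplified aliquots of the same RNA, assay noise of SD 0.15.

Each pathway owns 150 dedicated probes, uniformly up-regulated by the
effect size (2.0 log2 units) in perturbed/active samples. Latent activity
is binary, fixed per line or patient, and balanced so both classes occur.
The universe is 10,000 probes by default — large enough that the two
signatures (3% of probes) do not dominate whole-genome correlations, as
they must not, since on a real 22k-probe array they are ~2%.

Two control probe pairs (β-actin- and GAPDH-style) are always present at
high abundance. Both members of a pair read the same transcript, so their
abundance noise is common-mode within the pair; only a small probe-set
measurement term (shrunk by $\sqrt{11}$, the number of probe pairs a real
control summary averages) differs between the 3′ and 5′ members.

## Degradation model

FFPE degradation acts multiplicatively on the linear scale:

1. **Probe susceptibility**: each probe draws a log2 attenuation from a
   normal with mean 2.0 and SD 1.0, truncated at 0 (degradation never
   amplifies). The draw is shared across samples — a probe either measures
   degraded material tolerably or it does not, consistently from array to
   array — which is what makes FFPE arrays resemble *each other* and
   cluster apart from fresh-frozen ones.
2. **Severity**: each array draws a log-normal severity multiplier
   (log-SD 0.15) scaling all its losses, producing the block-to-block
   spread of QC metrics seen on real FFPE series.
3. **Noise**: every cell gains $\mathcal N(0, 0.5)$ log2 noise (controls:
   shrunk by $\sqrt{11}$).
4. **Dropout**: the weakest 35% of degraded log2 signals collapse to a
   jittered background level (30 linear units, jitter ±0.5 log2). Dropout
   is abundance-dependent by construction — low-abundance and
   highly susceptible probes fall first — because a detector loses weak
   signals before strong ones. An i.i.d. dropout alternative was rejected
   during calibration: it maps both classes' signature probes to the same
   background value, erasing exactly the class contrast that real FFPE
   predictions demonstrably retain. The marginal dropout probability still
   equals the configured rate.
5. **Controls**: control pairs receive the deterministic mean attenuation,
   no dropout, and the 5′ member loses an extra 3.0 log2 units (times the
   array's severity), so the geometric-mean 3′/5′ ratio of a unit-severity
   array is $2^3 = 8$ and essentially all simulated FFPE arrays exceed the
   quality cutoff of 3.

With all attenuation, noise and dropout parameters zero, the transform is
the identity (bit-exact), which anchors the degradation tests.

These defaults were calibrated — before the package's acceptance tests
were written — against the qualitative behavior of real paired FFPE
series: FFPE percent-present inside the 8.67–49.7% envelope reported for
degraded FFPE arrays, under the 2×-background detection rule, all 3′/5′ ratios above 3, scaling
factors exceeding every fresh-frozen partner's, matched whole-genome
correlation no higher than unmatched after degradation, clustering driven
by preservation type, and pathway predictions that survive. Attenuation
mean 2.0 (rather than a smaller value) keeps the percent-present ceiling
inside the envelope; the between-group SD of 0.3 places unrelated-line
correlations near values reported for distinct tumor lines.

## What the generator does not emulate

No probe-position-resolved degradation (fragment-length effects along the
transcript beyond the single 5′ control term), no batch effects other than
the FF/FFPE contrast, no missing values, no probe-level (PM/MM) structure,
and binary rather than graded pathway activity. Passing tests therefore
show that the *machinery* behaves correctly under a faithful statistical
caricature of the study — they do not certify performance on real arrays,
where probe effects, cross-hybridization and batch structure are richer.

# Numerical conventions

* Intensities are exchanged on the linear scale and must be strictly
  positive; log2 is applied transiently inside analyses. Missing values
  are not supported anywhere.
* TSV round trips are exact: matrices are written at 17 significant
  digits; the reader accepts scientific notation and preserves ordering.
  Signature JSON files round-trip to within 1 ulp.
* All ranking ties (probe selection, SD filter) break lexicographically by
  probe id; SVD loading signs are fixed as described; `hclust` input
  columns are pre-sorted so dendrograms are reproducible.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state. Pipeline stages derive sub-seeds by hashing the
  master seed with the stage name (always below $2^{31}$), so stages can
  be re-run in isolation and the whole pipeline is byte-identical across
  reruns.
* Monte-Carlo comparisons in the test suite use batch-means standard
  errors; the SE of a posterior SD uses the delta method on first and
  second moments, since within-batch SDs are biased low for slowly mixing
  chains.

# Problem sizes in the test suite

Unit tests run the generator at 500 probes to keep the suite fast;
acceptance-style end-to-end tests use the default study conditions (10,000
probes, 150-probe signatures, full MCMC) across 5–10 seed replicates, with
the sampler-versus-quadrature oracle on a fixed 6-sample toy problem.
These sizes were chosen so that the full suite exercises every code path
at the default conditions while remaining comfortable to run locally.

# Known limitations

* The probit sampler mixes slowly when training classes are separable and
  the prior is nearly flat; posterior *summaries* are still correct (the
  oracle test covers exactly this regime) but effective sample sizes drop,
  and the Geweke warning fires. The default unit prior avoids the regime
  in routine use.
* `arrayscale` normalization assumes the test matrix carries (most of) the
  training array's probes; applying it to a signature-only submatrix is an
  error by design.
* The patient concordance rule depends on calibrated probabilities;
  saturated classifiers make it trivially binary. See the prior
  discussion above.
* Dendrograms use `stats::hclust`; merge heights equal average distances,
  and the Newick export encodes branch lengths as height differences via
  `ape`.
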