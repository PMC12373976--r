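---
title: "Methods: compartment-stratified DSP analysis across differentiation grades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-stratified DSP analysis across differentiation grades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspgrade)
```

This vignette explains the statistical machinery of `dspgrade`: the
models and rules each stage applies, the parameters that matter and
why they default to what they do, what the synthetic cohort generator
does and does not emulate, and the numerical conventions used at edge
cases.

## Data model

The unit of measurement is the AOI — one compartment (EP, epithelial;
MA, macrophage; ST, stromal) of one ROI on one patient's section.
Counts form a genes × AOIs matrix with a companion negative-probe
matrix measuring technical background. Differentiation grade (well,
moderate, poor) attaches to each AOI; whether it comes from the ROI's
dominant histology or a per-AOI call is left to the data producer —
the schema carries it per AOI. Survival (time in months, recurrence
indicator) attaches to patients.

## QC cascade

An AOI fails technical QC iff `alignment_rate < 0.8` **or**
`ntc_count > 1000` **or** `nuclei < 100`. All rules are strict
inequalities on the failing side, so boundary values (alignment
exactly 0.8, NTC exactly 1000, exactly 100 nuclei) pass. All violated
reasons are recorded, in the fixed cascade order alignment → NTC →
nuclei → contamination; the order affects only reason attribution,
never the retained set.

The negative-probe background is summarized per AOI as a geometric
mean computed with a +1 offset (so all-zero probes are defined), and
the detection floor is `max(4, geomean)` — the floor of 4 counts is
the platform's conventional minimum and is configurable
(`negprobe_floor`). A gene is *detected* in an AOI when its count
reaches the floor; genes detected in fewer than `min_detect_fraction`
(default 0.1, boundary inclusive) of retained AOIs are dropped. The
0.1 retention fraction is a conventional choice, exposed in the
config.

Q3 normalization computes each AOI's 75th percentile over its
*detected* genes with the linear-interpolation percentile definition
(R's type 7), and scales by `geomean(Q3)/Q3(a)`. After scaling, every
AOI's detected-gene Q3 equals the cohort geometric mean exactly; a Q3
of zero is an error that points back to QC rather than being patched
silently. Rescaling one AOI's raw counts by any c > 0 changes the
normalized matrix only through the global geometric-mean reference.

### Epithelial contamination

Each AOI gets an epithelial score: the ssGSEA enrichment of an
epithelial marker set (at least 3 panel members required), min–max
rescaled to [0, 1] across the run's AOIs; a degenerate constant run
scores 0 everywhere. MA/ST AOIs with score strictly above
`contamination_thr` (default 0.05) are removed; EP AOIs are never
removed by this rule. The 0.05 default matches the convention of
score-based contamination calls but is *scale-dependent* — it is
meaningful only because pure non-epithelial AOIs sit near 0 on the
rescaled scale. A `data_driven` mode instead places the threshold just
below the minimum EP score, the calibration logic one would use when
the score scale is unknown.

## Grade-trend classification

Differential expression between two grade groups within one
compartment uses the Wilcoxon rank-sum test (exact null when the
pooled size is ≤ 20 and tie-free; otherwise the normal approximation
with midrank tie correction and continuity correction) and a mean-log2
fold change `mean(log2(B+1)) − mean(log2(A+1))`. The +1 pseudocount is
there because zeros are expected in DSP counts; screening significance
is `|logFC| > 1` and `p < .05`, with BH adjustment reported alongside.

The trend classifier runs the three pairwise comparisons well–moderate,
moderate–poor and well–poor. A gene is *eligible* when p < .1 in at
least two of the three (raw p by default; a config switch applies the
rule to BH-adjusted p instead). Among eligible genes the two
adjacent-grade signs decide the label — (+,+) P1, (−,−) P2, (+,−) P3,
(−,+) P4 — and the long-span well–poor comparison acts as a
consistency veto for P1/P2 only: when it is itself significant, its
sign must match the shared adjacent sign, otherwise the gene is left
UNCLASSIFIED. This is the weakest reading that uses all three
comparisons: the adjacent signs fully determine the four monotone /
peaked shapes, while the long-span comparison can only contradict a
monotone claim. A zero adjacent logFC (no direction) is UNCLASSIFIED.

Two caveats are worth stating. First, multiple AOIs from one patient
enter the rank tests as independent observations; no patient-level
random effect is applied, so p-values are anti-conservative to the
degree that within-patient AOIs correlate. Second, the rank tests'
discreteness at small group sizes makes the p < .1 eligibility rule
conservative for groups under ~5 AOIs.

## ssGSEA

For one AOI, genes are ranked by descending expression with ties
broken by gene-id order (a deterministic convention; the method's
usual description leaves ties open). With rank weight
`r_i = N − pos + 1` and exponent α (default 0.25):

$$ES = \sum_{i=1}^{N}\left[\frac{\sum_{g \in S,\ pos(g)\le i} r_g^\alpha}
{\sum_{g\in S} r_g^\alpha} - \frac{\#\{g \notin S,\ pos(g) \le i\}}{N - |S|}\right]$$

Scores over a collection are optionally divided by the global
(max − min) range of the whole matrix — the method's conventional
normalization; it preserves within-set rankings exactly. A set that
covers the whole panel is rejected (the out-of-set ECDF is undefined).
Because the statistic depends on expression only through ranks, any
strictly monotone transform of an AOI's profile leaves its scores
unchanged.

Over-representation p-values are upper-tail hypergeometric,
`P(X ≥ k)` for overlap k between query (n) and set (m) within universe
(N), BH-adjusted across sets.

## Paired compartments

Within each ROI that retains at least one EP and one MA AOI, duplicate
same-compartment AOIs are averaged on the log2(x+1) scale — the
least-assumptive symmetric aggregation — and a gene set is reduced to
its mean log2 expression. Across ROIs the EP-side and MA-side values
are correlated by Spearman's rho (Pearson on midranks). The p-value is
an exact two-sided permutation p (all n! orderings) for n ≤ 9 and the
t-approximation `t = rho·sqrt((n−2)/(1−rho²))` otherwise. Spearman is
the default because set-mean expressions are not bivariate normal at
ROI scale; Pearson is selectable. Zero variance on either side is an
error, not a silent NA.

## Deconvolution

The reference is a signature-genes × cell-types matrix; fractions for
one mixture are non-negative least squares coefficients over the
shared signature genes, renormalized to the simplex. An all-zero NNLS
solution falls back to uniform fractions with a warning. Quantile
normalization (on by default, `deconv_qn`) replaces each mixture
column by the reference distribution's values at matching midranks.

Significance is by Monte Carlo: the observed goodness R is the Pearson
correlation between the NNLS reconstruction and the mixture; the null
refits after permuting the mixture's gene labels, and
`p = (1 + #{R_b ≥ R}) / (1 + n_perm)` — the +1 correction keeps p
positive at finite permutations. Retention requires `p < .05` **and**
`R > .7`, both strict, with `n_perm = 1000` by default. The
permutation scheme (gene-label permutation of the mixture) is the
natural null for "this mixture matches the reference structure"; it is
seeded and documented because published deconvolution tools do not
fully specify theirs.

## Prognosis

The composite signature is the deduplicated, sorted union of the three
pathway member lists (17 genes; the `IGHG` symbol is carried verbatim
from the source list even though it is not a specific HGNC symbol).
Patient-level expression is the mean of log2(normalized+1) over the
patient's retained EP and MA AOIs — survival is a patient-level
outcome, so covariates must be patient-level; EP+MA is the default
compartment set because both tumour and macrophage biology feed the
signature, and it is configurable.

The Cox model maximizes the Breslow-ties log partial likelihood by
Newton–Raphson with step-halving; covariates are centred (which leaves
the coefficients unchanged), convergence requires the largest Newton
step below 1e-8 within 50 iterations, and the likelihood trace is
non-decreasing by construction. The pipeline config applies a small L2
ridge (0.1) in the composite-signature fit: the 17 signature genes are
strongly co-expressed (in the generator they load on a single latent
risk factor; in tissue they co-vary as pathway modules), so the
unpenalized information matrix is near-singular at cohort-scale n and
the unpenalized fit can diverge. `cox_fit()` itself defaults to no
penalty. Risk scores are the linear predictor; the median split sends
ties — including the median patient at odd n — to the low-risk group.

Kaplan–Meier curves, the log-rank test and reverse-KM median follow-up
(the KM estimator applied to the complemented event indicator; its
median is undefined and flagged when no observation is censored) are
computed through the survival package. The AUC against binary
recurrence status is the Mann–Whitney statistic with 0.5 tie credit —
the probability that a random recurrent patient outscores a random
non-recurrent one. Time-dependent ROC is deliberately out of scope;
recurrence status is the grouping the signature is evaluated against.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the pipeline assumes, with
ground truth for every planted feature:

* **Counts**: negative binomial with a single dispersion (default 0.1,
  a typical bulk-profiling value) around
  `mean = libsize × baseline × marker effect × grade effect × risk effect`,
  with log-normal gene baselines (meanlog log 20, sdlog 1) and
  log-normal AOI library sizes (sdlog 0.3).
* **Compartment markers**: 20 genes per compartment, enriched 16-fold
  in their own compartment and depleted ~256-fold outside it.
  Segmentation purifies compartments, so foreign markers sit at
  background; this is also what makes the rescaled epithelial score of
  pure MA/ST AOIs cluster near 0, giving the fixed 0.05 contamination
  threshold its meaning on this scale.
* **Grade effects**: multiplicative 2^(effect × step) with steps
  well = 0, moderate = 1, poor = 2 for P1/P2 genes (default effect
  1 log2 per step, matching the |logFC| > 1 screen), and ±effect at
  moderate only for P3/P4.
* **Contamination**: chosen MA/ST AOIs draw from
  `(1−λ)·own + λ·EP` mean profiles (default λ = 0.6).
* **Technical violations**: designated AOIs receive NTC > 1000,
  nuclei < 100 or alignment < 0.8; violation AOIs are disjoint from
  each other and from contaminated AOIs so that reason codes are
  identifiable.
* **Outcomes**: a latent standard-normal patient risk loads 0.5 log2
  units per unit risk on the 17 signature genes; event times are
  exponential with log-hazard `risk_loghr × risk` (default 1) over a
  baseline hazard of 0.02/month, censored uniformly on (0, 60)
  months.

What it does **not** emulate: spatial coordinates and neighbourhood
structure, per-gene dispersions, probe-level chemistry, batch/slide
effects, grade–compartment interactions, and correlation between grade
and patient risk. Passing tests on this generator therefore shows the
pipeline recovers the statistical structure it claims to recover — not
that any particular biological conclusion transfers to real tissue.

### Problem sizes and the planted-risk condition

The test suite and the acceptance script use the design scale — 11
patients × 5 ROIs (165 AOIs, 2000 genes) for QC, pairing and
deconvolution; 30 balanced ROIs (10 per grade) for pattern recovery; a
2500-gene no-effect cohort for type-I calibration; n = 200 patients
for single-covariate Cox recovery.

The risk-stratification check uses a 60-patient cohort with a strong
planted effect (log-hazard 3 per unit risk). Two considerations force
both numbers. Log-rank significance at p < .01 needs events on both
sides of the median split, which 11 patients cannot reliably supply.
And uniform administrative censoring injects label noise into the
binary recurrence outcome — early-censored high-risk patients are
labelled non-recurrent — which caps the AUC of even the *true* planted
risk well below the target at moderate hazard ratios; a high AUC
regime is a strong-separation regime. The default generator keeps the
moderate effect (log-hazard 1), which is the more realistic value for
power studies.

## Numerical conventions

* Wilcoxon: midranks with tie-corrected variance in normal mode; a
  fully tied pooled sample returns p = 1 (symmetric null).
* Percentiles: linear interpolation (type 7) everywhere.
* Geometric means over counts use a +1 offset where zeros occur.
* ssGSEA ties: stable gene-id order, so scores are reproducible on
  constant profiles.
* Spearman exact p: two-sided as `#{|rho_perm| ≥ |rho|}/n!` with a
  1e-12 equality tolerance; identical to doubling the smaller tail
  under the symmetric null.
* NNLS: active-set (`pracma::lsqnonneg`); simplex renormalization
  tolerates coefficient sums within 1e-9 of machine round-off.
* Cox: step-halving accepts a step only if the penalized log partial
  likelihood does not decrease (tolerance 1e-12); a singular Hessian
  is nudged by 1e-8 on the diagonal before solving.
* File output: floats at 6 significant digits, rows sorted by primary
  key, so stage outputs are diffable across runs.
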