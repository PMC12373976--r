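# dspgrade

Compartment-stratified analysis of GeoMx-style digital spatial
profiling (DSP) counts across tumour differentiation grades, built for
segmented lung-adenocarcinoma cohorts in which every region of interest
(ROI) is split into epithelial-enriched (EP, PanCK+),
macrophage-enriched (MA, CD68/CD163+) and stromal-enriched (ST) areas
of interest (AOIs). The package turns the raw gene × AOI count matrix,
its AOI annotations, the negative-probe matrix and a patient survival
table into graded, compartment-resolved biology: which genes rise or
fall monotonically from well- through moderately- to poorly
differentiated tissue, how signatures in one compartment co-vary with
the neighbouring compartment inside the same ROI, what the stroma is
made of, and whether a composite pathway signature stratifies
recurrence risk.

## What it computes

**QC and normalization.** AOIs fail technical QC when the read
alignment rate is below 80%, the no-template-control (NTC) count
exceeds 1000, or fewer than 100 nuclei were segmented. Negative probes
set a per-AOI detection floor, `floor(a) = max(4, geomean(negprobes_a))`;
genes detected in fewer than 10% of AOIs are dropped. Each AOI is then
scaled by Q3 (75th-percentile) normalization,

```
scale(a) = geomean_b(Q3(b)) / Q3(a)
```

so every AOI shares the same detected-gene upper quartile. Finally,
MA/ST AOIs whose epithelial marker-set ssGSEA score (min–max rescaled
to [0,1] over the run) exceeds 0.05 are removed as epithelially
contaminated; EP AOIs are exempt.

**Grade-trend patterns.** Within a compartment, each gene is compared
across the three grade pairs by Wilcoxon rank-sum with mean-log2 fold
changes (`mean log2(B+1) − mean log2(A+1)`). Genes with p < .1 in at
least two comparisons are classified by the adjacent-grade logFC signs:
(+,+) → P1 progressive upregulation, (−,−) → P2 progressive
downregulation, (+,−) → P3 peaked at moderate, (−,+) → P4 troughed at
moderate; a significant well–poor comparison with a contradictory sign
vetoes P1/P2.

**Signature scores and ORA.** Single-sample gene-set enrichment uses
the rank-weighted running sum ES = Σᵢ [P_in(i) − P_out(i)] with weight
exponent α = 0.25, ranks by descending expression and stable gene-id
tie-breaks; scores are normalized by the global range.
Over-representation of a gene list against a collection uses the
upper-tail hypergeometric test with BH adjustment.

**Paired compartments.** Within each ROI the EP and MA profiles
(log2-averaged over duplicate AOIs) are reduced to set means and
correlated across ROIs by Spearman's rho (exact permutation p for
n ≤ 9, t-approximation otherwise; Pearson selectable).

**Deconvolution.** Stromal mixtures are quantile-normalized to a
reference distribution and decomposed over a signature-gene reference
by non-negative least squares; fractions are kept only when the Monte
Carlo permutation p (1000 permutations) is < .05 and the
reconstruction–mixture correlation R is > .7.

**Prognosis.** The composite signature is the union of three pathway
gene lists — complement activation (CFB, IGHA1, IGHG, IGHG2, IGHG4,
IGHM), ECM remodelling (COL6A2, MMP1, SPP1, TNC, P3H3) and humoural
immune response (BPIFA1, CXCL1, CXCL3, CXCL5, CXCL8, DMBT1) — 17 genes
in all, shipped as `inst/extdata/signature17.gmt`. A Newton–Raphson Cox
fit (Breslow ties, optional ridge) on patient-level EP+MA expression
produces risk scores Σ βg·xg; patients are split at the median score
and evaluated by Kaplan–Meier/log-rank, Mann–Whitney AUC against
recurrence status, and reverse-KM median follow-up.

A synthetic cohort generator (`sim_config()` / `simulate_cohort()`)
emulates the full data structure — negative-binomial counts, library
sizes, compartment markers, planted trend genes, contaminated AOIs,
technical violations, and exponential recurrence outcomes tied to a
latent patient risk — with complete ground truth for every test.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
simulated 11-patient cohort (55 ROIs, 165 AOIs, 2000 genes) and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_normalize.R
...
Rscript analysis/07_prognosis.R
```

Output from a full run:

```
cohort: 2000 genes x 165 AOIs, 11 patients, 55 ROIs
retained 155/165 AOIs; 1993 genes after detection filter
EP: P1=76 P2=58 P3=91 P4=96 unclassified=1672
EP well vs poor: 98 significant genes at |logFC|>1, p<.05
ORA of 76 P1 genes: top set pattern1_up (adj p = 1.47e-79)
EP complement vs MA ECM across 46 ROI pairs: rho = 0.70, p = 6.5e-08
deconvolved 54 ST AOIs: 54 retained (p<.05, R>.7), mean ST fraction 1.000
17-gene risk model: AUC = 0.933, log-rank p = 0.00171
median follow-up (reverse KM) = 38.4 months, cutoff = 9.546
```

Reading: the ten AOIs removed are exactly the planted violations (2
high-NTC, 3 low-nuclei, 1 low-alignment, 4 contaminated MA); the P1
calls in the epithelium recover the planted progressive-upregulation
class (the ORA line); the cross-compartment correlation reflects the
shared latent risk factor loading complement genes in EP and ECM genes
in MA; and the 17-gene risk score separates recurrence despite only 11
patients.

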