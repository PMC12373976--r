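#!/usr/bin/env Rscript
# Stage 2 — technical QC and Q3 normalization.
#
# Applies the QC cascade to the simulated cohort: alignment < 80%,
# NTC > 1000 and nuclei < 100 remove AOIs; negative probes set per-AOI
# detection floors (minimum 4 counts); genes detected in < 10% of AOIs
# are dropped; surviving AOIs are scaled so their detected-gene 75th
# percentiles match the cohort geometric mean; finally MA/ST AOIs whose
# rescaled epithelial ssGSEA score exceeds 0.05 are flagged as
# contaminated and removed.

library(dspgrade)

cohort <- read_cohort("results/cohort/counts.tsv",
                      "results/cohort/annotations.tsv",
                      "results/cohort/negprobes.tsv",
                      "results/cohort/survival.tsv")
markers <- read_gmt("results/cohort/marker_sets.gmt")

qc <- qc_normalize(cohort$counts, cohort$annotations, cohort$negprobes,
                   markers$EP)

write_table(qc$qc, "results/qc_report.tsv")
write_table(qc$factors, "results/normalization_factors.tsv")
write_table(qc$scores, "results/epithelial_scores.tsv")
write_matrix(qc$normalized, "results/normalized_counts.tsv")

message(sprintf("retained %d/%d AOIs; %d genes after detection filter",
                length(qc$retained), nrow(cohort$annotations),
                nrow(qc$normalized)))
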