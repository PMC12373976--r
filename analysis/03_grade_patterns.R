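#!/usr/bin/env Rscript
# Stage 3 — differential expression and grade-trend patterns.
#
# Within each compartment, every gene is compared between the three
# grade pairs (well-moderate, moderate-poor, well-poor) by Wilcoxon
# rank-sum with mean-log2 fold changes, and classified into the four
# trend patterns (P1 progressive up, P2 progressive down, P3 peaked,
# P4 troughed at moderate) when p < .1 in at least two comparisons.

library(dspgrade)

normalized <- read_count_matrix("results/normalized_counts.tsv")
annotations <- read_annotations("results/cohort/annotations.tsv")

for (comp in c("EP", "MA", "ST")) {
  pat <- tryCatch(pattern_analysis(normalized, annotations, comp),
                  error = function(e) {
                    message(comp, " skipped: ", conditionMessage(e)); NULL
                  })
  if (is.null(pat)) next
  write_table(pat, sprintf("results/patterns_%s.tsv", comp))
  counts <- table(factor(pat$pattern,
                         c("P1", "P2", "P3", "P4", "UNCLASSIFIED")))
  message(sprintf("%s: P1=%d P2=%d P3=%d P4=%d unclassified=%d",
                  comp, counts[["P1"]], counts[["P2"]], counts[["P3"]],
                  counts[["P4"]], counts[["UNCLASSIFIED"]]))
}

# the screening DE table for the steepest contrast in the epithelium
de <- differential_expression(normalized, annotations, "EP", "well", "poor")
write_table(de, "results/de_EP_well_vs_poor.tsv")
message(sprintf("EP well vs poor: %d significant genes at |logFC|>1, p<.05",
                sum(de$significant)))
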