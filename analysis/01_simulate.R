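#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a DSP-like cohort at the design scale (11 patients, 5 ROIs
# each, one EP/MA/ST AOI per ROI, 2000 genes) with planted structure:
# grade-trend gene classes, compartment markers, a latent per-patient
# risk factor loading on the 17 composite-signature genes, designed
# technical QC violations (2 high-NTC, 3 low-nuclei, 1 low-alignment)
# and 4 epithelially contaminated macrophage AOIs (lambda = 0.6).
# Writes the five pipeline input files plus the ground-truth tables.

library(dspgrade)

cfg <- sim_config(qc_violations = c(ntc = 2, nuclei = 3, alignment = 1),
                  contam_n_ma = 4, contam_lambda = 0.6, seed = 7)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")
write_gmt(cohort$truth$signature_sets, "results/cohort/signature_sets.gmt")
write_gmt(cohort$truth$marker_sets, "results/cohort/marker_sets.gmt")

message(sprintf("cohort: %d genes x %d AOIs, %d patients, %d ROIs",
                nrow(cohort$counts), ncol(cohort$counts),
                cfg$n_patients, cfg$n_patients * cfg$rois_per_patient))
message("inputs and truth written under results/cohort/")
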