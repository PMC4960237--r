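#!/usr/bin/env Rscript
# Stage 1: simulate a fractionation-proteomics study.
#
# Generates the benchmark proteome (2176 proteins, ~4% outer membrane, two
# growth conditions, three fractions plus a 24-step sucrose gradient) and
# writes it to disk in the pipeline's interchange formats, together with the
# generator's ground truth, so the later stages run from files exactly as
# they would on real data.

library(omprofiler)

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_gradient_fractions = 24, seed = 101)
sim <- generate_dataset(cfg)

write_fasta(sim$records, file.path(out, "proteome.fasta"))
write_predictor_table(sim$profiles, file.path(out, "predictors.tsv"))
write_lfq_table(sim$table, file.path(out, "lfq.tsv"))
write.table(sample_meta(sim$table), file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$proteins, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- table(sim$truth$proteins$compartment)
cat("Simulated", cfg$n_proteins, "proteins over",
    ncol(lfq_values(sim$table)), "samples\n")
cat("Compartment counts:\n")
print(tr)
cat("Planted: ", cfg$n_responsive, " responsive OM proteins, ",
    2 * cfg$n_exclusive_per_condition, " condition-exclusive, ",
    cfg$n_undetected_om, " never-detected, ",
    cfg$n_pepcterm, " PEP-CTERM proteins\n", sep = "")
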