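#!/usr/bin/env Rscript
# Stage 1 — simulate the study's three expression datasets with known truth:
# two disease-vs-healthy cohorts (A with technical triplicates, B without)
# sharing an attenuated disease effect, and a paired TKI-treatment dataset
# whose per-gene effect is rescued, enhanced or independent.

library(persistsig)

seed <- as.integer(Sys.getenv("PERSISTSIG_SEED", "1"))
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- generate_cohort_pair(cfg)
matrix_T <- generate_treatment_dataset(sim$truth, cfg)

write_expression_matrix(sim$matrix_A, file.path(outdir, "matrix_A.tsv"),
                        file.path(outdir, "samples_A.tsv"))
write_expression_matrix(sim$matrix_B, file.path(outdir, "matrix_B.tsv"),
                        file.path(outdir, "samples_B.tsv"))
write_expression_matrix(matrix_T, file.path(outdir, "matrix_T.tsv"),
                        file.path(outdir, "samples_T.tsv"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(as.character(seed), file.path(outdir, "seed.txt"))

cat(sprintf("simulated %d genes (seed %d): %d truth-DE\n",
            cfg$n_genes, seed, sum(sim$truth$is_de)))
cat(sprintf("dataset A: %d columns (%d biological x %d replicates); B: %d; treatment: %d\n",
            ncol(sim$matrix_A$values), 2 * cfg$n_per_group_A,
            cfg$n_tech_reps, ncol(sim$matrix_B$values),
            ncol(matrix_T$values)))
print(table(sim$truth$treat_class))
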