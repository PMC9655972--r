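#!/usr/bin/env Rscript
# Stage 4 — the signature: intersect the DE sets of the two cohort datasets,
# test the overlap against the hypergeometric null, correlate fold-changes
# across datasets, classify the consistent genes as rescued / enhanced /
# TKI-independent, and score the labels against the simulated truth.

library(persistsig)

dir.create("results/signature", recursive = TRUE, showWarnings = FALSE)

results_A <- read_contrast_result("results/de/results_A.tsv")
results_B <- read_contrast_result("results/de/results_B.tsv")
results_T <- read_contrast_result("results/de/results_T.tsv")
nonchange <- read.delim("results/equivalence/nonchange.tsv")
truth <- read.delim("results/sim/truth.tsv")

consistent <- intersect_de(results_A, results_B, q_threshold = 0.1)
print(consistent)
overlap <- hypergeometric_overlap(consistent$n_universe, consistent$n_A,
                                  consistent$n_B, consistent$n_overlap)
print(overlap)
correlation <- correlate_foldchanges(results_A, results_B)
cat(sprintf("cross-dataset fold-change correlation: r = %.3f (p = %.3g, n = %d)\n",
            correlation$pearson_r, correlation$p_value,
            correlation$n_shared))

classification <- classify_genes(consistent, results_A, results_T, nonchange)
print(classification)

m <- match(classification$gene_id, truth$gene_id)
truth_lab <- ifelse(truth$treat_class[m] == "independent",
                    "tki_independent", truth$treat_class[m])
keep <- truth_lab != "none"
per_class <- vapply(c("rescued", "enhanced", "tki_independent"),
                    function(l) mean(classification$label[keep][truth_lab[keep] == l] == l),
                    numeric(1))
cat("per-class accuracy vs truth (truth-DE genes in the consistent set):\n")
print(round(per_class, 3))
cat(sprintf("macro-averaged accuracy: %.3f\n", mean(per_class)))

write.table(classification, "results/signature/classification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(overlap), "results/signature/overlap.json",
                     auto_unbox = TRUE, digits = NA)
jsonlite::write_json(correlation, "results/signature/correlation.json",
                     auto_unbox = TRUE, digits = NA)
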