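#!/usr/bin/env Rscript
# Stage 3 — equivalence margin and non-change calls: pool signed log2
# fold-changes between technical replicates of dataset A, take their
# 2.5/97.5 percentiles as the expected technical variation, round to the
# nearest 0.1, and call a gene non-changing after treatment when its 95% CI
# crosses zero and is contained within the margin.

library(persistsig)

dir.create("results/equivalence", recursive = TRUE, showWarnings = FALSE)

matrix_A <- read_expression_matrix("results/sim/matrix_A.tsv",
                                   "results/sim/samples_A.tsv")
diffs <- replicate_foldchanges(matrix_A)
margin <- derive_margin(diffs)
cat(sprintf("pooled %d replicate differences (SD %.3f)\n",
            length(diffs), sd(diffs)))
cat(sprintf("raw percentiles: [%.4f, %.4f] -> margin [%g, %g]\n",
            margin$raw_lower, margin$raw_upper, margin$lower, margin$upper))

results_T <- read_contrast_result("results/de/results_T.tsv")
nonchange <- call_nonchanging(results_T, margin)
cat(sprintf("%d of %d genes non-changing after treatment\n",
            sum(nonchange$nonchanging), nrow(nonchange)))

write_margin(margin, "results/equivalence/margin.json")
write.table(nonchange, "results/equivalence/nonchange.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
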