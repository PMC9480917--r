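#!/usr/bin/env Rscript
# Design-efficiency comparison of the five ER sequence variants: random and
# selected fast ER (block-randomized, with nulls), slow ER, fully randomized
# fast ER, and fast ER without null events. Writes the summary table to
# results/table1.tsv.

library(somatomap)

dir.create("results", showWarnings = FALSE)

tab <- experiment_table1(n_draws = 1000, n_select = 50000, top_k = 20,
                         seed = 1)

write.table(tab$table, "results/table1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

t <- tab$table
g <- function(d, c) t[t$design == d, c]
cat("Design efficiencies (mean over draws; detection / HRF estimation /",
    "difference detection):\n")
print(t, digits = 3)
cat(sprintf(
  "\nRandom fast vs slow detection ratio: %.2f (selection raises it to %.2f)\n",
  g("fast_er", "detection") / g("slow_er", "detection"),
  g("fast_er_selected", "detection") / g("slow_er", "detection")
))
cat(sprintf("HRF-estimation ratio fast vs slow: %.2f\n",
            g("fast_er", "hrf_estimation") / g("slow_er", "hrf_estimation")))
cat(sprintf(
  "Removing null events collapses detection (%.2f) and HRF estimation (%.3f):\n",
  g("fast_er_nonull", "detection"), g("fast_er_nonull", "hrf_estimation")
))
cat("with every TR stimulated the regressors sum to a near-constant that is\n")
cat("collinear with the baseline, while pairwise differences survive\n")
cat(sprintf("(difference detection %.2f vs %.2f for the standard fast ER).\n",
            g("fast_er_nonull", "difference_detection"),
            g("fast_er", "difference_detection")))
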