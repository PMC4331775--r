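#!/usr/bin/env Rscript
# Per-tissue differential expression for the three pairwise comparisons
# (castrated vs sham, testosterone vs castrated, follistatin vs castrated):
# two-group linear fits, empirical-Bayes moderated t, BH q-values.

library(sensigo)

out <- "results/synthetic"
dat <- read_expression(file.path(out, "expression_rma.tsv"),
                       file.path(out, "samples.tsv"))

for (tissue in unique(dat$samples$tissue)) {
  de <- run_differential_expression(dat$expr, dat$samples, tissue)
  for (cmp in names(de)) {
    path <- file.path(out, sprintf("de_%s_%s.tsv", tissue, cmp))
    write.table(de[[cmp]], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cat(sprintf("%s %-11s: %4d genes at q < 0.2  (min q = %.2g)\n",
                tissue, cmp, sum(de[[cmp]]$q < 0.2), min(de[[cmp]]$q)))
  }
}
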