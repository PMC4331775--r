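#!/usr/bin/env Rscript
# Dual-contrast sensitivity calls: a gene is androgen-sensitive when q < 0.2
# in both castrated-vs-sham and testosterone-vs-castrated; follistatin-
# sensitive when q < 0.2 in both castrated-vs-sham and
# follistatin-vs-castrated. Venn counts are compared against the planted
# truth to quantify recovery per tissue.

library(sensigo)

out <- "results/synthetic"
truth <- read.delim(file.path(out, "truth.tsv"))
samples <- read.delim(file.path(out, "samples.tsv"))

venn_rows <- list()
for (tissue in unique(samples$tissue)) {
  de <- lapply(c(cx_vs_sham = "cx_vs_sham", T_vs_cx = "T_vs_cx",
                 F_vs_cx = "F_vs_cx"), function(cmp)
    read.delim(file.path(out, sprintf("de_%s_%s.tsv", tissue, cmp))))
  calls <- classify_sensitivity(de, q_threshold = 0.2)
  write.table(calls, file.path(out, sprintf("calls_%s.tsv", tissue)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  v <- venn_partition(calls)
  tt <- truth[truth$tissue == tissue, ]
  tt <- tt[match(calls$gene_id, tt$gene_id), ]
  rec_a <- sum(calls$androgen_sensitive & tt$is_androgen_sensitive) /
    max(sum(tt$is_androgen_sensitive), 1)
  cat(sprintf(
    "%s: %d androgen / %d follistatin / %d both (androgen recovery %.0f%%)\n",
    tissue, v$n_androgen, v$n_follistatin, v$n_both, 100 * rec_a))
  venn_rows[[tissue]] <- data.frame(tissue = tissue, v)
}
write.table(do.call(rbind, venn_rows), file.path(out, "venn_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

v <- do.call(rbind, venn_rows)
cat(sprintf(
  "muscle both/androgen = %.2f; prostate follistatin/androgen = %.3f\n",
  v$n_both[v$tissue == "levator_ani"] /
    v$n_androgen[v$tissue == "levator_ani"],
  v$n_follistatin[v$tissue == "prostate"] /
    v$n_androgen[v$tissue == "prostate"]))
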