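#!/usr/bin/env Rscript
# Simulate the study: two tissues (levator ani muscle, prostate), four
# conditions (sham, castrated, castrated+testosterone,
# castrated+follistatin), four replicates per group, 10,000 genes with
# planted effects that mirror the expected tissue asymmetry (large
# androgen/follistatin overlap in muscle, almost no follistatin response in
# prostate), plus Affymetrix-like probe-level intensities and a synthetic GO
# hierarchy with sparse annotations.

library(sensigo)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

design <- study_design()
cfg <- synth_config(seed = seed)

sim <- generate_expression(design, cfg)
write_expression(sim$expr, sim$samples,
                 file.path(out, "expression_true.tsv"),
                 file.path(out, "samples.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pl <- generate_probe_level(sim$expr, cfg)
write_probe_data(pl$data, file.path(out, "probe_intensities.tsv"))

onto <- generate_ontology(150, nrow(sim$expr), cfg,
                          genes = rownames(sim$expr))
write_obo(onto$dag, file.path(out, "ontology.obo"))
write_gaf(onto$annotations, file.path(out, "annotations.gaf"))

tr <- sim$truth
for (tissue in design$tissues) {
  tt <- tr[tr$tissue == tissue, ]
  cat(sprintf(
    "%s: planted %d androgen-sensitive, %d follistatin-sensitive, %d both\n",
    tissue, sum(tt$is_androgen_sensitive),
    sum(tt$is_follistatin_sensitive),
    sum(tt$is_androgen_sensitive & tt$is_follistatin_sensitive)))
}
cat(sprintf("wrote %d genes x %d samples, %d probes, %d GO terms to %s\n",
            nrow(sim$expr), ncol(sim$expr), nrow(pl$data$intensity),
            nrow(onto$dag$terms), out))
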