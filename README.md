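# sensigo

Separating androgen-sensitive from follistatin-sensitive transcripts in a
two-tissue hormone study, with a self-contained GO enrichment engine.

## The problem

Testosterone builds muscle but also drives prostate growth; follistatin is a
candidate prostate-sparing anabolic agent. A transcriptome experiment that
compares sham, castrated, castrated+testosterone and castrated+follistatin
mice in an androgen-responsive muscle (levator ani) and in prostate can ask,
gene by gene, which hormone a transcript responds to — and whether the two
hormones share their transcriptional program in muscle while diverging in
prostate. `sensigo` implements that analysis end to end for anyone who has
probe-level (or probeset-level) expression tables for such a
2-tissue x 4-condition design, and bundles a synthetic-data generator so
every stage can be validated against planted ground truth.

## The method

1. **RMA preprocessing.** Probe intensities are background-corrected under
   the exponential-signal + normal-background convolution model
   (`E[s | o]` posterior mean, parameters estimated per array from the
   intensity mode), quantile-normalized across arrays, log2-transformed and
   summarized per probeset by Tukey median polish of the additive model
   `log2 I = mu + probe + sample + resid`.

2. **Moderated differential expression.** For each tissue and each pairwise
   comparison (cx vs sham, cx+T vs cx, cx+F vs cx), a two-group linear fit
   gives the log2 fold change `b_g`, pooled variance `s_g^2` and residual df
   `d_g`. An empirical-Bayes scaled inverse-chi-square prior
   `(d_0, s_0^2)` is fitted to the variances by digamma/trigamma moment
   matching, and each gene's variance is shrunk:

   ```
   s~_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)
   t~_g   = b_g / (u_g * s~_g),    p from t with d_0 + d_g df
   ```

   p-values are Benjamini–Hochberg adjusted; the adjusted values are the
   q-values used downstream.

3. **Dual-contrast classification.** A gene is *androgen-sensitive* when
   q < 0.2 in both cx-vs-sham and T-vs-cx; *follistatin-sensitive* when
   q < 0.2 in both cx-vs-sham and F-vs-cx. Genes partition into uniquely
   androgen, uniquely follistatin, both, or neither, with Venn counts per
   tissue.

4. **GO enrichment.** OBO and GAF files are parsed, restricted to
   biological_process, and every gene is propagated to all is_a ancestors of
   its direct terms (so the root is annotated to every annotated gene).
   Terms with more than 5 and fewer than 300 genes are retained; for a
   selected set of k genes out of an n-gene annotated universe, a term
   covering m genes with x selected hits is scored with the upper-tail
   hypergeometric probability

   ```
   P(X >= x) = sum_{j=x}^{min(m,k)} C(m,j) C(n-m,k-j) / C(n,k)
   ```

   computed in log space, BH-adjusted across retained terms, and reported
   at adjusted p < e^-3 (~0.0498) by default.

## Worked example

```r
library(sensigo)
cfg <- pipeline_config("demo_out", seed = 1,
                       synth = synth_config(n_genes = 2000, seed = 1),
                       probe_level = FALSE, n_go_terms = 80)
s <- run_pipeline(cfg)
cat(make_report(s, top = 4), sep = "\n")
```

```
Hormone-sensitivity analysis report
===================================
seed: 1
q_threshold: 0.2 (strict <)
GO filter: >5 and <300 genes per term
enrichment adjust: BH, alpha = 0.0498

Tissue: levator_ani
  androgen-sensitive: 166
  follistatin-sensitive: 151
  both: 82
  uniquely_androgen (84 genes): gene_00737, gene_01904, gene_00316, gene_01319
  uniquely_follistatin (69 genes): gene_00126, gene_00672, gene_00867, gene_00664
  both (82 genes): gene_00499, gene_00526, gene_01708, gene_00378

Tissue: prostate
  androgen-sensitive: 106
  follistatin-sensitive: 1
  both: 1
  uniquely_androgen (105 genes): gene_01532, gene_00279, gene_00981, gene_01588
  uniquely_follistatin (0 genes):
  both (1 genes): gene_01516
```

The report shows the expected asymmetry: in muscle roughly half of the
androgen-sensitive genes are also follistatin-sensitive, while in prostate
the follistatin-sensitive set is essentially empty. Per-stage tables
(expression matrix, three contrast tables per tissue, sensitivity calls,
Venn counts, enrichment results) are written as tab-delimited files under
the output directory, together with a YAML copy of the configuration.

## The analysis, step by step

The `analysis/` directory runs the same pipeline as separate narrated
stages on a full-size simulation (10,000 genes, 11 probes per probeset,
both tissues), writing intermediates under `results/synthetic/`:

```sh
Rscript analysis/01_simulate.R                 # data + ontology generation
Rscript analysis/02_preprocess.R               # RMA; agreement with truth
Rscript analysis/03_differential_expression.R  # moderated t per contrast
Rscript analysis/04_classify.R                 # calls, Venn counts, recovery
Rscript analysis/05_enrichment.R               # GO over-representation
```

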