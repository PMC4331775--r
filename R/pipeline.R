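# End-to-end orchestration: simulate -> preprocess -> differential
# expression -> classification -> enrichment, with provenance and a
# machine-readable summary.

#' Pipeline configuration
#'
#' Collects every tunable of the full run. The configuration is validated
#' here and serialized (YAML) into the output directory for provenance.
#'
#' @param out_dir output directory (created if missing).
#' @param seed base seed; overrides the synth config's seed.
#' @param design a [study_design()].
#' @param synth a [synth_config()].
#' @param q_threshold sensitivity q-value cutoff (default 0.2).
#' @param go_min_excl,go_max_excl GO frequency-filter bounds (default 5 and
#'   300, exclusive).
#' @param adjust multiplicity adjustment for enrichment ("BH" or
#'   "bonferroni").
#' @param alpha adjusted-p reporting threshold for enrichment (default
#'   exp(-3)).
#' @param probe_level simulate probe intensities and run RMA (TRUE) or use
#'   the simulated expression matrix directly (FALSE).
#' @param n_go_terms number of synthetic ontology terms.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            design = study_design(),
                            synth = synth_config(seed = seed),
                            q_threshold = 0.2,
                            go_min_excl = 5L, go_max_excl = 300L,
                            adjust = "BH", alpha = exp(-3),
                            probe_level = TRUE,
                            n_go_terms = 150L) {
  stopifnot(inherits(design, "study_design"), inherits(synth, "synth_config"))
  if (!(q_threshold > 0 && q_threshold <= 1))
    stop_input("q_threshold must lie in (0, 1]")
  if (go_min_excl >= go_max_excl) stop_input("require go_min < go_max")
  synth$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 design = design, synth = synth,
                 q_threshold = q_threshold,
                 go_min_excl = as.integer(go_min_excl),
                 go_max_excl = as.integer(go_max_excl),
                 adjust = adjust, alpha = alpha,
                 probe_level = isTRUE(probe_level),
                 n_go_terms = as.integer(n_go_terms)),
            class = "pipeline_config")
}

serialize_config <- function(cfg, path) {
  plain <- list(
    seed = cfg$seed,
    tissues = cfg$design$tissues,
    replicates_per_group = cfg$design$replicates_per_group,
    q_threshold = cfg$q_threshold,
    go_min_excl = cfg$go_min_excl, go_max_excl = cfg$go_max_excl,
    adjust = cfg$adjust, alpha = cfg$alpha,
    probe_level = cfg$probe_level, n_go_terms = cfg$n_go_terms,
    synth = unclass(cfg$synth))
  plain$synth$tissue_params <- as.list(cfg$synth$tissue_params)
  yaml::write_yaml(plain, path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in order: simulate expression (and optionally probe-level data
#' followed by RMA preprocessing), fit the three contrasts per tissue with
#' moderated t and BH q-values, call androgen/follistatin sensitivity,
#' partition into Venn categories, and test each non-empty category for GO
#' over-representation against a synthetic ontology. Every stage writes a
#' tab-delimited table under `out_dir`; the run is deterministic given the
#' seed.
#'
#' @param cfg a [pipeline_config()].
#' @return A `pipeline_summary` list: per-tissue Venn counts, per-category
#'   significant GO terms, thresholds used, file index.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  serialize_config(cfg, file.path(cfg$out_dir, "config.yaml"))

  sim <- stage("simulate", generate_expression(cfg$design, cfg$synth))
  expr <- sim$expr
  if (cfg$probe_level) {
    pl <- stage("probe_level", generate_probe_level(sim$expr, cfg$synth))
    expr <- stage("rma", rma(pl$data))
    expr <- expr[rownames(sim$expr), , drop = FALSE]
  }
  write_expression(expr, sim$samples,
                   file.path(cfg$out_dir, "expression.tsv"),
                   file.path(cfg$out_dir, "samples.tsv"))
  write_tsv(sim$truth, file.path(cfg$out_dir, "truth.tsv"))

  onto <- stage("ontology",
                generate_ontology(cfg$n_go_terms, nrow(expr), cfg$synth,
                                  genes = rownames(expr)))
  write_obo(onto$dag, file.path(cfg$out_dir, "ontology.obo"))
  write_annotations(onto$annotations,
                    file.path(cfg$out_dir, "annotations.tsv"))
  ann <- stage("propagate", propagate_annotations(onto$dag,
                                                  onto$annotations))

  summary <- list(seed = cfg$seed, q_threshold = cfg$q_threshold,
                  alpha = cfg$alpha, adjust = cfg$adjust,
                  go_min_excl = cfg$go_min_excl,
                  go_max_excl = cfg$go_max_excl,
                  probe_level = cfg$probe_level,
                  tissues = list())
  venn_rows <- list()
  for (tissue in cfg$design$tissues) {
    de <- stage("diffexpr",
                run_differential_expression(expr, sim$samples, tissue))
    for (cmp in names(de))
      write_tsv(de[[cmp]],
                file.path(cfg$out_dir,
                          sprintf("de_%s_%s.tsv", tissue, cmp)))
    calls <- stage("classify", classify_sensitivity(de, cfg$q_threshold))
    write_tsv(calls, file.path(cfg$out_dir,
                               sprintf("calls_%s.tsv", tissue)))
    venn <- venn_partition(calls)
    venn_rows[[tissue]] <- data.frame(tissue = tissue,
                                      n_androgen = venn$n_androgen,
                                      n_follistatin = venn$n_follistatin,
                                      n_both = venn$n_both)
    enr <- list()
    for (cat in c("uniquely_androgen", "uniquely_follistatin", "both")) {
      sel <- calls$gene_id[calls$category == cat]
      if (!length(sel)) next  # empty selection: no enrichment performed
      tab <- stage("enrich", suppressWarnings(
        enrich_terms(sel, ann, onto$dag, cfg$go_min_excl, cfg$go_max_excl,
                     cfg$adjust, cfg$alpha)))
      write_tsv(tab, file.path(cfg$out_dir,
                               sprintf("enrich_%s_%s.tsv", tissue, cat)))
      enr[[cat]] <- sum(tab$significant)
    }
    summary$tissues[[tissue]] <- list(venn = venn,
                                      n_significant_go = enr)
  }
  write_tsv(do.call(rbind, venn_rows),
            file.path(cfg$out_dir, "venn_counts.tsv"))
  yaml::write_yaml(summary, file.path(cfg$out_dir, "summary.yaml"))
  structure(c(summary, list(out_dir = cfg$out_dir)),
            class = "pipeline_summary")
}

#' Render a plain-text run report
#'
#' Lists the thresholds used, per-tissue Venn counts, the top sensitive
#' genes per category ordered by q, and significant GO terms.
#'
#' @param summary a `pipeline_summary` from [run_pipeline()].
#' @param path optional file to write; the lines are also returned.
#' @param top number of genes to list per category.
#' @return Character vector of report lines, invisibly when `path` is given.
#' @export
make_report <- function(summary, path = NULL, top = 10L) {
  stopifnot(inherits(summary, "pipeline_summary"))
  out_dir <- summary$out_dir
  lines <- c("Hormone-sensitivity analysis report",
             "===================================",
             sprintf("seed: %d", summary$seed),
             sprintf("q_threshold: %g (strict <)", summary$q_threshold),
             sprintf("GO filter: >%d and <%d genes per term",
                     summary$go_min_excl, summary$go_max_excl),
             sprintf("enrichment adjust: %s, alpha = %.4f",
                     summary$adjust, summary$alpha), "")
  for (tissue in names(summary$tissues)) {
    v <- summary$tissues[[tissue]]$venn
    lines <- c(lines, sprintf("Tissue: %s", tissue),
               sprintf("  androgen-sensitive: %d", v$n_androgen),
               sprintf("  follistatin-sensitive: %d", v$n_follistatin),
               sprintf("  both: %d", v$n_both))
    calls_file <- file.path(out_dir, sprintf("calls_%s.tsv", tissue))
    if (!file.exists(calls_file))
      stop_input("missing stage output: ", calls_file)
    calls <- read_tsv(calls_file)
    de <- read_tsv(file.path(out_dir,
                             sprintf("de_%s_cx_vs_sham.tsv", tissue)))
    q <- de$q[match(calls$gene_id, de$gene_id)]
    for (cat in c("uniquely_androgen", "uniquely_follistatin", "both")) {
      sel <- calls$gene_id[calls$category == cat]
      sel <- sel[order(q[match(sel, calls$gene_id)])]
      lines <- c(lines, sprintf("  %s (%d genes): %s", cat, length(sel),
                                paste(utils::head(sel, top),
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
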