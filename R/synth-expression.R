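#' Describe the study design
#'
#' The design mirrors a two-tissue castration/restoration experiment: sham
#' (intact) controls, castrated mice, castrated mice given testosterone, and
#' castrated mice given recombinant follistatin, with at least four replicates
#' per group. The condition labels are fixed; tissues and replication are
#' configurable.
#'
#' @param tissues character vector of unique tissue labels. Defaults to the
#'   androgen-responsive levator ani muscle and the prostate.
#' @param replicates_per_group integer >= 2, number of arrays per
#'   tissue-by-condition group (default 4).
#' @return A `study_design` list with `tissues`, `conditions`,
#'   `replicates_per_group`.
#' @export
study_design <- function(tissues = c("levator_ani", "prostate"),
                         replicates_per_group = 4L) {
  if (anyDuplicated(tissues)) stop_input("tissue labels must be unique")
  if (length(tissues) < 1L) stop_input("at least one tissue is required")
  replicates_per_group <- as.integer(replicates_per_group)
  if (is.na(replicates_per_group) || replicates_per_group < 2L)
    stop_input("replicates_per_group must be an integer >= 2")
  structure(
    list(tissues = as.character(tissues),
         conditions = c("sham", "cx", "cx_T", "cx_F"),
         replicates_per_group = replicates_per_group),
    class = "study_design")
}

default_tissue_params <- function() {
  # Sensitive-gene fractions per 10,000-gene universe, mirroring the observed
  # Venn structure: muscle has a large androgen/follistatin overlap (~46% of
  # androgen-sensitive genes), prostate has almost no follistatin response.
  data.frame(
    tissue = c("levator_ani", "prostate"),
    frac_androgen = c(0.0852, 0.0593),
    overlap_follistatin = c(391 / 852, 7 / 593),
    frac_follistatin_only = c((778 - 391) / 10000, 2 / 10000),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults define the simulated study conditions: a 10,000-gene universe,
#' planted condition effects of |delta| in \[0.5, 2\] log2 units with random
#' sign, per-gene residual variances drawn from a scaled inverse-chi-square
#' prior (d0 = 4, s0^2 = 0.04, i.e. residual sd around 0.2 log2 units, typical
#' of RMA-summarized arrays), 11 probes per probeset with probe-affinity sd
#' 0.4, and an additive normal optical background (mean 100, sd 20) under an
#' exponential-like signal, matching the convolution model the background
#' correction assumes.
#'
#' @param n_genes number of genes/probesets.
#' @param tissue_params data.frame with columns `tissue`, `frac_androgen`,
#'   `overlap_follistatin` (fraction of androgen-sensitive genes that are also
#'   follistatin-sensitive), `frac_follistatin_only`.
#' @param effect_min,effect_max bounds of the uniform |delta| distribution
#'   (log2 units).
#' @param var_prior_df,var_prior_scale prior df and scale of the scaled
#'   inverse-chi-square residual-variance distribution. `var_prior_scale = 0`
#'   gives noise-free data.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression.
#' @param probes_per_set probes per probeset (Affymetrix-like default 11).
#' @param probe_affinity_sd sd of fixed per-probe affinity offsets (log2).
#' @param bg_mean,bg_sd additive background intensity parameters (linear
#'   scale).
#' @param annot_prob probability that a gene carries any direct GO annotation.
#' @param seed base seed driving every sub-generator (see [with_seed()]).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 10000L,
                         tissue_params = default_tissue_params(),
                         effect_min = 0.5, effect_max = 2,
                         var_prior_df = 4, var_prior_scale = 0.04,
                         baseline_mean = 8, baseline_sd = 2,
                         probes_per_set = 11L, probe_affinity_sd = 0.4,
                         bg_mean = 100, bg_sd = 20,
                         annot_prob = 0.9,
                         seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stop_input("n_genes must be positive")
  if (as.integer(probes_per_set) < 1L)
    stop_input("probes_per_set must be >= 1")
  fr <- unlist(tissue_params[, c("frac_androgen", "overlap_follistatin",
                                 "frac_follistatin_only")])
  if (any(fr < 0 | fr > 1)) stop_input("sensitive fractions must lie in [0,1]")
  if (effect_min <= 0 || effect_max < effect_min)
    stop_input("require 0 < effect_min <= effect_max")
  if (var_prior_scale < 0 || var_prior_df <= 0)
    stop_input("variance prior parameters must be positive")
  structure(
    list(n_genes = n_genes, tissue_params = tissue_params,
         effect_min = effect_min, effect_max = effect_max,
         var_prior_df = var_prior_df, var_prior_scale = var_prior_scale,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         probes_per_set = as.integer(probes_per_set),
         probe_affinity_sd = probe_affinity_sd,
         bg_mean = bg_mean, bg_sd = bg_sd,
         annot_prob = annot_prob,
         seed = as.integer(seed)),
    class = "synth_config")
}

# Signed effect sizes: +/- Uniform[effect_min, effect_max], n at a time.
draw_effect <- function(n, cfg, sign = NULL) {
  mag <- stats::runif(n, cfg$effect_min, cfg$effect_max)
  if (is.null(sign)) sign <- sample(c(-1, 1), n, replace = TRUE)
  sign * mag
}

make_effect_truth <- function(design, cfg) {
  n <- cfg$n_genes
  genes <- sprintf("gene_%05d", seq_len(n))
  out <- vector("list", length(design$tissues))
  for (ti in seq_along(design$tissues)) {
    tissue <- design$tissues[ti]
    row <- cfg$tissue_params[cfg$tissue_params$tissue == tissue, , drop = FALSE]
    if (nrow(row) != 1L)
      stop_input("no tissue_params entry for tissue '", tissue, "'")
    n_a <- round(row$frac_androgen * n)
    n_both <- round(row$overlap_follistatin * n_a)
    n_fonly <- round(row$frac_follistatin_only * n)
    if (n_a + n_fonly > n) stop_input("sensitive fractions exceed gene count")
    idx <- sample.int(n, n_a + n_fonly)
    a_idx <- idx[seq_len(n_a)]
    both_idx <- a_idx[seq_len(n_both)]
    fonly_idx <- if (n_fonly > 0) idx[n_a + seq_len(n_fonly)] else integer(0)
    f_idx <- c(both_idx, fonly_idx)

    d_cx <- d_t <- d_f <- numeric(n)
    affected <- union(a_idx, f_idx)
    d_cx[affected] <- draw_effect(length(affected), cfg)
    # Restoration effects oppose the castration effect, as for a gene whose
    # expression is hormone-maintained (down on castration, back up on
    # treatment) or hormone-repressed (the mirror image).
    d_t[a_idx] <- draw_effect(length(a_idx), cfg, sign = -sign(d_cx[a_idx]))
    d_f[f_idx] <- draw_effect(length(f_idx), cfg, sign = -sign(d_cx[f_idx]))

    sigma2 <- if (cfg$var_prior_scale == 0) rep(0, n) else
      cfg$var_prior_scale * cfg$var_prior_df /
        stats::rchisq(n, df = cfg$var_prior_df)
    out[[ti]] <- data.frame(
      gene_id = genes, tissue = tissue,
      delta_cx = d_cx, delta_t = d_t, delta_f = d_f,
      sigma = sqrt(sigma2),
      is_androgen_sensitive = d_cx != 0 & d_t != 0,
      is_follistatin_sensitive = d_cx != 0 & d_f != 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic log2 expression matrix with planted effects
#'
#' Per-gene condition means are baseline + castration effect (cx, cx_T, cx_F
#' groups) + restoration effect (cx_T) or follistatin effect (cx_F); i.i.d.
#' normal noise with per-gene sd is added. The same seed reproduces the output
#' bit for bit.
#'
#' @param design a [study_design()].
#' @param cfg a [synth_config()].
#' @return list with `expr` (genes x samples log2 matrix), `samples`
#'   (data.frame: sample_id, tissue, condition, replicate) and `truth`
#'   (per gene x tissue effect sizes, residual sd, sensitivity flags).
#' @export
generate_expression <- function(design = study_design(),
                                cfg = synth_config()) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "synth_config"))
  with_seed(cfg$seed + SEED_OFFSET_EXPRESSION, {
    truth <- make_effect_truth(design, cfg)
    genes <- unique(truth$gene_id)
    n <- length(genes)
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

    samples <- expand.grid(
      replicate = seq_len(design$replicates_per_group),
      condition = design$conditions,
      tissue = design$tissues,
      stringsAsFactors = FALSE)[, c("tissue", "condition", "replicate")]
    samples$sample_id <- sprintf("%s.%s.r%d", samples$tissue,
                                 samples$condition, samples$replicate)

    expr <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
    for (tissue in design$tissues) {
      tt <- truth[truth$tissue == tissue, ]
      tt <- tt[match(genes, tt$gene_id), ]
      means <- cbind(
        sham = baseline,
        cx   = baseline + tt$delta_cx,
        cx_T = baseline + tt$delta_cx + tt$delta_t,
        cx_F = baseline + tt$delta_cx + tt$delta_f)
      for (cond in design$conditions) {
        cols <- samples$tissue == tissue & samples$condition == cond
        nrep <- sum(cols)
        noise <- matrix(stats::rnorm(n * nrep, 0, tt$sigma), n, nrep)
        expr[, cols] <- means[, cond] + noise
      }
    }
    list(expr = expr, samples = samples, truth = truth)
  })
}
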