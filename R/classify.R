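# Dual-contrast sensitivity classification and Venn partition.

#' Call androgen- and follistatin-sensitive genes
#'
#' A gene is androgen-sensitive when it is differentially expressed (q below
#' the threshold, strict) in both the castrated-vs-sham and the
#' testosterone-vs-castrated comparison; follistatin-sensitive when q is
#' below the threshold in both castrated-vs-sham and
#' follistatin-vs-castrated. The castration contrast is shared by both
#' definitions. No fold-change direction consistency is required by default;
#' `require_direction = TRUE` additionally demands that the restoration
#' contrast oppose the castration contrast in sign.
#'
#' @param results named list of the three contrast tables (from
#'   [run_differential_expression()]); every gene must appear in all three.
#' @param q_threshold strict q-value cutoff, in (0, 1] (default 0.2).
#' @param require_direction require sign(log2fc restoration) ==
#'   -sign(log2fc castration) on top of the q rule (default FALSE).
#' @return data.frame: gene_id, tissue, androgen_sensitive,
#'   follistatin_sensitive, category (uniquely_androgen,
#'   uniquely_follistatin, both, neither).
#' @export
classify_sensitivity <- function(results, q_threshold = 0.2,
                                 require_direction = FALSE) {
  if (!all(c("cx_vs_sham", "T_vs_cx", "F_vs_cx") %in% names(results)))
    stop_input("results must contain cx_vs_sham, T_vs_cx and F_vs_cx")
  if (!(q_threshold > 0 && q_threshold <= 1))
    stop_input("q_threshold must lie in (0, 1]")
  cx <- results$cx_vs_sham
  genes <- cx$gene_id
  align <- function(tab) {
    i <- match(genes, tab$gene_id)
    if (anyNA(i)) stop_input("gene(s) missing from a comparison table")
    tab[i, ]
  }
  tr <- align(results$T_vs_cx)
  fr <- align(results$F_vs_cx)

  a <- cx$q < q_threshold & tr$q < q_threshold
  f <- cx$q < q_threshold & fr$q < q_threshold
  if (require_direction) {
    a <- a & sign(tr$log2fc) == -sign(cx$log2fc)
    f <- f & sign(fr$log2fc) == -sign(cx$log2fc)
  }
  category <- ifelse(a & f, "both",
              ifelse(a, "uniquely_androgen",
              ifelse(f, "uniquely_follistatin", "neither")))
  data.frame(gene_id = genes,
             tissue = cx$tissue %||% NA_character_,
             androgen_sensitive = a,
             follistatin_sensitive = f,
             category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Venn counts of sensitivity calls
#'
#' @param calls output of [classify_sensitivity()], one row per gene.
#' @return list with `n_androgen`, `n_follistatin`, `n_both`.
#' @export
venn_partition <- function(calls) {
  if (anyDuplicated(calls$gene_id))
    stop_input("duplicate gene ids in sensitivity calls")
  list(n_androgen = sum(calls$androgen_sensitive),
       n_follistatin = sum(calls$follistatin_sensitive),
       n_both = sum(calls$androgen_sensitive & calls$follistatin_sensitive))
}
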