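# Hypergeometric over-representation scoring of gene sets against the
# propagated ontology annotations.

#' Upper-tail hypergeometric probability
#'
#' P(X >= x) when drawing k genes without replacement from a universe of n
#' genes of which m carry the term:
#' sum_{j=x}^{min(m,k)} C(m,j) C(n-m,k-j) / C(n,k), accumulated in log space
#' for numerical stability.
#'
#' @param x observed count of selected genes carrying the term.
#' @param k number of selected genes.
#' @param m genes carrying the term in the universe.
#' @param n universe size (genes with any annotation).
#' @return p in \[0, 1\]; exactly 1 when `x == 0`.
#' @export
hypergeom_p <- function(x, k, m, n) {
  v <- c(x = x, k = k, m = m, n = n)
  if (any(!is.finite(v)) || any(v != round(v)) || any(v < 0))
    stop_input("x, k, m, n must be non-negative integers")
  if (m > n || k > n) stop_input("require m <= n and k <= n")
  if (x > min(m, k)) stop_input("x cannot exceed min(m, k)")
  if (x == 0) return(1)
  j <- x:min(m, k)
  lt <- lchoose(m, j) + lchoose(n - m, k - j) - lchoose(n, k)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' GO-term over-representation of a selected gene set
#'
#' For every term retained by the frequency filter, counts m (genes
#' annotated to the term over the whole annotated universe), n (genes with
#' any annotation), k (selected genes within that universe) and x (selected
#' genes annotated to the term), scores the upper hypergeometric tail, and
#' adjusts across retained terms. Selected genes outside the annotated
#' universe are dropped with a warning.
#'
#' @param selected character vector of selected gene ids.
#' @param ann an `annotation_set` from [propagate_annotations()].
#' @param dag a [go_dag()] (for term names).
#' @param min_excl,max_excl frequency-filter bounds (see [filter_terms()]).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param alpha reporting threshold on the adjusted p (default exp(-3), i.e.
#'   about 0.0498).
#' @return data.frame sorted by adjusted then raw p: term_id, name, m, n, k,
#'   x, p_raw, p_adjusted, significant.
#' @export
enrich_terms <- function(selected, ann, dag,
                         min_excl = 5L, max_excl = 300L,
                         adjust = c("BH", "bonferroni"),
                         alpha = exp(-3)) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ann, "annotation_set"), inherits(dag, "go_dag"))
  selected <- unique(selected)
  outside <- setdiff(selected, ann$universe)
  if (length(outside)) {
    warning(length(outside),
            " selected gene(s) outside the annotated universe were dropped")
    selected <- setdiff(selected, outside)
  }
  cols <- c("term_id", "name", "m", "n", "k", "x", "p_raw", "p_adjusted",
            "significant")
  if (!length(selected)) {
    warning("empty selected gene set; no enrichment computed")
    empty <- data.frame(term_id = character(0), name = character(0),
                        m = integer(0), n = integer(0), k = integer(0),
                        x = integer(0), p_raw = numeric(0),
                        p_adjusted = numeric(0), significant = logical(0))
    return(empty[, cols])
  }
  terms <- filter_terms(ann, min_excl, max_excl)
  n <- length(ann$universe)
  k <- length(selected)
  sel_terms <- unlist(ann$closure[selected], use.names = FALSE)
  x_tab <- table(factor(sel_terms, levels = terms))
  res <- data.frame(
    term_id = terms,
    name = dag$terms$name[match(terms, dag$terms$id)],
    m = as.integer(ann$term_counts[terms]),
    n = n, k = k,
    x = as.integer(x_tab[terms]),
    stringsAsFactors = FALSE)
  res$p_raw <- vapply(seq_len(nrow(res)), function(i)
    hypergeom_p(res$x[i], res$k[i], res$m[i], res$n[i]), numeric(1))
  res$p_adjusted <- if (adjust == "BH") bh_adjust(res$p_raw) else
    pmin(1, res$p_raw * nrow(res))
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_adjusted, res$p_raw, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Collapse probeset-level results to gene level
#'
#' When several probesets map to one gene, the probeset with the smallest
#' q-value represents the gene.
#'
#' @param tab data.frame with `gene_id` (probeset id) and `q`.
#' @param map named character vector: probeset id -> gene id. Probesets
#'   absent from the map keep their own id.
#' @return `tab` with `gene_id` replaced by gene ids, one row per gene.
#' @export
collapse_probesets <- function(tab, map) {
  gene <- ifelse(tab$gene_id %in% names(map), map[tab$gene_id], tab$gene_id)
  tab$gene_id <- unname(gene)
  tab <- tab[order(tab$q), ]
  tab <- tab[!duplicated(tab$gene_id), ]
  rownames(tab) <- NULL
  tab
}
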