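#' Construct a GO DAG object
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list: term id -> character vector of direct (is_a)
#'   parent ids. The root has no parents.
#' @return A `go_dag` with a computed topological order and designated root.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in%
                                        names(terms)))
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) as.character(p %||% character(0)))
  unknown <- setdiff(unlist(parents), terms$id)
  if (length(unknown))
    stop_input("is_a parent(s) not among terms: ",
               paste(unknown, collapse = ", "))
  roots <- terms$id[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop_input("ontology must have exactly one root term (found ",
               length(roots), ")")
  topo <- topo_sort(terms$id, parents)
  structure(list(terms = terms, parents = parents, root = roots,
                 topo = topo),
            class = "go_dag")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kahn topological sort, parents before children; errors on cycles.
topo_sort <- function(ids, parents) {
  remaining <- lengths(parents)
  names(remaining) <- ids
  children <- split(rep(names(parents), lengths(parents)), unlist(parents))
  order <- character(0)
  queue <- ids[remaining == 0L]
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    order <- c(order, id)
    for (ch in children[[id]] %||% character(0)) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(ids))
    stop_input("cycle detected in ontology is_a graph")
  order
}

#' Generate a random rooted ontology and sparse gene annotations
#'
#' Builds a random acyclic is_a hierarchy under a single biological_process
#' root (every non-root term has one or two parents among earlier terms, so
#' depth grows and terms gain specificity away from the root), then annotates
#' genes directly to a small number of non-root terms.
#'
#' @param n_terms total number of terms including the root (>= 2).
#' @param n_genes number of genes in the universe.
#' @param cfg a [synth_config()]; uses `annot_prob` and `seed`.
#' @param genes optional character vector of gene ids.
#' @return list with `dag` (a [go_dag()]) and `annotations` (data.frame:
#'   gene_id, term_id — direct annotations only).
#' @export
generate_ontology <- function(n_terms, n_genes, cfg = synth_config(),
                              genes = NULL) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 2L) stop_input("n_terms must be >= 2")
  if (is.null(genes)) genes <- sprintf("gene_%05d", seq_len(n_genes))
  ids <- c("GO:0008150", sprintf("GO:%07d", 1000000L + seq_len(n_terms - 1L)))
  nms <- c("biological_process",
           sprintf("synthetic process %d", seq_len(n_terms - 1L)))
  dag <- with_seed(cfg$seed + SEED_OFFSET_ONTOLOGY, {
    parents <- vector("list", n_terms)
    for (i in seq_len(n_terms)[-1L]) {
      k <- min(i - 1L, 1L + stats::rbinom(1L, 1L, 0.3))
      parents[[i]] <- ids[sample.int(i - 1L, k)]
    }
    names(parents) <- ids
    go_dag(data.frame(id = ids, name = nms,
                      namespace = "biological_process",
                      stringsAsFactors = FALSE),
           parents)
  })
  ann <- with_seed(cfg$seed + SEED_OFFSET_ANNOTATION, {
    annotated <- genes[stats::runif(length(genes)) < cfg$annot_prob]
    n_direct <- pmin(1L + stats::rpois(length(annotated), 0.8), 3L)
    data.frame(
      gene_id = rep(annotated, n_direct),
      term_id = ids[1L + sample.int(n_terms - 1L, sum(n_direct),
                                    replace = TRUE)],
      stringsAsFactors = FALSE)
  })
  ann <- unique(ann)
  ann <- ann[order(ann$gene_id, ann$term_id), ]
  rownames(ann) <- NULL
  list(dag = dag, annotations = ann)
}
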