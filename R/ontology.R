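# Ontology parsing, annotation propagation and term-frequency filtering.

#' Parse a (minimal) OBO ontology restricted to biological_process
#'
#' Reads `[Term]` stanzas (id, name, namespace, is_a, is_obsolete), drops
#' obsolete terms and terms outside the biological_process namespace together
#' with their edges, and validates acyclicity and the existence of a single
#' root.
#'
#' @param path OBO 1.2/1.4 file.
#' @return A [go_dag()].
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop_input("no stanzas found in OBO file")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    field <- function(key) {
      v <- sub(paste0("^", key, ": "), "",
               grep(paste0("^", key, ": "), body, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing comments
    }
    if (any(field("is_obsolete") == "true")) next
    id <- field("id")
    if (length(id) != 1L) stop_input("term stanza without a single id")
    terms[[length(terms) + 1L]] <-
      list(id = id,
           name = if (length(field("name"))) field("name")[1L] else id,
           namespace = if (length(field("namespace")))
             field("namespace")[1L] else NA_character_,
           is_a = field("is_a"))
  }
  ns <- vapply(terms, `[[`, "", "namespace")
  terms <- terms[!is.na(ns) & ns == "biological_process"]
  if (!length(terms)) stop_input("no biological_process terms in OBO file")
  ids <- vapply(terms, `[[`, "", "id")
  keep <- function(p) p[p %in% ids]  # drop edges into removed namespaces
  parents <- stats::setNames(lapply(terms, function(t) keep(t$is_a)), ids)
  go_dag(data.frame(id = ids,
                    name = vapply(terms, `[[`, "", "name"),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         parents)
}

#' Parse direct gene-to-term annotations
#'
#' Two formats: `two_column` (tab-delimited gene_id, term_id with a header)
#' and `gaf` (GAF 2.x, 17 tab-separated columns; comment lines start with
#' `!`; rows whose qualifier contains NOT are excluded). Duplicate pairs
#' collapse to one.
#'
#' @param path annotation file.
#' @param format `"two_column"` or `"gaf"`.
#' @return data.frame: gene_id, term_id (direct annotations).
#' @export
parse_annotations <- function(path, format = c("two_column", "gaf")) {
  format <- match.arg(format)
  if (format == "two_column") {
    ann <- read_tsv(path)[, c("gene_id", "term_id")]
  } else {
    lines <- grep("^!", readLines(path), value = TRUE, invert = TRUE)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    # column count from delimiters: trailing columns may legitimately be
    # empty and strsplit drops them
    nf <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
    if (any(nf != 17L))
      stop_input("malformed GAF: expected 17 columns, found ",
                 paste(unique(nf[nf != 17L]), collapse = ", "))
    fields <- lapply(fields, function(f) c(f, rep("", 17L - length(f))))
    qualifier <- vapply(fields, `[[`, "", 4L)
    keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
    ann <- data.frame(gene_id = vapply(fields, `[[`, "", 3L)[keep],
                      term_id = vapply(fields, `[[`, "", 5L)[keep],
                      stringsAsFactors = FALSE)
  }
  ann <- unique(ann)
  ann <- ann[order(ann$gene_id, ann$term_id), ]
  rownames(ann) <- NULL
  ann
}

#' Ancestors of every term (is_a transitive closure)
#'
#' @param dag a [go_dag()].
#' @return Named list: term id -> character vector of all ancestors
#'   (excluding the term itself; empty for the root).
#' @export
term_ancestors <- function(dag) {
  anc <- stats::setNames(vector("list", nrow(dag$terms)), dag$terms$id)
  for (id in dag$topo) {  # parents are processed before children
    ps <- dag$parents[[id]]
    anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate direct annotations to all ancestor terms
#'
#' Each gene annotated to a term is subsumed by every ancestor of that term,
#' so the root ends up annotated to all annotated genes. Annotations to terms
#' absent from the DAG are reported and dropped.
#'
#' @param dag a [go_dag()].
#' @param direct data.frame with `gene_id`, `term_id`.
#' @return An `annotation_set`: list with `direct`, `closure` (named list
#'   gene -> term ids), `term_counts` (named integer vector over the
#'   closure), `universe` (annotated gene ids).
#' @export
propagate_annotations <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"))
  unknown <- setdiff(unique(direct$term_id), dag$terms$id)
  if (length(unknown)) {
    warning("dropping annotations to ", length(unknown),
            " term(s) absent from the ontology: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
    direct <- direct[!direct$term_id %in% unknown, ]
  }
  anc <- term_ancestors(dag)
  up <- lapply(stats::setNames(dag$terms$id, dag$terms$id),
               function(t) c(t, anc[[t]]))
  closure <- lapply(split(direct$term_id, direct$gene_id),
                    function(ts) unique(unlist(up[ts], use.names = FALSE)))
  counts <- table(unlist(closure, use.names = FALSE))
  term_counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(direct = direct, closure = closure,
                 term_counts = term_counts,
                 universe = names(closure)),
            class = "annotation_set")
}

#' Filter terms by annotation frequency
#'
#' Retains terms whose propagated gene count lies strictly between the
#' bounds (defaults: more than 5 and fewer than 300 genes). The root term,
#' annotated to every gene, is removed by the upper bound in any realistic
#' universe.
#'
#' @param ann an `annotation_set` from [propagate_annotations()].
#' @param min_excl,max_excl exclusive bounds on the per-term gene count.
#' @return Character vector of retained term ids.
#' @export
filter_terms <- function(ann, min_excl = 5L, max_excl = 300L) {
  if (min_excl >= max_excl) stop_input("require min_excl < max_excl")
  cnt <- ann$term_counts
  names(cnt)[cnt > min_excl & cnt < max_excl]
}
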