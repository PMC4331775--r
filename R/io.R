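# Tab-delimited readers/writers so every stage can run standalone on files.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a log2 expression matrix with sample metadata
#'
#' The matrix is written genes-in-rows, samples-in-columns with a leading
#' `gene_id` column; metadata (`sample_id`, `tissue`, `condition`,
#' `replicate`) goes to a companion table.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param samples sample metadata data.frame covering every column once.
#' @param path,meta_path output files (tab-delimited).
#' @return `write_expression` returns the paths invisibly; `read_expression`
#'   returns `list(expr, samples)`.
#' @export
write_expression <- function(expr, samples, path, meta_path) {
  stopifnot(identical(colnames(expr), samples$sample_id))
  write_tsv(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
            path)
  write_tsv(samples[, c("sample_id", "tissue", "condition", "replicate")],
            meta_path)
  invisible(c(path, meta_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(path, meta_path) {
  tab <- read_tsv(path)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab$gene_id
  samples <- read_tsv(meta_path)
  if (!identical(colnames(expr), samples$sample_id))
    stop_input("sample metadata does not match expression columns")
  list(expr = expr, samples = samples)
}

#' Write / read probe-level data
#'
#' Long layout: probe_id, probeset_id, then one intensity column per sample.
#'
#' @param pd a [probe_data()].
#' @param path tab-delimited output file.
#' @export
write_probe_data <- function(pd, path) {
  stopifnot(inherits(pd, "probe_data"))
  write_tsv(data.frame(probe_id = rownames(pd$intensity),
                       probeset_id = pd$probeset, pd$intensity,
                       check.names = FALSE), path)
}

#' @rdname write_probe_data
#' @export
read_probe_data <- function(path) {
  tab <- read_tsv(path)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab$probe_id
  probe_data(m, tab$probeset_id)
}

#' Write an ontology as a minimal OBO 1.2 file
#'
#' Emits term stanzas with id, name, namespace and is_a lines; parses back
#' with [parse_obo()].
#'
#' @param dag a [go_dag()].
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("ontology: synthetic-", dag$root), ""), con)
  nm <- stats::setNames(dag$terms$name, dag$terms$id)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 sprintf("is_a: %s ! %s", dag$parents[[id]],
                         nm[dag$parents[[id]]]),
                 ""), con)
  }
  invisible(path)
}

#' Write direct annotations as a two-column table or GAF 2.2
#'
#' @param ann data.frame with `gene_id`, `term_id`.
#' @param path output file.
#' @export
write_annotations <- function(ann, path) {
  write_tsv(ann[, c("gene_id", "term_id")], path)
}

#' @rdname write_annotations
#' @export
write_gaf <- function(ann, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  rows <- cbind("SYNTH", ann$gene_id, ann$gene_id, "involved_in",
                ann$term_id, "SYNTH:0000001", "IEA", "", "P",
                ann$gene_id, "", "protein", "taxon:10090", "20260101",
                "SYNTH", "", "")
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
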