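write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a minimal two-stanza OBO file parses into a two-node DAG", {
  path <- write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: child process",
    "namespace: biological_process", "is_a: GO:0008150 ! biological_process",
    ""))
  dag <- parse_obo(path)
  expect_equal(nrow(dag$terms), 2L)
  expect_equal(dag$root, "GO:0008150")
  expect_equal(dag$parents[["GO:0000001"]], "GO:0008150")
})

test_that("obsolete and non-biological_process terms are dropped with their edges", {
  path <- write_lines_tmp(c(
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: gone", "namespace: biological_process",
    "is_a: GO:0008150", "is_obsolete: true", "",
    "[Term]", "id: GO:0005575", "name: cellular_component",
    "namespace: cellular_component", "",
    "[Term]", "id: GO:0000003", "name: kept",
    "namespace: biological_process",
    "is_a: GO:0008150", "is_a: GO:0005575", ""))
  dag <- parse_obo(path)
  expect_setequal(dag$terms$id, c("GO:0008150", "GO:0000003"))
  expect_equal(dag$parents[["GO:0000003"]], "GO:0008150")
})

test_that("cyclic or rootless ontologies are format errors", {
  cyc <- write_lines_tmp(c(
    "[Term]", "id: GO:0008150", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000001", ""))
  expect_error(parse_obo(cyc), "root|cycle")
  two_roots <- write_lines_tmp(c(
    "[Term]", "id: GO:0008150", "name: r1",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: r2",
    "namespace: biological_process", ""))
  expect_error(parse_obo(two_roots), "root")
})

test_that("the OBO emitter and parser round-trip a generated DAG", {
  onto <- generate_ontology(40, 100, synth_config(seed = 4))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto$dag, path)
  back <- parse_obo(path)
  expect_equal(back$terms, onto$dag$terms, ignore_attr = TRUE)
  expect_equal(lapply(back$parents, sort), lapply(onto$dag$parents, sort))
})

test_that("GAF parsing obeys NOT qualifiers, duplicates and column counts", {
  onto <- generate_ontology(20, 30, synth_config(seed = 6))
  ann <- onto$annotations
  gaf <- withr::local_tempfile(fileext = ".gaf")
  write_gaf(ann, gaf)
  parsed <- parse_annotations(gaf, "gaf")
  expect_equal(parsed, ann)
  # two-column encoding of the same pairs is identical
  two <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, two)
  expect_equal(parse_annotations(two, "two_column"), parsed)
  # NOT rows excluded; duplicates collapse
  lines <- readLines(gaf)
  row1 <- strsplit(lines[2], "\t")[[1]]
  row1 <- c(row1, rep("", 17L - length(row1)))  # trailing empties
  not_row <- row1; not_row[4] <- "NOT|involved_in"
  writeLines(c(lines, paste(not_row, collapse = "\t"), lines[2]), gaf)
  expect_equal(parse_annotations(gaf, "gaf"), parsed)
  # malformed column count
  writeLines(c(lines, paste(row1[1:10], collapse = "\t")), gaf)
  expect_error(parse_annotations(gaf, "gaf"), "17 columns")
})

test_that("propagation covers chains, diamonds and drops unknown terms", {
  dag <- go_dag(
    data.frame(id = c("root", "A", "B", "L", "R", "D"),
               name = c("root", "A", "B", "L", "R", "D"),
               namespace = "biological_process"),
    list(root = character(0), A = "root", B = "A",
         L = "root", R = "root", D = c("L", "R")))
  ann <- propagate_annotations(dag, data.frame(gene_id = c("g1", "g2"),
                                               term_id = c("B", "D")))
  expect_setequal(ann$closure$g1, c("B", "A", "root"))
  expect_setequal(ann$closure$g2, c("D", "L", "R", "root"))
  expect_equal(unname(ann$term_counts["root"]), 2L)
  expect_warning(
    propagate_annotations(dag, data.frame(gene_id = "g3", term_id = "nope")),
    "absent from the ontology")
})

test_that("closure matches the transitive-closure matrix oracle on random DAGs", {
  for (seed in 1:5) {
    onto <- generate_ontology(50, 120, synth_config(seed = seed))
    ann <- propagate_annotations(onto$dag, onto$annotations)
    reach <- oracle_reachability(onto$dag)
    direct <- split(onto$annotations$term_id, onto$annotations$gene_id)
    for (g in names(direct)) {
      expected <- colnames(reach)[colSums(
        reach[direct[[g]], , drop = FALSE]) > 0]
      expect_setequal(ann$closure[[g]], expected)
    }
    # idempotence: propagating the closure adds nothing
    closure_df <- data.frame(
      gene_id = rep(names(ann$closure), lengths(ann$closure)),
      term_id = unlist(ann$closure, use.names = FALSE))
    again <- propagate_annotations(onto$dag, closure_df)
    expect_equal(lapply(again$closure, sort), lapply(ann$closure, sort))
    # counts are monotone along is_a edges
    for (id in onto$dag$terms$id) {
      cnt <- function(t) sum(ann$term_counts[t], na.rm = TRUE)
      for (p in onto$dag$parents[[id]]) expect_gte(cnt(p), cnt(id))
    }
    expect_true(all(vapply(ann$closure, function(ts)
      onto$dag$root %in% ts, logical(1))))
  }
})

test_that("the frequency filter applies strict bounds on propagated counts", {
  counts <- c(a = 5L, b = 6L, c = 299L, d = 300L, root = 1000L)
  ann <- structure(list(term_counts = counts), class = "annotation_set")
  expect_setequal(filter_terms(ann), c("b", "c"))
  expect_error(filter_terms(ann, 10, 10), "min_excl < max_excl")
})
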