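test_that("OBO parsing captures is_a and part_of edges and drops obsoletes", {
  dag <- load_obo(toy_path("ontology.obo"))
  expect_setequal(names(dag$roots),
                  c("biological_process", "cellular_component",
                    "molecular_function"))
  expect_equal(dag$parents[["GO:0006979"]], "GO:0050896")
  # part_of edge present in parents and remembered as part_of
  expect_equal(dag$parents[["GO:0031090"]], "GO:0016020")
  expect_equal(dag$partof[["GO:0031090"]], "GO:0016020")
  expect_false("GO:0099999" %in% names(dag$name)) # obsolete dropped
  expect_equal(unname(dag$name["GO:0008152"]), "metabolic process")
})

test_that("OBO parse agrees with a naive line-oriented re-parse", {
  # independent oracle: regex scan of the raw file
  lines <- readLines(toy_path("ontology.obo"))
  starts <- which(lines == "[Term]")
  ends <- c(starts[-1L] - 1L, length(lines))
  oracle <- list()
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    if (any(grepl("^is_obsolete: true", blk))) next
    id <- sub("^id: ", "", grep("^id: ", blk, value = TRUE))
    isa <- sub("^is_a: (GO:[0-9]+).*$", "\\1",
               grep("^is_a: ", blk, value = TRUE))
    po <- sub("^relationship: part_of (GO:[0-9]+).*$", "\\1",
              grep("^relationship: part_of ", blk, value = TRUE))
    oracle[[id]] <- sort(c(isa, po))
  }
  dag <- load_obo(toy_path("ontology.obo"))
  expect_setequal(names(dag$name), names(oracle))
  for (id in names(oracle)) {
    expect_equal(sort(dag$parents[[id]]), oracle[[id]], label = id)
  }
})

test_that("cyclic or mis-namespaced ontologies are rejected", {
  cyc <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: a",
    "namespace: biological_process", "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "name: b",
    "namespace: biological_process", "is_a: GO:0000001", ""
  ))
  expect_error(load_obo(cyc), "cycle")
  bad_ns <- withr::local_tempfile(lines = c(
    "[Term]", "id: GO:0000001", "name: a", "namespace: made_up_process", ""
  ))
  expect_error(load_obo(bad_ns), "unknown namespace")
})

test_that("ancestor closure is reflexive and follows the hierarchy", {
  dag <- load_obo(toy_path("ontology.obo"))
  expect_equal(ancestors(dag, "GO:0008150"), "GO:0008150") # root
  # a hit low in the DAG marks its whole chain up to the namespace root
  expect_equal(ancestors(dag, "GO:0006979"),
               c("GO:0006979", "GO:0008150", "GO:0050896"))
  expect_error(ancestors(dag, "GO:4999999"), "unknown term")
  # diamond: a -> {b, c} -> d
  ids <- sprintf("GO:%07d", 1:4)
  dm <- fracres:::new_go_dag(
    stats::setNames(letters[1:4], ids),
    stats::setNames(rep("biological_process", 4), ids),
    stats::setNames(list(c(ids[2], ids[3]), ids[4], ids[4], character(0)),
                    ids)
  )
  expect_equal(ancestors(dm, ids[1]), ids)
})

test_that("ancestors matches igraph reachability on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:50) {
    dag <- random_dag(sample(5:50, 1L))
    term <- sample(names(dag$name), 1L)
    expect_equal(ancestors(dag, term), oracle_ancestors(dag, term))
  }
})

test_that("no ancestor chain crosses namespaces", {
  dag <- load_obo(toy_path("ontology.obo"))
  for (id in names(dag$name)) {
    anc <- ancestors(dag, id)
    expect_length(unique(dag$namespace[anc]), 1L)
  }
})

test_that("set annotation is the union of member-gene closures", {
  dag <- load_obo(toy_path("ontology.obo"))
  sets <- compute_F(read_homology_sets(toy_path("homology_sets.tsv")))
  hits <- read_gene_annotations(toy_path("annotations.tsv"))
  ann <- annotate_sets(sets, hits, dag)
  expect_equal(ann$set_terms[["s01"]],
               c("GO:0006979", "GO:0008150", "GO:0050896"))
  expect_equal(ann$set_terms[["s09"]], character(0)) # unannotated set
  # genes inherit their set-level terms, even unannotated members
  expect_equal(ann$gene_terms[["s01C2"]], ann$set_terms[["s01"]])
  # brute-force union-of-closures oracle over the whole collection
  expect_equal(ann$set_terms[sets$set_id], oracle_set_terms(sets, hits, dag))
})

test_that("annotation propagation is idempotent and warns on unknown genes", {
  dag <- load_obo(toy_path("ontology.obo"))
  sets <- compute_F(read_homology_sets(toy_path("homology_sets.tsv")))
  hits <- read_gene_annotations(toy_path("annotations.tsv"))
  ann <- annotate_sets(sets, hits, dag)
  again <- annotate_sets(sets, ann$gene_terms, dag)
  expect_equal(again$set_terms, ann$set_terms)
  expect_equal(again$gene_terms, ann$gene_terms)
  hits$phantom_gene <- "GO:0006979"
  expect_warning(annotate_sets(sets, hits, dag), "absent from the homology")
})

test_that("top-level categories are the sorted depth-1 children of a root", {
  dag <- load_obo(toy_path("ontology.obo"))
  expect_equal(top_level_categories(dag, "biological_process"),
               c("GO:0008152", "GO:0050896"))
  expect_equal(top_level_categories(dag, "molecular_function"), "GO:0003824")
  # oracle: scan all terms whose parents contain the root
  for (ns in names(dag$roots)) {
    root <- dag$roots[[ns]]
    expect_equal(
      top_level_categories(dag, ns),
      sort(names(Filter(function(p) root %in% p, dag$parents)))
    )
  }
})

test_that("a DAG round-trips through write_obo/load_obo", {
  dag <- toy_go_dag(n_categories = 3L)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- load_obo(path)
  expect_equal(back$name, dag$name)
  expect_equal(back$namespace, dag$namespace)
  expect_equal(lapply(back$parents, sort), lapply(dag$parents, sort))
  expect_equal(back$roots, dag$roots)
  expect_equal(Filter(length, back$partof), Filter(length, dag$partof))
})
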