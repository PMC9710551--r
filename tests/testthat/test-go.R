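# OBO parsing, ancestor closure, leaf filtering and function encoding.

toy_obo <- function(extra = character(0)) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "namespace: molecular_function",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "namespace: molecular_function",
    "alt_id: GO:0009999", "is_a: GO:0000002", "",
    extra), path)
  path
}

test_that("parse_obo builds nodes, edges, alt ids and obsolete flags", {
  dag <- parse_obo(toy_obo())
  expect_length(dag$namespace, 3L)
  expect_identical(unname(dag$namespace[["GO:0000002"]]), "MF")
  expect_identical(dag$parents_isa[["GO:0000003"]], "GO:0000002")
  expect_identical(resolve_term(dag, "GO:0009999"), "GO:0000003")
  expect_identical(resolve_term(dag, "GO:404"), NA_character_)

  dag2 <- parse_obo(toy_obo(c("[Term]", "id: GO:0000004",
                              "namespace: molecular_function",
                              "is_obsolete: true")))
  expect_true(dag2$obsolete[["GO:0000004"]])
})

test_that("cyclic ontologies are rejected with a named cycle", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "namespace: molecular_function",
               "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "namespace: molecular_function",
               "is_a: GO:0000001"), path)
  expect_error(parse_obo(path), "cyclic", class = "savanno_parse")
})

test_that("OBO round trip preserves ancestor sets (closure oracle)", {
  for (seed in 1:8) {
    dag <- random_dag(n_terms = sample(5:20, 1), p_edge = 0.25, seed = seed)
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(dag, path)
    back <- parse_obo(path)
    for (id in names(dag$namespace)) {
      expect_setequal(go_ancestors(back, id), closure_ancestors(dag, id))
    }
  }
})

test_that("leaf_filter retains only non-ancestor terms", {
  dag <- parse_obo(toy_obo())
  expect_identical(leaf_filter(c("GO:0000002", "GO:0000003"), dag), "GO:0000003")
  expect_identical(leaf_filter("GO:0000002", dag), "GO:0000002")
  # alt ids resolve before filtering
  expect_identical(leaf_filter(c("GO:0000002", "GO:0009999"), dag), "GO:0000003")
  # unknown terms are dropped, not raised
  expect_identical(suppressMessages(leaf_filter(c("GO:404", "GO:0000003"), dag)),
                   "GO:0000003")
})

test_that("leaf_filter is idempotent and matches brute force (random DAGs)", {
  for (seed in 1:10) {
    dag <- random_dag(n_terms = 15, p_edge = 0.2, seed = seed)
    ids <- names(dag$namespace)
    set.seed(seed + 100)
    terms <- sample(ids, sample(2:10, 1))
    ours <- leaf_filter(terms, dag)
    # brute force: drop terms that are ancestors (closure oracle) of others
    anc_union <- unique(unlist(lapply(terms, closure_ancestors, dag = dag)))
    brute <- setdiff(terms, anc_union)
    expect_setequal(ours, brute)
    expect_identical(leaf_filter(ours, dag), ours)
  }
})

test_that("part_of participates in ancestor closure unless disabled", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "namespace: cellular_component", "",
               "[Term]", "id: GO:0000002", "namespace: cellular_component",
               "relationship: part_of GO:0000001"), path)
  dag <- parse_obo(path)
  expect_identical(go_ancestors(dag, "GO:0000002"), "GO:0000001")
  expect_identical(go_ancestors(dag, "GO:0000002", use_part_of = FALSE), character(0))
  expect_identical(leaf_filter(c("GO:0000001", "GO:0000002"), dag), "GO:0000002")
  expect_setequal(leaf_filter(c("GO:0000001", "GO:0000002"), dag, use_part_of = FALSE),
                  c("GO:0000001", "GO:0000002"))
})

make_table <- function(ids, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(ids) * k), nrow = length(ids), dimnames = list(ids, NULL))
  class(m) <- c("term_vector_table", class(m))
  m
}

test_that("encode_go averages leaf vectors per namespace with zero fallback", {
  dag <- parse_obo(toy_obo())
  tab <- make_table(c("GO:0000001", "GO:0000002", "GO:0000003"), k = 5)

  p0 <- protein_record("P0", "MKV")
  expect_identical(as.numeric(encode_go(p0, dag, tab)), rep(0, 15))

  p1 <- protein_record("P1", "MKV", go_terms = list(MF = "GO:0000003"))
  enc1 <- encode_go(p1, dag, tab)
  expect_equal(as.numeric(enc1), c(tab["GO:0000003", ], rep(0, 10)))

  # two MF leaves -> arithmetic mean (hand oracle); sibling leaves needed
  dag2 <- parse_obo(toy_obo(c("[Term]", "id: GO:0000005",
                              "namespace: molecular_function",
                              "is_a: GO:0000002")))
  tab2 <- make_table(c("GO:0000003", "GO:0000005"), k = 4)
  p2 <- protein_record("P2", "MKV",
                       go_terms = list(MF = c("GO:0000003", "GO:0000005")))
  enc2 <- encode_go(p2, dag2, tab2)
  expect_equal(as.numeric(enc2)[1:4],
               (tab2["GO:0000003", ] + tab2["GO:0000005", ]) / 2,
               ignore_attr = TRUE)
})

test_that("encode_go is order-invariant and absorbs ancestors", {
  dag <- parse_obo(toy_obo(c("[Term]", "id: GO:0000005",
                             "namespace: molecular_function",
                             "is_a: GO:0000002")))
  tab <- make_table(sprintf("GO:%07d", 1:5), k = 6)
  a <- protein_record("A", "MKV", go_terms = list(MF = c("GO:0000003", "GO:0000005")))
  b <- protein_record("B", "MKV", go_terms = list(MF = c("GO:0000005", "GO:0000003")))
  expect_equal(as.numeric(encode_go(a, dag, tab)), as.numeric(encode_go(b, dag, tab)))
  # adding the shared parent changes nothing
  c_ <- protein_record("C", "MKV",
                       go_terms = list(MF = c("GO:0000003", "GO:0000005", "GO:0000002")))
  expect_equal(as.numeric(encode_go(c_, dag, tab)), as.numeric(encode_go(a, dag, tab)))
})

test_that("encoding length is 3x the table width (property)", {
  dag <- parse_obo(toy_obo())
  for (k in c(1, 7, 200)) {
    tab <- make_table("GO:0000003", k = k)
    p <- protein_record("P", "MKV", go_terms = list(MF = "GO:0000003"))
    expect_length(encode_go(p, dag, tab), 3 * k)
  }
})

test_that("term-vector and annotation files round-trip", {
  d <- withr::local_tempdir()
  tab <- make_table(c("GO:0000001", "GO:0000003"), k = 4)
  write_term_vectors(tab, file.path(d, "tv.tsv"))
  back <- read_term_vectors(file.path(d, "tv.tsv"))
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(tab))

  dag <- parse_obo(toy_obo())
  prots <- list(protein_record("P1", "MKV"))
  apath <- file.path(d, "ann.tsv")
  writeLines(c("accession\tgo_id", "P1\tGO:0000003;GO:0009999"), apath)
  annotated <- read_annotations(apath, prots, dag)
  expect_identical(annotated$P1$go_terms$MF, "GO:0000003")
})
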