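test_that("loading consistent node/edge tables yields exact collection counts", {
  kg <- toy_kg()
  mg <- meta_graph(kg)
  counts <- setNames(mg$nodes$count, mg$nodes$node_type)
  expect_equal(counts[["Drug"]], 2L)
  expect_equal(counts[["Signature"]], 3L)
  expect_equal(counts[["Gene"]], 4L)
  expect_equal(counts[["Cell"]], 1L)
  expect_equal(counts[["Concept"]], 1L)
  ecounts <- setNames(mg$edges$count, mg$edges$edge_type)
  expect_equal(ecounts[["SIGNATURE_GENE"]], 4L)
  expect_equal(ecounts[["CELL_SIGNATURE"]], 3L)
  expect_equal(ecounts[["DRUG_SIGNATURE"]], 3L)
  expect_equal(ecounts[["INDICATION"]], 2L)
})

test_that("meta_graph of an empty graph is empty", {
  kg <- kgap_graph()
  mg <- meta_graph(kg)
  expect_equal(nrow(mg$nodes), 0L)
  expect_equal(nrow(mg$edges), 0L)
})

test_that("edges referencing unknown nodes are integrity errors naming the id", {
  expect_error(
    kgap_graph(
      drugs = data.frame(drug_id = "d1", name = "alpha"),
      signatures = data.frame(signature_id = "s1", cell_id = "c1"),
      cells = data.frame(cell_id = "c1"),
      drug_signature = data.frame(drug_id = "d1", signature_id = "sGHOST")
    ),
    "integrity error.*sGHOST"
  )
  expect_error(
    kgap_graph(
      signatures = data.frame(signature_id = "s1", cell_id = "cGHOST")
    ),
    "integrity error.*cGHOST"
  )
})

test_that("schema, parse and duplicate-edge errors are reported", {
  expect_error(
    kgap_graph(drugs = data.frame(name = "alpha")),
    "schema error.*drug_id"
  )
  expect_error(
    kgap_graph(
      genes = data.frame(gene_id = "g1", symbol = "A"),
      signatures = data.frame(signature_id = "s1", cell_id = "c1"),
      cells = data.frame(cell_id = "c1"),
      signature_gene = data.frame(signature_id = "s1", gene_id = "g1",
                                  z = "not-a-number")
    ),
    "parse error"
  )
  dup <- data.frame(drug_id = c("d1", "d1"), signature_id = c("s1", "s1"))
  base <- list(
    drugs = data.frame(drug_id = "d1", name = "alpha"),
    signatures = data.frame(signature_id = "s1", cell_id = "c1"),
    cells = data.frame(cell_id = "c1")
  )
  expect_error(do.call(kgap_graph, c(base, list(drug_signature = dup))),
               "duplicate")
  deduped <- do.call(kgap_graph, c(base, list(drug_signature = dup,
                                              dedup = TRUE)))
  expect_equal(nrow(deduped$edges$drug_signature), 1L)
})

test_that("in_lincs is derived from DRUG_SIGNATURE degree and checked when supplied", {
  kg <- toy_kg()
  expect_true(all(kg$nodes$drug$in_lincs))
  solo <- kgap_graph(
    drugs = data.frame(drug_id = c("d1", "d2"), name = c("a", "b")),
    signatures = data.frame(signature_id = "s1", cell_id = "c1"),
    cells = data.frame(cell_id = "c1"),
    drug_signature = data.frame(drug_id = "d1", signature_id = "s1")
  )
  expect_equal(solo$nodes$drug$in_lincs, c(TRUE, FALSE))
  expect_error(toy_kg(in_lincs = c(TRUE, FALSE)),
               "in_lincs flag disagrees")
})

test_that("export/load round-trip reproduces the graph exactly", {
  dir <- withr::local_tempdir()
  kg <- toy_kg(z = c(4.2, -3.5, 1.0, pi * 1e-7))
  load_back <- load_graph(dir = export_graph(kg, dir))
  expect_identical(meta_graph(load_back), meta_graph(kg))
  expect_identical(load_back$edges$signature_gene$z,
                   kg$edges$signature_gene$z)

  sim <- generate_graph(synthetic_spec(n_genes = 200, edge_density = 0.25,
                                       seed = 11))
  dir2 <- withr::local_tempdir()
  back <- load_graph(dir = export_graph(sim$kg, dir2))
  for (t in names(kg$nodes)) {
    expect_equal(back$nodes[[t]], sim$kg$nodes[[t]], ignore_attr = TRUE)
  }
  for (t in names(kg$edges)) {
    expect_equal(back$edges[[t]], sim$kg$edges[[t]], ignore_attr = TRUE)
  }
})

test_that("extra columns survive as opaque properties and load_graph reads files", {
  dir <- withr::local_tempdir()
  kg <- toy_kg()
  kg$nodes$drug$custom_note <- c("x1", "x2")
  out <- export_graph(kg, dir)
  back <- load_graph(
    node_files = list(drug = file.path(out, "drug.tsv"),
                      gene = file.path(out, "gene.tsv"),
                      signature = file.path(out, "signature.tsv"),
                      cell = file.path(out, "cell.tsv"),
                      concept = file.path(out, "concept.tsv")),
    edge_files = list(drug_signature = file.path(out, "drug_signature.tsv"),
                      signature_gene = file.path(out, "signature_gene.tsv"),
                      indication = file.path(out, "indication.tsv"))
  )
  expect_equal(back$nodes$drug$custom_note, c("x1", "x2"))
})

test_that("cypher export emits one CREATE per node and relationship", {
  kg <- toy_kg()
  cy <- cypher_script(kg)
  expect_equal(sum(grepl("^CREATE \\(:", cy)), 11L)  # 2+4+3+1+1 nodes
  expect_equal(sum(grepl("CELL_SIGNATURE", cy)), 3L)
  expect_equal(sum(grepl("SIGNATURE_GENE", cy)), 4L)
  expect_equal(sum(grepl("INDICATION", cy)), 2L)
})
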