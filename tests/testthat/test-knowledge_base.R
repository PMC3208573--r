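test_that("parsing transcribes statements and builds typed entities", {
  path <- write_kb_file(list(kb_row("A", "+", "t1"),
                             kb_row("A", "-", "t2"),
                             kb_row("B", "+", "t1")))
  kg <- parse_kb(path)
  expect_equal(nrow(kg$entities), 4)
  expect_equal(nrow(kg$statements), 3)
  expect_setequal(kg$transcript_index, c("t1", "t2"))
  rep <- attr(kg, "report")
  expect_equal(rep$n_rejected, 0)
  expect_equal(rep$n_statements, 3)

  # word dialect for signs
  path2 <- write_kb_file(list(kb_row("A", "increases", "t1"),
                              kb_row("A", "decreases", "t2")))
  kg2 <- parse_kb(path2)
  expect_equal(sort(kg2$statements$sign), c(-1L, 1L))
})

test_that("duplicate triples collapse with merged evidence, conflicts kept", {
  path <- write_kb_file(list(kb_row("A", "+", "t1", cit = "PMID:1"),
                             kb_row("A", "+", "t1", cit = "PMID:2"),
                             kb_row("A", "-", "t1", cit = "PMID:3")))
  kg <- parse_kb(path)
  expect_equal(nrow(kg$statements), 2)  # contradictory duplicate kept
  plus <- kg$statements[kg$statements$sign == 1, ]
  expect_equal(plus$n_evidence, 2)
  expect_setequal(plus$evidence[[1]]$citation, c("PMID:1", "PMID:2"))
})

test_that("malformed input is rejected with the offending line", {
  expect_error(parse_kb(write_kb_file(list(kb_row("A", "modulates", "t1")))),
               "modulates.*line 2")
  expect_error(parse_kb(write_kb_file(list(c("A", "protein", "+", "t1")))),
               "line 2")
  expect_error(parse_kb(write_kb_file(list(), header = TRUE)),
               "empty")
  expect_error(parse_kb(write_kb_file(list(
    kb_row("A", "+", "t1", tgt_kind = "gene")))), "gene.*line 2")
  expect_error(parse_kb(write_kb_file(list(
    kb_row("A", "+", "t1"),
    kb_row("t1", "+", "t2", src_kind = "protein")))), "conflicting kind")
})

test_that("self-loops are rejected at parse time and counted", {
  path <- write_kb_file(list(kb_row("A", "+", "t1"),
                             kb_row("A", "+", "A", tgt_kind = "protein")))
  expect_warning(kg <- parse_kb(path), "self-loop")
  expect_equal(nrow(kg$statements), 1)
  expect_equal(attr(kg, "report")$n_rejected, 1)
})

test_that("write_kb round-trips to an identical graph without losing evidence", {
  path <- write_kb_file(list(kb_row("A", "+", "t1", cit = "PMID:1",
                                    quo = "induction observed"),
                             kb_row("A", "+", "t1", cit = "PMID:2"),
                             kb_row("A", "-", "t2"),
                             kb_row("B", "+", "t1", cit = "PMID:9")))
  kg <- parse_kb(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kg, out)
  kg2 <- parse_kb(out)
  expect_equal(kg2$entities, kg$entities)
  expect_equal(kg2$transcript_index, kg$transcript_index)
  expect_equal(kg2$statements[c("source", "sign", "target", "n_evidence")],
               kg$statements[c("source", "sign", "target", "n_evidence")])
  expect_equal(sum(kg2$statements$n_evidence), 3)
  # collapse never exceeds the raw line count
  expect_lte(nrow(kg$statements), attr(kg, "report")$n_lines)
})

test_that("mapping rate is the mapped fraction of significant transcripts", {
  kg <- toy_kb(data.frame(source = "A", sign = 1,
                          target = paste0("t", 1:7)))
  oc <- observed_changes(universe = paste0("t", 1:10),
                         direction = setNames(rep(1, 10), paste0("t", 1:10)))
  m <- map_changes(kg, oc)
  expect_equal(m$mapping_rate, 0.7)
  expect_setequal(m$unmapped, paste0("t", 8:10))

  oc_all <- observed_changes(universe = paste0("t", 1:7),
                             direction = setNames(rep(-1, 7), paste0("t", 1:7)))
  expect_equal(map_changes(kg, oc_all)$mapping_rate, 1.0)
})

test_that("a knowledge base covering 76 of 100 changed ids maps at 0.76", {
  kg <- toy_kb(data.frame(source = "A", sign = 1,
                          target = sprintf("t%03d", 1:76)))
  ids <- sprintf("t%03d", 1:100)
  oc <- observed_changes(ids, setNames(rep(c(1, -1), 50), ids))
  expect_equal(map_changes(kg, oc)$mapping_rate, 0.76)
})

test_that("zero mapped transcripts errors advising a namespace mismatch", {
  kg <- toy_kb(data.frame(source = "A", sign = 1, target = "t1"))
  oc <- observed_changes("ENSG1", setNames(1, "ENSG1"))
  expect_error(map_changes(kg, oc), "namespace")
})

test_that("KB exports to SIF and GraphML preserve the graph", {
  kg <- demo_kg()
  sif <- withr::local_tempfile(fileext = ".sif")
  export_kb(kg, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(kg$statements))
  expect_true(all(grepl("\t(increases|decreases)\t", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_kb(kg, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  g1 <- kb_to_igraph(kg)
  expect_equal(igraph::vcount(g2), igraph::vcount(g1))
  expect_equal(igraph::ecount(g2), igraph::ecount(g1))
  expect_true(igraph::isomorphic(g1, g2))
})
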