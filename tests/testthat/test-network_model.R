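make_model_results <- function() {
  obs <- setNames(c(1, 1, 1, -1, -1, -1, 1, -1, 1, -1),
                  paste0("g", 1:10))
  make_results(entity = c("A", "B"), direction = c(1, -1),
               correctness_p = c(1e-6, 1e-5), enrichment_p = c(1e-6, 1e-5),
               n_correct = c(3, 4), n_incorrect = c(0, 0),
               correct_set = list(paste0("g", 1:3), paste0("g", 4:7)),
               obs_dir = obs)
}

test_that("merging computes union coverage, overlap and contradictions", {
  mapped <- make_mapped(paste0("g", 1:20), up = paste0("g", c(1:3, 7, 9)),
                        down = paste0("g", c(4:6, 8, 10)))
  res <- make_model_results()
  m <- merge_hypotheses(res, mapped)
  expect_equal(m$pct_unique_correct, 0.7)
  expect_length(m$overlap, 0)
  expect_length(m$contradictions, 0)

  # the same hypothesis twice: union unchanged, overlap = its correct set
  twice <- rbind(res[1, ], res[1, ])
  twice$label <- c("A+", "A+bis")
  m2 <- merge_hypotheses(twice, mapped)
  expect_equal(length(m2$union_correct), 3)
  expect_setequal(names(m2$overlap), paste0("g", 1:3))

  expect_error(merge_hypotheses(res[0, ], mapped), "empty")
})

test_that("a transcript correct for one member and incorrect for another is a contradiction", {
  mapped <- make_mapped(paste0("g", 1:10), up = paste0("g", 1:5))
  res <- make_results(entity = c("A", "B"), direction = c(1, 1),
                      correctness_p = 1e-6, enrichment_p = 1e-6,
                      n_correct = c(2, 1), n_incorrect = c(0, 1),
                      correct_set = list(c("g1", "g2"), "g3"),
                      incorrect_set = list(character(), "g1"))
  m <- merge_hypotheses(res, mapped)
  expect_equal(m$contradictions, "g1")
  # pairwise cross-check oracle
  for (g in m$contradictions) {
    in_cor <- vapply(res$correct_set, function(s) g %in% s, logical(1))
    in_inc <- vapply(res$incorrect_set, function(s) g %in% s, logical(1))
    expect_true(any(in_cor) && any(in_inc))
  }
})

test_that("coverage is monotone as hypotheses are added", {
  mapped <- make_mapped(paste0("g", 1:20), up = paste0("g", c(1:3, 7, 9)),
                        down = paste0("g", c(4:6, 8, 10)))
  res <- make_model_results()
  expect_lte(merge_hypotheses(res[1, ], mapped)$pct_unique_correct,
             merge_hypotheses(res, mapped)$pct_unique_correct)
})

test_that("evidence matrix cells and marginals reproduce the classifications", {
  res <- make_results(entity = c("A", "B"), direction = c(1, 1),
                      correctness_p = 1e-6, enrichment_p = 1e-6,
                      n_correct = c(2, 1), n_incorrect = c(1, 1),
                      n_ambiguous = c(1, 0),
                      correct_set = list(c("g1", "g2"), "g2"),
                      incorrect_set = list("g3", "g5"),
                      ambiguous_set = list("g4", character()))
  m <- evidence_matrix(res)
  expect_equal(colnames(m)[1], "g2")  # explained by both members
  for (i in seq_len(nrow(res))) {
    expect_equal(sum(m[i, ] == 1, na.rm = TRUE), res$n_correct[i])
    expect_equal(sum(m[i, ] == -1, na.rm = TRUE), res$n_incorrect[i])
    expect_equal(sum(m[i, ] == 0, na.rm = TRUE), res$n_ambiguous[i])
    expect_setequal(names(which(m[i, ] == 1)), res$correct_set[[i]])
  }
})

test_that("the demo hypothesis yields evidence-matrix marginals 36/14/6", {
  kg <- demo_kg()
  mapped <- demo_mapped(kg)
  res <- score_hypothesis(kg, mapped, "RGLR1", -1)
  m <- evidence_matrix(res)
  expect_equal(unname(rowSums(m == 1, na.rm = TRUE)), 36)
  expect_equal(unname(rowSums(m == -1, na.rm = TRUE)), 14)
  expect_equal(unname(rowSums(m == 0, na.rm = TRUE)), 6)
})

test_that("model export writes SIF, GraphML and TSV with the color semantics", {
  mapped <- make_mapped(paste0("g", 1:20), up = paste0("g", c(1:3, 7, 9)),
                        down = paste0("g", c(4:6, 8, 10)))
  res <- make_model_results()
  model <- merge_hypotheses(res, mapped)
  dir <- withr::local_tempdir()
  paths <- export_model(model, mapped, dir, name = "m")
  expect_true(all(file.exists(paths)))

  sif <- readLines(paths["sif"])
  expect_length(sif, 7)  # one edge per explained transcript
  single <- export_model(merge_hypotheses(res[1, ], mapped), mapped,
                         dir, name = "one")
  expect_length(readLines(single["sif"]), 3)

  nodes <- read.delim(paths["nodes"])
  edges <- read.delim(paths["edges"])
  expect_setequal(nodes$type, c("hypothesis", "transcript"))
  expect_equal(edges$observed,
               unname(mapped$direction[edges$to]))
  expect_true(all(edges$predicted == edges$observed))  # all correct here

  expect_error(export_model(model, mapped, dir, formats = "dot"),
               "unknown export format")
})

test_that("GraphML round-trips to an isomorphic attributed graph", {
  mapped <- make_mapped(paste0("g", 1:20), up = paste0("g", c(1:3, 7, 9)),
                        down = paste0("g", c(4:6, 8, 10)))
  model <- merge_hypotheses(make_model_results(), mapped)
  dir <- withr::local_tempdir()
  paths <- export_model(model, mapped, dir, name = "m", formats = "graphml")
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), 9)
  expect_equal(igraph::ecount(g), 7)
  expect_setequal(igraph::vertex_attr(g, "type"),
                  c("hypothesis", "transcript"))
  expect_true("relation" %in% igraph::edge_attr_names(g))
})

test_that("regulators sharing targets produce in-degree-2 transcripts", {
  obs <- setNames(rep(-1, 6), paste0("g", 1:6))
  res <- make_results(entity = c("A", "B"), direction = c(-1, -1),
                      correctness_p = 1e-6, enrichment_p = 1e-6,
                      n_correct = c(4, 4),
                      correct_set = list(paste0("g", 1:4), paste0("g", 3:6)),
                      obs_dir = obs)
  mapped <- make_mapped(paste0("g", 1:10), down = paste0("g", 1:6))
  model <- merge_hypotheses(res, mapped)
  dir <- withr::local_tempdir()
  paths <- export_model(model, mapped, dir, formats = "graphml")
  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  indeg <- igraph::degree(g, mode = "in")
  expect_equal(sort(names(indeg[indeg == 2])), c("g3", "g4"))
  expect_setequal(names(model$overlap), c("g3", "g4"))
})

test_that("inter-hypothesis edges are drawn from knowledge-base statements", {
  kg <- toy_kb(data.frame(source = c("A", "A", "B"), sign = c(1, -1, 1),
                          target = c("B", "t1", "t2")),
               kinds = c(A = "protein", B = "protein",
                         t1 = "transcript", t2 = "transcript"))
  mapped <- make_mapped(c("t1", "t2"), up = "t2", down = "t1")
  res <- score_hypotheses(kg, mapped,
                          hypotheses = data.frame(entity = c("A", "B"),
                                                  direction = c(1, 1)))
  model <- merge_hypotheses(res, mapped)
  dir <- withr::local_tempdir()
  paths <- export_model(model, mapped, dir, kg = kg)
  edges <- read.delim(paths["edges"])
  ih <- edges[edges$class == "inter_hypothesis", ]
  expect_equal(nrow(ih), 1)
  expect_equal(ih$from, "A+")
  expect_equal(ih$to, "B+")
  expect_equal(ih$relation, "increases")
})
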