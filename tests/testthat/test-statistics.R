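test_that("degenerate null distributions are exact", {
  nd0 <- correctness_null(10, 3, 2, 0, 0)
  expect_equal(nd0$support, 0L)
  expect_equal(nd0$pmf, 1)

  # one up-label uniform over 3 nodes, one predicted-up node
  nd1 <- correctness_null(3, 1, 0, 1, 0)
  expect_equal(nd1$support, c(0L, 1L))
  expect_equal(nd1$pmf, c(2 / 3, 1 / 3))

  expect_error(correctness_null(5, 4, 3, 1, 1), "exceed N")
  expect_error(correctness_null(5, -1, 0, 1, 0), "non-negative")
})

test_that("the convolution null equals exhaustive enumeration at N = 12", {
  nd <- correctness_null(12, 4, 3, 3, 2)
  oracle <- enum_null_oracle(12, 4, 3, 3, 2)
  expect_lt(tv_distance(nd, oracle), 1e-12)

  p3 <- correctness_pvalue(3, nd)
  expect_equal(p3, sum(oracle$pmf[oracle$support >= 3]), tolerance = 1e-12)
})

test_that("the null mean matches the closed form (G_up-G_down)(d_up-d_down)/N", {
  set.seed(42)
  for (i in 1:10) {
    N <- sample(5:40, 1)
    G_up <- sample(0:(N %/% 2), 1)
    G_down <- sample(0:(N - G_up), 1)
    d_up <- sample(0:(N %/% 2), 1)
    d_down <- sample(0:(N - d_up), 1)
    nd <- correctness_null(N, G_up, G_down, d_up, d_down)
    expect_equal(sum(nd$support * nd$pmf),
                 (G_up - G_down) * (d_up - d_down) / N,
                 tolerance = 1e-9)
    expect_equal(sum(nd$pmf), 1, tolerance = 1e-9)
    expect_true(all(abs(nd$support) <= d_up + d_down))
  }
})

test_that("correctness p-values are exact distribution tails", {
  nd <- correctness_null(12, 4, 3, 3, 2)
  expect_equal(correctness_pvalue(min(nd$support), nd), 1)
  expect_equal(correctness_pvalue(min(nd$support) - 5, nd), 1)
  expect_equal(correctness_pvalue(max(nd$support) + 1, nd), 0)
})

test_that("enrichment p-value equals the hypergeometric tail", {
  # all 10 downstream transcripts significant out of 100/10
  mapped <- make_mapped(sprintf("g%03d", 1:100),
                        up = sprintf("g%03d", 1:10))
  pred <- make_prediction(setNames(rep(1L, 10), sprintf("g%03d", 1:10)))
  p <- enrichment_pvalue(classify(pred, mapped), pred, mapped)
  expect_equal(p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(p, 5.776904e-14, tolerance = 1e-6)

  # downstream disjoint from the significant set
  pred0 <- make_prediction(setNames(rep(1L, 10), sprintf("g%03d", 41:50)))
  expect_equal(enrichment_pvalue(classify(pred0, mapped), pred0, mapped), 1)

  # universe 20, significant 5, downstream 4, hits 3
  mapped2 <- make_mapped(paste0("g", 1:20), up = paste0("g", 1:5))
  pred2 <- make_prediction(setNames(c(1L, 1L, 1L, 1L),
                                    paste0("g", c(1, 2, 3, 10))))
  p2 <- enrichment_pvalue(classify(pred2, mapped2), pred2, mapped2)
  expect_equal(p2, hyper_tail_oracle(3, 5, 4, 20), tolerance = 1e-12)

  # empty downstream set warns and returns 1
  prede <- make_prediction(setNames(integer(), character()))
  expect_warning(pe <- enrichment_pvalue(classify(prede, mapped),
                                         prede, mapped), "empty")
  expect_equal(pe, 1)
})

test_that("ambiguous predictions are excluded from the enrichment table", {
  mapped <- make_mapped(paste0("g", 1:20), up = paste0("g", 1:5))
  # 3 significant hits + 1 ambiguous significant + 1 ambiguous background
  pred <- make_prediction(setNames(c(1L, 1L, 1L, 0L, 0L),
                                   paste0("g", c(1, 2, 3, 4, 10))))
  p <- enrichment_pvalue(classify(pred, mapped), pred, mapped)
  expect_equal(p, hyper_tail_oracle(3, 5, 3, 20), tolerance = 1e-12)
})

test_that("score_hypothesis composes prediction, classification and p-values", {
  kg <- toy_kb(data.frame(source = "A", sign = 1, target = paste0("t", 1:3)))
  mapped <- make_mapped(paste0("t", 1:10), up = paste0("t", 1:3))
  r <- score_hypothesis(kg, mapped, "A", 1)
  expect_equal(r$score, 3)
  expect_equal(r$percent_correct, 1.0)
  expect_equal(r$n_ambiguous, 0)
  nd <- correctness_null(10, 3, 0, 3, 0)
  expect_equal(r$correctness_p, correctness_pvalue(3, nd))
  expect_equal(r$enrichment_p, hyper_tail_oracle(3, 3, 3, 10),
               tolerance = 1e-12)

  rflip <- score_hypothesis(kg, mapped, "A", -1)
  expect_equal(rflip$score, -3)
  expect_equal(rflip$n_ambiguous, r$n_ambiguous)
})

test_that("two-sided gene-set enrichment matches a brute-force Fisher oracle", {
  # hits 8, term-only 6, significant-only 2, rest 84
  N <- 100
  ids <- sprintf("g%03d", 1:N)
  mapped <- make_mapped(ids, up = ids[1:10])
  sets <- data.frame(term = "T1", gene = ids[c(1:8, 11:16)])
  got <- go_enrichment(sets, mapped)
  expect_equal(got$p_value, fisher2_oracle(8, 6, 2, 84), tolerance = 1e-9)
  expect_equal(got$odds_ratio, (8 * 84) / (6 * 2))
})

test_that("desirability ranking rewards effect size, significance and size 20", {
  ids <- sprintf("g%03d", 1:200)
  mapped <- make_mapped(ids, up = ids[1:20])
  sets <- rbind(
    data.frame(term = "exhausted", gene = ids[1:4]),     # OR Inf
    # 4/40 significant = the universe rate 20/200: no signal, OR exactly 1
    data.frame(term = "null_term", gene = ids[c(1:4, 21:56)]),
    data.frame(term = "strong20", gene = ids[c(1:15, 51:55)]),
    data.frame(term = "missing", gene = "absent_gene"))
  expect_warning(tab <- go_enrichment(sets, mapped), "no overlap")
  expect_false("missing" %in% tab$term)
  expect_equal(tab$odds_ratio[tab$term == "exhausted"], Inf)
  expect_equal(tab$term[1], "strong20")  # best composite desirability
  expect_equal(tab$desirability[tab$term == "null_term"], 0)

  # proportions identical to the universe: OR 1, p 1
  mapped2 <- make_mapped(sprintf("g%03d", 1:40), up = sprintf("g%03d", 1:10))
  sets2 <- data.frame(term = "even", gene = sprintf("g%03d", c(1:4, 11:22)))
  tab2 <- go_enrichment(sets2, mapped2)
  expect_equal(tab2$odds_ratio, 1)
  expect_equal(tab2$p_value, 1)
})
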