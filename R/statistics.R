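# Significance measures for hypotheses: Fisher exact enrichment, the exact
# combinatorial null distribution of the correctness score, and GO-style
# two-sided enrichment with desirability ranking.

# Upper-tail hypergeometric probability of observing >= k significant
# transcripts when n of the N measured transcripts are downstream and K
# are significant.
hyper_enrichment_p <- function(k, K, n, N) {
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment p-value of a hypothesis
#'
#' One-sided (over-representation) Fisher exact p-value from the 2x2 table
#' over the mapped measured universe - rows: downstream of the hypothesis
#' or not; columns: significantly changed or not. The downstream "hit"
#' count is `n_correct + n_incorrect`; ambiguously predicted transcripts
#' are excluded from both the hit count and the downstream draw size.
#'
#' @param cls a `cre_classification`.
#' @param pred the `cre_prediction` the classification came from.
#' @param mapped a `mapped_changes` object.
#' @return The p-value; 1 (with a warning) when the downstream set is empty.
#' @export
enrichment_pvalue <- function(cls, pred, mapped) {
  stopifnot(inherits(cls, "cre_classification"),
            inherits(pred, "cre_prediction"),
            inherits(mapped, "mapped_changes"))
  N <- length(mapped$universe)
  if (N == 0) stop("mapped universe is empty")
  K <- length(mapped$direction)
  down <- names(pred$signs)[pred$signs != 0]
  n <- sum(down %in% mapped$universe)
  if (n == 0) {
    warning("downstream set is empty within the mapped universe; p = 1")
    return(1)
  }
  hyper_enrichment_p(cls$n_correct + cls$n_incorrect, K, n, N)
}

#' Exact null distribution of the correctness score
#'
#' Under the null, the `G_up` up-labels and `G_down` down-labels of the
#' measured universe are re-assigned uniformly onto distinct nodes of the
#' `N`-node universe (a multivariate hypergeometric draw). For a hypothesis
#' predicting `d_up` transcripts up and `d_down` down, the correctness
#' score is `S = (u+ + v-) - (u- + v+)` where `u+`/`u-` are up/down labels
#' landing in the predicted-up set and `v+`/`v-` in the predicted-down set.
#' The probability mass function of `S` is computed exactly by a
#' polynomial-time convolution over `(u+, u-, v+, v-)` - never by
#' enumerating label assignments.
#'
#' @param N size of the measured (mapped) universe.
#' @param G_up,G_down numbers of up- and down-regulated transcripts.
#' @param d_up,d_down numbers of transcripts predicted up and down
#'   (ambiguous predictions excluded).
#' @return A `null_distribution`: `support` (integer scores), `pmf`
#'   (probabilities summing to 1 within 1e-9) and `params`.
#' @export
correctness_null <- function(N, G_up, G_down, d_up, d_down) {
  ints <- c(N = N, G_up = G_up, G_down = G_down, d_up = d_up, d_down = d_down)
  if (any(ints < 0) || any(ints != round(ints)))
    stop("parameters must be non-negative integers")
  if (G_up + G_down > N) stop("G_up + G_down must not exceed N")
  if (d_up + d_down > N) stop("d_up + d_down must not exceed N")
  params <- as.list(ints)
  if (d_up + d_down == 0)
    return(structure(list(support = 0L, pmf = 1, params = params),
                     class = "null_distribution"))
  R <- N - d_up - d_down
  g <- expand.grid(u_p = 0:min(d_up, G_up),
                   u_m = 0:min(d_up, G_down),
                   v_p = 0:min(d_down, G_up),
                   v_m = 0:min(d_down, G_down))
  rest_up <- G_up - g$u_p - g$v_p
  rest_dn <- G_down - g$u_m - g$v_m
  keep <- g$u_p + g$u_m <= d_up & g$v_p + g$v_m <= d_down &
    rest_up >= 0 & rest_dn >= 0 & rest_up <= R & rest_dn <= R - rest_up
  g <- g[keep, ]
  rest_up <- rest_up[keep]
  rest_dn <- rest_dn[keep]
  logw <- lchoose(d_up, g$u_p) + lchoose(d_up - g$u_p, g$u_m) +
    lchoose(d_down, g$v_p) + lchoose(d_down - g$v_p, g$v_m) +
    lchoose(R, rest_up) + lchoose(R - rest_up, rest_dn) -
    lchoose(N, G_up) - lchoose(N - G_up, G_down)
  s <- g$u_p + g$v_m - g$u_m - g$v_p
  lev <- sort(unique(s))
  pmf <- vapply(split(exp(logw), factor(s, levels = lev)), sum, numeric(1))
  if (abs(sum(pmf) - 1) > 1e-9)
    stop("null pmf does not sum to 1 (numerical failure)")
  structure(list(support = as.integer(lev), pmf = unname(pmf),
                 params = params),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  p <- x$params
  cat(sprintf("Correctness-score null (N=%d, G_up=%d, G_down=%d, d_up=%d, d_down=%d)\n",
              p$N, p$G_up, p$G_down, p$d_up, p$d_down))
  cat(sprintf("  support [%d, %d], mean %.4f\n", min(x$support), max(x$support),
              sum(x$support * x$pmf)))
  invisible(x)
}

#' Correctness p-value
#'
#' Upper-tail probability `P(S >= score)` of the correctness score under
#' its exact null distribution. A score above the maximum of the support
#' yields the exact (empty) tail, 0.
#'
#' @param score observed integer score (`n_correct - n_incorrect`).
#' @param nd a `null_distribution` from [correctness_null()].
#' @return The p-value.
#' @export
correctness_pvalue <- function(score, nd) {
  stopifnot(inherits(nd, "null_distribution"))
  sum(nd$pmf[nd$support >= score])
}

#' Score one hypothesis
#'
#' Composes [predict_downstream()], [classify()] and both p-values.
#'
#' @param kg a `causal_kb`.
#' @param mapped a `mapped_changes` object.
#' @param entity hypothesis entity id.
#' @param direction +1 or -1.
#' @param depth maximum chain length.
#' @return A one-row `cre_results` data.frame (see [score_hypotheses()]).
#' @export
score_hypothesis <- function(kg, mapped, entity, direction, depth = 1L) {
  score_hypotheses(kg, mapped, depth = depth,
                   hypotheses = data.frame(entity = entity,
                                           direction = as.integer(direction)))
}

#' Score a set of hypotheses
#'
#' For every hypothesis (by default all enumerated by
#' [enumerate_hypotheses()]), predicts downstream transcript signs,
#' classifies them against the observed calls, and computes the correctness
#' score, the exact correctness p-value and the Fisher enrichment p-value.
#' Ambiguous predictions are excluded from the score, from the null's
#' predicted-set sizes and from the enrichment table. Null distributions
#' are cached across hypotheses sharing predicted-set sizes.
#'
#' @param kg a `causal_kb`.
#' @param mapped a `mapped_changes` object.
#' @param depth maximum chain length.
#' @param min_targets passed to [enumerate_hypotheses()] when `hypotheses`
#'   is `NULL`.
#' @param hypotheses optional data.frame with columns `entity`, `direction`.
#' @return A `cre_results` data.frame, one row per hypothesis: `entity`,
#'   `direction`, `label`, counts, `score`, `correctness_p`,
#'   `enrichment_p`, `percent_correct`, `n_downstream`, plus list-columns
#'   `correct_set`, `incorrect_set`, `ambiguous_set`, `evidence` (correctly
#'   explained gene/direction features) and `contra` (incorrect
#'   explanations as signed features).
#' @export
score_hypotheses <- function(kg, mapped, depth = 1L, min_targets = 1L,
                             hypotheses = NULL) {
  stopifnot(inherits(kg, "causal_kb"), inherits(mapped, "mapped_changes"))
  if (is.null(hypotheses))
    hypotheses <- enumerate_hypotheses(kg, depth, min_targets)
  if (nrow(hypotheses) == 0) return(empty_results())
  stopifnot(all(c("entity", "direction") %in% names(hypotheses)),
            all(hypotheses$direction %in% c(-1, 1)))
  if (!all(hypotheses$entity %in% kg$entities$id))
    stop("hypothesis entity not in knowledge base: ",
         paste(setdiff(hypotheses$entity, kg$entities$id), collapse = ", "))

  adj <- kb_adjacency(kg)
  sig <- mapped$direction
  N <- length(mapped$universe)
  G_up <- sum(sig == 1)
  G_down <- sum(sig == -1)
  nd_cache <- new.env(parent = emptyenv())
  base_cache <- new.env(parent = emptyenv())

  rows <- vector("list", nrow(hypotheses))
  for (i in seq_len(nrow(hypotheses))) {
    e <- hypotheses$entity[i]
    dir <- as.integer(hypotheses$direction[i])
    base <- base_cache[[e]]
    if (is.null(base)) {
      base <- chain_sign_sets(kg, e, depth, adj)$signs
      base <- base[names(base) %in% mapped$universe]
      base_cache[[e]] <- base
    }
    s <- dir * base
    obs <- sig[names(s)[names(s) %in% names(sig)]]
    ss <- s[names(obs)]
    cor <- names(ss)[ss != 0 & ss == obs]
    inc <- names(ss)[ss != 0 & ss != obs]
    amb <- names(ss)[ss == 0]
    nc <- length(cor); ni <- length(inc)
    d_up <- sum(s == 1); d_down <- sum(s == -1)
    key <- paste(d_up, d_down)
    nd <- nd_cache[[key]]
    if (is.null(nd)) {
      nd <- correctness_null(N, G_up, G_down, d_up, d_down)
      nd_cache[[key]] <- nd
    }
    n_down <- d_up + d_down
    rows[[i]] <- data.frame(
      entity = e, direction = dir,
      label = paste0(e, if (dir > 0) "+" else "-"),
      n_correct = nc, n_incorrect = ni, n_ambiguous = length(amb),
      score = nc - ni,
      correctness_p = correctness_pvalue(nc - ni, nd),
      enrichment_p = if (n_down == 0) 1 else
        hyper_enrichment_p(nc + ni, length(sig), n_down, N),
      percent_correct = if (nc + ni > 0) nc / (nc + ni) else NA_real_,
      n_downstream = n_down)
    rows[[i]]$correct_set <- list(sort(cor))
    rows[[i]]$incorrect_set <- list(sort(inc))
    rows[[i]]$ambiguous_set <- list(sort(amb))
    rows[[i]]$evidence <- list(evidence_features(sort(cor), obs))
    rows[[i]]$contra <- list(evidence_features(sort(inc), -obs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cre_results", "data.frame")
  out
}

# Feature strings "gene/+" or "gene/-": the explained direction, i.e. the
# predicted direction (equal to the observed one for correct explanations).
evidence_features <- function(ids, signed) {
  if (length(ids) == 0) return(character())
  paste0(ids, ifelse(signed[ids] > 0, "/+", "/-"))
}

empty_results <- function() {
  out <- data.frame(entity = character(), direction = integer(),
                    label = character(), n_correct = integer(),
                    n_incorrect = integer(), n_ambiguous = integer(),
                    score = integer(), correctness_p = numeric(),
                    enrichment_p = numeric(), percent_correct = numeric(),
                    n_downstream = integer())
  out$correct_set <- list(); out$incorrect_set <- list()
  out$ambiguous_set <- list(); out$evidence <- list(); out$contra <- list()
  class(out) <- c("cre_results", "data.frame")
  out
}

#' Flatten scored results to a plain exportable table
#'
#' Drops the list-columns and orders columns as in the standard results
#' TSV: hypothesis, direction, rank, cluster id/size (when present),
#' counts, score, p-values and percent correct.
#'
#' @param results a `cre_results` data.frame.
#' @param path optional output TSV path.
#' @return The flat data.frame (invisibly when written to `path`).
#' @export
results_table <- function(results, path = NULL) {
  cols <- c("label", "direction", "rank", "cluster_id", "cluster_size",
            "n_correct", "n_incorrect", "n_ambiguous", "score",
            "correctness_p", "enrichment_p", "percent_correct")
  out <- as.data.frame(results)[, intersect(cols, names(results)),
                                drop = FALSE]
  names(out)[names(out) == "label"] <- "hypothesis"
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' GO-style gene-set enrichment with desirability ranking
#'
#' Per term: a two-sided Fisher exact test on the 2x2 table of term
#' membership against significance over the mapped universe, the sample
#' odds ratio (observed/expected; `Inf` when the term is exhausted by the
#' significant set), and a composite desirability score - the geometric
#' mean of three Derringer-style components with linear ramps: monotone in
#' `|log2(odds ratio)|` (saturating at `log2(or_saturation)`), monotone in
#' `-log10(p)` (saturating at `logp_saturation`), and peaked at
#' `size_target` genes (zero outside `size_range`). The anchor values are
#' conventions and configurable. Terms without universe overlap are
#' skipped with a warning.
#'
#' @param sets data.frame with columns `term`, `gene` (long format).
#' @param mapped a `mapped_changes` object.
#' @param size_target most desirable term size (default 20 genes).
#' @param size_range sizes outside this window get zero size-desirability.
#' @param or_saturation odds ratio at which effect desirability reaches 1.
#' @param logp_saturation `-log10(p)` at which p desirability reaches 1.
#' @return data.frame sorted by descending desirability: `term`, `size`
#'   (term genes in the universe), `n_sig`, `p_value`, `odds_ratio`,
#'   `desirability`.
#' @export
go_enrichment <- function(sets, mapped, size_target = 20,
                          size_range = c(2, 500), or_saturation = 10,
                          logp_saturation = 5) {
  stopifnot(is.data.frame(sets), all(c("term", "gene") %in% names(sets)),
            inherits(mapped, "mapped_changes"))
  universe <- mapped$universe
  sig <- names(mapped$direction)
  N <- length(universe)
  terms <- split(as.character(sets$gene), as.character(sets$term))
  rows <- lapply(names(terms), function(tm) {
    genes <- unique(intersect(terms[[tm]], universe))
    if (length(genes) == 0) {
      warning("term has no overlap with the measured universe, skipped: ", tm)
      return(NULL)
    }
    a <- length(intersect(genes, sig))
    b <- length(genes) - a
    cc <- length(sig) - a
    d <- N - a - b - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2))
    or <- (a * d) / (b * cc)  # observed/expected sample odds ratio
    if (is.nan(or)) or <- 1   # degenerate 0/0 table margin
    data.frame(term = tm, size = length(genes), n_sig = a,
               p_value = ft$p.value, odds_ratio = or,
               desirability = desirability_score(or, ft$p.value,
                                                 length(genes), size_target,
                                                 size_range, or_saturation,
                                                 logp_saturation))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), size = integer(),
                      n_sig = integer(), p_value = numeric(),
                      odds_ratio = numeric(), desirability = numeric()))
  out <- out[order(-out$desirability, out$p_value, out$term,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

desirability_score <- function(or, p, size, size_target, size_range,
                               or_saturation, logp_saturation) {
  eff <- abs(log2(or))                     # Inf (or = 0 or Inf) -> 1
  d_eff <- min(1, eff / log2(or_saturation))
  d_p <- min(1, max(0, -log10(p)) / logp_saturation)
  L <- size_range[1]; U <- size_range[2]; Tt <- size_target
  d_size <- if (size < L || size > U) 0
  else if (size <= Tt) (size - L) / (Tt - L)
  else (U - size) / (U - Tt)
  (d_eff * d_p * d_size)^(1 / 3)
}
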