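# Hypothesis-admission cutoffs and competition ranking.

#' Hypothesis filter configuration
#'
#' The default cutoffs admit a hypothesis when its correctness p-value and
#' enrichment p-value are both below 0.01 (strict), it correctly explains
#' at least 3 gene expression changes, and at least 60% of its
#' non-ambiguous explanations are correct.
#'
#' @param max_correctness_p strict upper bound on the correctness p-value.
#' @param max_enrichment_p strict upper bound on the enrichment p-value.
#' @param min_correct minimum number of correctly explained changes.
#' @param min_percent_correct minimum fraction correct.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_correctness_p = 0.01, max_enrichment_p = 0.01,
                          min_correct = 3, min_percent_correct = 0.60) {
  stopifnot(max_correctness_p > 0, max_correctness_p <= 1,
            max_enrichment_p > 0, max_enrichment_p <= 1,
            min_correct >= 0,
            min_percent_correct >= 0, min_percent_correct <= 1)
  structure(list(max_correctness_p = max_correctness_p,
                 max_enrichment_p = max_enrichment_p,
                 min_correct = min_correct,
                 min_percent_correct = min_percent_correct),
            class = "filter_config")
}

#' Filter scored hypotheses on the admission cutoffs
#'
#' Keeps rows meeting all four conditions: `correctness_p` strictly below
#' the cutoff, `enrichment_p` strictly below the cutoff, `n_correct` at
#' least `min_correct`, and `percent_correct` at least
#' `min_percent_correct` (rows with an undefined percent - no non-ambiguous
#' explanations - are dropped). Input order is preserved; filtering is
#' idempotent.
#'
#' @param results a `cre_results` data.frame (from [score_hypotheses()]).
#' @param cfg a [filter_config()].
#' @return The admitted subset, same class and column set.
#' @export
filter_hypotheses <- function(results, cfg = filter_config()) {
  stopifnot(is.data.frame(results), inherits(cfg, "filter_config"))
  pct <- results$percent_correct
  keep <- results$correctness_p < cfg$max_correctness_p &
    results$enrichment_p < cfg$max_enrichment_p &
    results$n_correct >= cfg$min_correct &
    !is.na(pct) & pct >= cfg$min_percent_correct
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hypotheses by correctness p-value
#'
#' Competition ranking on ascending correctness p-value: tied p-values
#' share the minimum rank and the next distinct value resumes at its
#' ordinal position (1, 2, 2, 4). Rows are reordered by rank, breaking
#' ties by ascending enrichment p-value, then entity id, then direction.
#'
#' @param results a `cre_results` data.frame.
#' @return The results with a `rank` column, reordered.
#' @export
rank_hypotheses <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) {
    results$rank <- integer()
    return(results)
  }
  results$rank <- rank(results$correctness_p, ties.method = "min")
  ord <- order(results$rank, results$enrichment_p, results$entity,
               -results$direction, method = "radix")
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
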