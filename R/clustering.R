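# Grouping hypotheses by similarity of their supporting evidence:
# cosine similarity on binary feature sets, average-linkage agglomeration
# stopped by a user threshold.

#' Cosine similarity of two evidence feature sets
#'
#' On binary feature vectors this is `|a intersect b| / sqrt(|a| * |b|)`:
#' 1 for identical supporting evidence, 0 for disjoint (or when either set
#' is empty).
#'
#' @param a,b character vectors of features (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

# Evidence feature sets per hypothesis row. Support = correctly explained
# (gene, direction) pairs; optionally the incorrect explanations as signed
# features too.
evidence_sets <- function(results, include_incorrect = FALSE) {
  feats <- results$evidence
  if (include_incorrect)
    feats <- Map(c, feats, results$contra)
  setNames(lapply(feats, unique), results$label)
}

#' Cluster hypotheses by evidence similarity
#'
#' Agglomerative average-linkage clustering on the cosine similarity of
#' supporting-evidence sets. Starting from singletons, the pair of
#' clusters with the highest average pairwise similarity is merged while
#' that similarity is at least `threshold`; ties are broken by merging the
#' lexicographically smallest qualifying pair (by each cluster's smallest
#' member label), which makes the result invariant to input order.
#' Hypotheses with empty evidence never merge and stay singletons.
#' Clusters are numbered by descending size, then by best member rank
#' (smallest `rank` if present, else smallest correctness p-value), then
#' by smallest member label.
#'
#' @param results a `cre_results` data.frame.
#' @param threshold minimum average similarity to merge, in `[0, 1]`.
#' @param include_incorrect also use incorrect explanations as signed
#'   features (default `FALSE`: support only).
#' @return `results` with `cluster_id` and `cluster_size` columns;
#'   `attr(, "clusters")` is a list of member-label vectors per cluster id
#'   and `attr(, "cluster_threshold")` records the threshold.
#' @export
cluster_hypotheses <- function(results, threshold, include_incorrect = FALSE) {
  stopifnot(is.data.frame(results), threshold >= 0, threshold <= 1)
  n <- nrow(results)
  if (n == 0) {
    results$cluster_id <- integer()
    results$cluster_size <- integer()
    attr(results, "clusters") <- list()
    attr(results, "cluster_threshold") <- threshold
    return(results)
  }
  feats <- evidence_sets(results, include_incorrect)
  labels <- results$label
  if (anyDuplicated(labels)) stop("duplicate hypothesis labels")

  nonempty <- unname(which(lengths(feats) > 0))
  S <- matrix(0, n, n)
  for (i in nonempty) for (j in nonempty) if (j > i)
    S[i, j] <- S[j, i] <- cosine_similarity(feats[[i]], feats[[j]])

  clusters <- lapply(nonempty, identity)      # merging pool
  eps <- 1e-9
  while (length(clusters) > 1) {
    best <- -Inf; pick <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        lk <- mean(S[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (lk > best + eps ||
            (lk > best - eps && !is.null(pick) &&
             lex_less(key, pick$key))) {
          best <- lk
          pick <- list(i = i, j = j, key = key)
        }
      }
    }
    if (is.null(pick) || best < threshold - eps) break
    clusters[[pick$i]] <- c(clusters[[pick$i]], clusters[[pick$j]])
    clusters[[pick$j]] <- NULL
  }
  clusters <- c(clusters, lapply(setdiff(seq_len(n), nonempty), identity))

  # deterministic numbering: size desc, best member rank, smallest label
  best_key <- if ("rank" %in% names(results)) results$rank else
    results$correctness_p
  sizes <- lengths(clusters)
  ord <- order(-sizes,
               vapply(clusters, function(m) min(best_key[m]), numeric(1)),
               vapply(clusters, function(m) min(labels[m]), character(1)),
               method = "radix")
  clusters <- clusters[ord]

  cid <- integer(n); csz <- integer(n)
  for (k in seq_along(clusters)) {
    cid[clusters[[k]]] <- k
    csz[clusters[[k]]] <- length(clusters[[k]])
  }
  results$cluster_id <- cid
  results$cluster_size <- csz
  attr(results, "clusters") <- lapply(clusters, function(m) sort(labels[m]))
  attr(results, "cluster_threshold") <- threshold
  results
}

lex_less <- function(a, b) {
  if (a[1] != b[1]) return(a[1] < b[1])
  a[2] < b[2]
}

#' Cluster membership table
#'
#' The standard cluster summary: hypothesis, rank, cluster id and size,
#' p-values and percent correct, ordered by cluster id then rank.
#'
#' @param results clustered results from [cluster_hypotheses()].
#' @param path optional output TSV path.
#' @return The data.frame (invisibly when written to `path`).
#' @export
cluster_table <- function(results, path = NULL) {
  stopifnot("cluster_id" %in% names(results))
  cols <- c("label", "rank", "cluster_id", "cluster_size",
            "correctness_p", "enrichment_p", "percent_correct")
  out <- as.data.frame(results)[, intersect(cols, names(results)),
                                drop = FALSE]
  names(out)[names(out) == "label"] <- "hypothesis"
  ord <- if ("rank" %in% names(out))
    order(out$cluster_id, out$rank, out$hypothesis, method = "radix")
  else order(out$cluster_id, out$hypothesis, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
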