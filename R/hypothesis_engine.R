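# Hypothesis enumeration, signed downstream prediction, and classification
# of predictions against observed expression changes.

kb_adjacency <- function(kg) {
  split(seq_len(nrow(kg$statements)), kg$statements$source)
}

# Transcript ids reachable from `entity` by a statement chain of length
# <= depth. BFS suffices: a shortest chain is simple, so reachability
# within depth under the simple-path rule equals BFS reachability.
transcript_descendants <- function(kg, entity, depth, adj = kb_adjacency(kg)) {
  st <- kg$statements
  is_tx <- setNames(kg$entities$kind == "transcript", kg$entities$id)
  frontier <- entity
  visited <- entity
  found <- character()
  for (d in seq_len(depth)) {
    rows <- unlist(adj[frontier], use.names = FALSE)
    if (is.null(rows) || length(rows) == 0) break
    nxt <- unique(st$target[rows])
    found <- c(found, nxt[is_tx[nxt]])
    frontier <- setdiff(nxt, visited)
    visited <- c(visited, frontier)
    if (length(frontier) == 0) break
  }
  sort(unique(found))
}

#' Enumerate candidate upstream hypotheses
#'
#' Every entity with at least `min_targets` transcript descendants within
#' `depth` statement hops yields two hypotheses, one per assumed direction
#' of regulation. Output order is deterministic: ascending entity id, then
#' predicted increase (+1) before predicted decrease (-1).
#'
#' @param kg a `causal_kb`.
#' @param depth maximum chain length (default 1: direct statements only).
#' @param min_targets minimum number of reachable transcripts.
#' @return data.frame with columns `entity`, `direction`, `label`
#'   (entity id suffixed with `+`/`-`), and `n_reachable`.
#' @export
enumerate_hypotheses <- function(kg, depth = 1L, min_targets = 1L) {
  stopifnot(inherits(kg, "causal_kb"), depth >= 1, min_targets >= 1)
  adj <- kb_adjacency(kg)
  ids <- sort(kg$entities$id, method = "radix")
  n_reach <- vapply(ids, function(e)
    length(transcript_descendants(kg, e, depth, adj)), integer(1))
  keep <- ids[n_reach >= min_targets]
  if (length(keep) == 0)
    return(data.frame(entity = character(), direction = integer(),
                      label = character(), n_reachable = integer()))
  out <- data.frame(entity = rep(keep, each = 2L),
                    direction = rep(c(1L, -1L), length(keep)))
  out$label <- paste0(out$entity, ifelse(out$direction > 0, "+", "-"))
  out$n_reachable <- rep(unname(n_reach[keep]), each = 2L)
  out
}

# Signs of all simple statement chains of length <= depth from `entity`,
# accumulated per reachable transcript. Returns a named integer vector:
# +1 / -1 for a consistent chain-sign product, 0 where chains of both
# signs exist (ambiguous), relative to an assumed *increase* of `entity`.
chain_sign_sets <- function(kg, entity, depth, adj = kb_adjacency(kg),
                            keep_paths = FALSE) {
  st <- kg$statements
  is_tx <- setNames(kg$entities$kind == "transcript", kg$entities$id)
  acc <- new.env(parent = emptyenv())
  paths <- if (keep_paths) new.env(parent = emptyenv()) else NULL
  walk <- function(node, prod, used, d, trail) {
    rows <- adj[[node]]
    if (is.null(rows)) return(invisible())
    for (i in rows) {
      tgt <- st$target[i]
      if (tgt %in% used) next
      p <- prod * st$sign[i]
      tr <- if (keep_paths) paste0(trail, ifelse(st$sign[i] > 0, " -+> ", " --> "),
                                   tgt) else NULL
      if (isTRUE(is_tx[[tgt]])) {
        prev <- acc[[tgt]]
        acc[[tgt]] <- union(prev, p)
        if (keep_paths) paths[[tgt]] <- c(paths[[tgt]], tr)
      }
      if (d < depth) walk(tgt, p, c(used, tgt), d + 1L, tr)
    }
    invisible()
  }
  walk(entity, 1L, entity, 1L, entity)
  tx <- sort(ls(acc))
  if (length(tx) == 0)
    return(list(signs = setNames(integer(0), character(0)), paths = NULL))
  signs <- vapply(tx, function(t) {
    s <- acc[[t]]
    if (length(s) > 1L) 0L else as.integer(s)
  }, integer(1))
  list(signs = signs,
       paths = if (keep_paths) mget(tx, envir = paths) else NULL)
}

#' Predict signed downstream transcript changes for a hypothesis
#'
#' Enumerates all simple statement chains of length at most `depth` from
#' the hypothesis entity. A reachable transcript's predicted sign is the
#' hypothesis direction times the product of chain signs; transcripts
#' supported by chains of both signs are ambiguous (sign 0). Transcript
#' nodes may be intermediates; non-transcript endpoints never appear.
#'
#' @param kg a `causal_kb`.
#' @param entity hypothesis entity id (must exist in `kg`).
#' @param direction assumed regulation direction, +1 or -1.
#' @param depth maximum chain length.
#' @param keep_paths record the supporting chains per transcript.
#' @return A `cre_prediction`: list with `entity`, `direction`, `depth`,
#'   `signs` (named vector, +1/-1/0 = ambiguous) and optionally `paths`.
#' @export
predict_downstream <- function(kg, entity, direction, depth = 1L,
                               keep_paths = FALSE) {
  stopifnot(inherits(kg, "causal_kb"), direction %in% c(-1, 1), depth >= 1)
  if (!entity %in% kg$entities$id)
    stop("entity not in knowledge base: ", entity)
  base <- chain_sign_sets(kg, entity, depth, keep_paths = keep_paths)
  structure(list(entity = entity,
                 direction = as.integer(direction),
                 depth = as.integer(depth),
                 signs = setNames(as.integer(direction) * base$signs,
                                  names(base$signs)),
                 paths = base$paths),
            class = "cre_prediction")
}

#' @export
print.cre_prediction <- function(x, ...) {
  cat(sprintf("Prediction for %s%s (depth %d): %d transcripts (%d up, %d down, %d ambiguous)\n",
              x$entity, if (x$direction > 0) "+" else "-", x$depth,
              length(x$signs), sum(x$signs == 1), sum(x$signs == -1),
              sum(x$signs == 0)))
  invisible(x)
}

#' Classify predicted transcript changes against observed calls
#'
#' Considers only significant transcripts of the mapped universe that have
#' a prediction. An ambiguous prediction goes to the ambiguous set; a
#' predicted sign equal to the observed sign is correct; otherwise
#' incorrect. Unmeasured or non-significant predicted transcripts are
#' ignored.
#'
#' @param pred a `cre_prediction`.
#' @param mapped a `mapped_changes` object.
#' @return A `cre_classification`: counts `n_correct`, `n_incorrect`,
#'   `n_ambiguous` and the corresponding disjoint id sets.
#' @export
classify <- function(pred, mapped) {
  stopifnot(inherits(pred, "cre_prediction"), inherits(mapped, "mapped_changes"))
  sig <- mapped$direction
  s <- pred$signs[names(pred$signs) %in% names(sig)]
  obs <- sig[names(s)]
  amb <- names(s)[s == 0]
  cor <- names(s)[s != 0 & s == obs]
  inc <- names(s)[s != 0 & s != obs]
  structure(list(n_correct = length(cor),
                 n_incorrect = length(inc),
                 n_ambiguous = length(amb),
                 correct_set = sort(cor),
                 incorrect_set = sort(inc),
                 ambiguous_set = sort(amb)),
            class = "cre_classification")
}

#' @export
print.cre_classification <- function(x, ...) {
  cat(sprintf("Classification: %d correct, %d incorrect, %d ambiguous\n",
              x$n_correct, x$n_incorrect, x$n_ambiguous))
  invisible(x)
}

#' Export a hypothesis prediction as a per-transcript table
#'
#' One row per significant mapped transcript with a prediction: predicted
#' sign, observed sign, class, and supporting citations when available.
#'
#' @param pred a `cre_prediction`.
#' @param mapped a `mapped_changes` object.
#' @param kg the `causal_kb` (for citations of direct statements).
#' @param path optional file path; when given, the table is written as TSV.
#' @return The data.frame, invisibly when `path` is given.
#' @export
prediction_table <- function(pred, mapped, kg = NULL, path = NULL) {
  cls <- classify(pred, mapped)
  ids <- c(cls$correct_set, cls$incorrect_set, cls$ambiguous_set)
  if (length(ids) == 0) {
    out <- data.frame(transcript = character(), predicted = integer(),
                      observed = numeric(), class = character(),
                      citations = character())
  } else {
    cl <- c(rep("correct", cls$n_correct), rep("incorrect", cls$n_incorrect),
            rep("ambiguous", cls$n_ambiguous))
    cits <- rep("", length(ids))
    if (!is.null(kg)) {
      st <- kg$statements
      direct <- st$source == pred$entity
      cits <- vapply(ids, function(t) {
        ev <- st$evidence[direct & st$target == t]
        paste(unique(unlist(lapply(ev, `[[`, "citation"))), collapse = ";")
      }, character(1))
    }
    out <- data.frame(transcript = ids,
                      predicted = unname(pred$signs[ids]),
                      observed = unname(mapped$direction[ids]),
                      class = cl,
                      citations = unname(cits))
    out <- out[order(out$class, out$transcript), ]
    rownames(out) <- NULL
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
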