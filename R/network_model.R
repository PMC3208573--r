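# Merging hypotheses into biological network models: coverage statistics,
# the evidence matrix, and headless SIF/GraphML/TSV export.

#' Merge a subset of hypotheses into a model
#'
#' Computes the coverage statistics of a hypothesis subset: the union of
#' correctly explained transcripts, the fraction of significant mapped
#' transcripts it covers, the per-transcript overlap (transcripts
#' correctly explained by two or more members), and the contradictions
#' (transcripts classified correct by one member and incorrect by
#' another).
#'
#' @param results a nonempty `cre_results` subset.
#' @param mapped the `mapped_changes` the results were scored against.
#' @return A `merged_model`: `hypotheses`, `union_correct`,
#'   `pct_unique_correct`, `overlap` (named counts >= 2), `overlap_frac`
#'   (fraction of the union explained by >= 2 members), `contradictions`.
#' @export
merge_hypotheses <- function(results, mapped) {
  stopifnot(is.data.frame(results), inherits(mapped, "mapped_changes"))
  if (nrow(results) == 0) stop("cannot merge an empty hypothesis subset")
  cor_all <- unlist(lapply(results$correct_set, unique), use.names = FALSE)
  inc_all <- unlist(lapply(results$incorrect_set, unique), use.names = FALSE)
  union_correct <- sort(unique(cor_all))
  counts <- table(cor_all)
  overlap <- counts[counts >= 2]
  overlap <- setNames(as.integer(overlap), names(overlap))
  structure(list(hypotheses = results,
                 union_correct = union_correct,
                 pct_unique_correct =
                   length(union_correct) / length(mapped$direction),
                 overlap = overlap,
                 overlap_frac = if (length(union_correct) == 0) 0 else
                   length(overlap) / length(union_correct),
                 contradictions = sort(intersect(cor_all, inc_all))),
            class = "merged_model")
}

#' @export
print.merged_model <- function(x, ...) {
  cat("Merged hypothesis model\n")
  cat("  hypotheses:            ", nrow(x$hypotheses), "\n")
  cat("  unique correct:        ", length(x$union_correct),
      sprintf(" (%.1f%% of significant mapped)\n", 100 * x$pct_unique_correct))
  cat("  overlap (>=2 members): ", length(x$overlap),
      sprintf(" transcripts (%.1f%% of union)\n", 100 * x$overlap_frac))
  cat("  contradictions:        ", length(x$contradictions), "\n")
  invisible(x)
}

#' Evidence matrix of a hypothesis subset
#'
#' Hypothesis-by-transcript matrix: `+1` correct, `-1` incorrect, `0`
#' ambiguous, `NA` no relation. Columns are ordered by descending number
#' of explaining hypotheses, then transcript id.
#'
#' @param results a nonempty `cre_results` subset.
#' @return A numeric matrix with hypothesis labels as row names.
#' @export
evidence_matrix <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) stop("empty hypothesis subset")
  ids <- sort(unique(unlist(c(results$correct_set, results$incorrect_set,
                              results$ambiguous_set), use.names = FALSE)))
  m <- matrix(NA_real_, nrow(results), length(ids),
              dimnames = list(results$label, ids))
  for (i in seq_len(nrow(results))) {
    m[i, results$correct_set[[i]]] <- 1
    m[i, results$incorrect_set[[i]]] <- -1
    m[i, results$ambiguous_set[[i]]] <- 0
  }
  if (length(ids))
    m <- m[, order(-colSums(!is.na(m)), colnames(m), method = "radix"),
           drop = FALSE]
  m
}

#' Write an evidence matrix as TSV
#'
#' @param m matrix from [evidence_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_evidence_matrix <- function(m, path) {
  out <- data.frame(hypothesis = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a merged model for network visualization
#'
#' Builds the overview graph - hypothesis nodes and transcript nodes,
#' edges for every explained transcript - with attributes encoding the
#' predicted direction (hypothesis direction and per-transcript predicted
#' sign) and the observed mRNA direction, i.e. the usual color semantics
#' of causal-network views (predicted decrease vs increase, observed
#' decrease vs increase). When a knowledge graph is supplied,
#' inter-hypothesis edges are drawn for causal statements linking two
#' member entities, with their sign. Output is bit-stable for fixed input.
#'
#' @param model a `merged_model`.
#' @param mapped the `mapped_changes` (for observed directions).
#' @param dir output directory (created if needed).
#' @param name file-name stem.
#' @param formats any of `"sif"`, `"graphml"`, `"tsv"`.
#' @param kg optional `causal_kb` for inter-hypothesis edges.
#' @return Named character vector of written file paths, invisibly.
#' @export
export_model <- function(model, mapped, dir, name = "model",
                         formats = c("sif", "graphml", "tsv"), kg = NULL) {
  stopifnot(inherits(model, "merged_model"), inherits(mapped, "mapped_changes"))
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) stop("unknown export format(s): ", paste(bad, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- model$hypotheses
  sig <- mapped$direction

  edges <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    lab <- res$label[i]; hdir <- res$direction[i]
    cor <- res$correct_set[[i]]; inc <- res$incorrect_set[[i]]
    amb <- res$ambiguous_set[[i]]
    ids <- c(cor, inc, amb)
    if (length(ids) == 0) return(NULL)
    cls <- c(rep("correct", length(cor)), rep("incorrect", length(inc)),
             rep("ambiguous", length(amb)))
    obs <- unname(sig[ids])
    pred <- ifelse(cls == "correct", obs,
                   ifelse(cls == "incorrect", -obs, 0))
    data.frame(from = lab, to = ids, class = cls,
               predicted = as.integer(pred), observed = as.integer(obs),
               relation = ifelse(pred == 0, "ambiguous",
                                 ifelse(hdir * pred > 0, "increases",
                                        "decreases")))
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        class = character(), predicted = integer(),
                        observed = integer(), relation = character())
  if (!is.null(kg)) {
    ents <- setNames(res$label, res$entity)
    st <- kg$statements
    hh <- st[st$source %in% names(ents) & st$target %in% names(ents), ,
             drop = FALSE]
    if (nrow(hh)) {
      # one edge per (source hypothesis, target hypothesis, sign)
      ie <- do.call(rbind, lapply(seq_len(nrow(hh)), function(i) {
        data.frame(from = unname(ents[names(ents) == hh$source[i]]),
                   to = unname(ents[names(ents) == hh$target[i]]),
                   class = "inter_hypothesis",
                   predicted = NA_integer_, observed = NA_integer_,
                   relation = if (hh$sign[i] > 0) "increases" else "decreases")
      }))
      ie <- ie[ie$from != ie$to, , drop = FALSE]
      edges <- rbind(edges, unique(ie))
    }
  }
  edges <- edges[order(edges$from, edges$to, edges$relation,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL

  tx <- sort(setdiff(unique(edges$to), res$label))
  nodes <- rbind(
    data.frame(id = res$label, type = "hypothesis",
               direction = res$direction),
    if (length(tx)) data.frame(id = tx, type = "transcript",
                               direction = as.integer(unname(sig[tx]))))
  nodes <- nodes[order(nodes$type, nodes$id, method = "radix"), ,
                 drop = FALSE]
  rownames(nodes) <- NULL

  out <- character()
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(name, ".sif"))
    writeLines(paste(edges$from, edges$relation, edges$to, sep = "\t"), p)
    out["sif"] <- p
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(name, ".graphml"))
    g <- igraph::graph_from_data_frame(
      transform(edges, predicted = ifelse(is.na(predicted), 99L, predicted),
                observed = ifelse(is.na(observed), 99L, observed)),
      directed = TRUE, vertices = nodes)
    igraph::write_graph(g, p, format = "graphml")
    out["graphml"] <- p
  }
  if ("tsv" %in% formats) {
    pn <- file.path(dir, paste0(name, "_nodes.tsv"))
    pe <- file.path(dir, paste0(name, "_edges.tsv"))
    write.table(nodes, pn, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(edges, pe, sep = "\t", quote = FALSE, row.names = FALSE)
    out["nodes"] <- pn; out["edges"] <- pe
  }
  invisible(out)
}
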