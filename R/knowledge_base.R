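# Knowledge base of signed causal statements: parsing, validation, indexing.

#' Closed vocabulary of entity kinds
#'
#' Only entities of kind `"transcript"` are comparable with expression data;
#' all other kinds can act as regulators or intermediates.
#' @export
kb_entity_kinds <- c("protein", "transcript", "compound", "process",
                     "phenotype", "other")

#' Construct a knowledge graph of signed causal statements
#'
#' A causal statement asserts that an increase in `source` increases
#' (`sign = +1`) or decreases (`sign = -1`) `target`. Duplicate
#' (source, sign, target) triples are collapsed and their evidence lists
#' merged; contradictory duplicates (both signs present for the same
#' source/target pair) are kept and resolved as ambiguity at prediction
#' time. Self-loops are invalid.
#'
#' @param statements data.frame with columns `source`, `sign` (+1/-1),
#'   `target`, and either a list-column `evidence` (each element a
#'   data.frame with columns `citation`, `quote`) or character columns
#'   `citation`/`quote`.
#' @param entities data.frame with columns `id`, `kind` (see
#'   [kb_entity_kinds]) and optionally `label`.
#' @return An object of class `causal_kb`: list with `entities`,
#'   `statements` (collapsed, with list-column `evidence` and `n_evidence`),
#'   and `transcript_index` (ids of kind `"transcript"`).
#' @seealso [parse_kb()], [write_kb()], [export_kb()]
#' @export
causal_kb <- function(statements, entities) {
  stopifnot(is.data.frame(statements), is.data.frame(entities))
  need <- c("source", "sign", "target")
  if (!all(need %in% names(statements)))
    stop("statements must have columns: ", paste(need, collapse = ", "))
  if (!all(c("id", "kind") %in% names(entities)))
    stop("entities must have columns: id, kind")

  statements$source <- as.character(statements$source)
  statements$target <- as.character(statements$target)
  statements$sign <- as.integer(statements$sign)
  if (!all(statements$sign %in% c(-1L, 1L)))
    stop("statement sign must be +1 or -1")
  if (any(statements$source == statements$target))
    stop("self-loop statement(s): ",
         paste(unique(statements$source[statements$source == statements$target]),
               collapse = ", "))

  entities$id <- as.character(entities$id)
  entities$kind <- as.character(entities$kind)
  if (anyDuplicated(entities$id))
    stop("duplicate entity id(s): ",
         paste(unique(entities$id[duplicated(entities$id)]), collapse = ", "))
  bad_kind <- setdiff(unique(entities$kind), kb_entity_kinds)
  if (length(bad_kind))
    stop("unknown entity kind(s): ", paste(bad_kind, collapse = ", "))
  if (is.null(entities$label)) entities$label <- entities$id
  missing_ent <- setdiff(c(statements$source, statements$target), entities$id)
  if (length(missing_ent))
    stop("statement endpoint(s) missing from entities: ",
         paste(missing_ent, collapse = ", "))

  if (!"evidence" %in% names(statements)) {
    cit <- if (is.null(statements$citation)) rep("", nrow(statements)) else
      as.character(statements$citation)
    quo <- if (is.null(statements$quote)) rep("", nrow(statements)) else
      as.character(statements$quote)
    statements$evidence <- lapply(seq_len(nrow(statements)), function(i) {
      if (!nzchar(cit[i]) && !nzchar(quo[i]))
        data.frame(citation = character(), quote = character())
      else data.frame(citation = cit[i], quote = quo[i])
    })
  }

  key <- paste(statements$source, statements$sign, statements$target,
               sep = "\r")
  first <- !duplicated(key)
  if (any(!first)) {
    ev_merged <- lapply(split(statements$evidence, factor(key, levels = key[first])),
                        function(evs) do.call(rbind, evs))
    out <- statements[first, c("source", "sign", "target")]
    out$evidence <- unname(ev_merged)
  } else {
    out <- statements[, c("source", "sign", "target")]
    out$evidence <- statements$evidence
  }
  ord <- order(out$source, out$target, out$sign, method = "radix")
  out <- out[ord, ]
  rownames(out) <- NULL
  out$n_evidence <- vapply(out$evidence, nrow, integer(1))

  ents <- entities[order(entities$id, method = "radix"),
                   c("id", "kind", "label")]
  rownames(ents) <- NULL
  structure(list(entities = ents,
                 statements = out,
                 transcript_index = ents$id[ents$kind == "transcript"]),
            class = "causal_kb")
}

#' @export
print.causal_kb <- function(x, ...) {
  cat("Causal knowledge graph\n")
  cat("  entities:   ", nrow(x$entities), "\n")
  cat("  statements: ", nrow(x$statements),
      sprintf(" (%d with literature evidence)\n", sum(x$statements$n_evidence > 0)))
  cat("  transcripts:", length(x$transcript_index), "\n")
  invisible(x)
}

default_sign_tokens <- c("+" = 1L, "-" = -1L,
                         "increases" = 1L, "decreases" = -1L)

kb_file_columns <- c("source_id", "source_kind", "sign",
                     "target_id", "target_kind", "citation", "quote")

#' Parse a knowledge-base file into a causal knowledge graph
#'
#' Reads a UTF-8, tab-separated file with header columns
#' `source_id, source_kind, sign, target_id, target_kind, citation, quote`.
#' Sign tokens are configurable; the default dialect accepts `+`/`-` and
#' `increases`/`decreases`. Duplicate triples collapse with merged evidence.
#' Self-loop lines and blank lines are rejected (with a warning) and
#' counted; malformed lines, unknown sign tokens, unknown entity kinds and
#' conflicting kind declarations are errors naming the offending line.
#'
#' @param path file path.
#' @param sign_tokens named integer vector mapping sign tokens to +1/-1.
#' @return A `causal_kb`; `attr(, "report")` holds counts of entities,
#'   statements, transcripts, input lines and rejected lines.
#' @export
parse_kb <- function(path, sign_tokens = default_sign_tokens) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(raw) == 0 || all(!nzchar(trimws(raw))))
    stop("empty knowledge-base file: ", path)
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, kb_file_columns))
    stop("bad header; expected: ", paste(kb_file_columns, collapse = ", "))
  body <- raw[-1]
  lineno <- seq_along(body) + 1L

  blank <- !nzchar(trimws(body))
  n_rejected <- sum(blank)
  body <- body[!blank]
  lineno <- lineno[!blank]
  if (length(body) == 0)
    stop("empty knowledge-base file (header but no statements): ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty quote fields drop off strsplit; pad 6-field lines
  parts[nf == 6L] <- lapply(parts[nf == 6L], function(p) c(p, ""))
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1]
    stop(sprintf("malformed line %d: expected 7 tab-separated fields, got %d",
                 lineno[i], nf[i]))
  }
  m <- do.call(rbind, parts)
  colnames(m) <- kb_file_columns

  sgn_tok <- m[, "sign"]
  unknown <- !(sgn_tok %in% names(sign_tokens))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("unknown sign token '%s' on line %d", sgn_tok[i], lineno[i]))
  }
  for (kc in c("source_kind", "target_kind")) {
    bad <- !(m[, kc] %in% kb_entity_kinds)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unknown entity kind '%s' on line %d", m[i, kc], lineno[i]))
    }
  }

  self <- m[, "source_id"] == m[, "target_id"]
  if (any(self)) {
    warning(sprintf("rejected %d self-loop line(s): %s", sum(self),
                    paste(lineno[self], collapse = ", ")))
    n_rejected <- n_rejected + sum(self)
    m <- m[!self, , drop = FALSE]
    if (nrow(m) == 0) stop("no valid statements after rejecting self-loops")
  }

  ent <- rbind(data.frame(id = m[, "source_id"], kind = m[, "source_kind"]),
               data.frame(id = m[, "target_id"], kind = m[, "target_kind"]))
  ent <- unique(ent)
  if (anyDuplicated(ent$id)) {
    dup <- unique(ent$id[duplicated(ent$id)])
    stop("conflicting kind declarations for entity id(s): ",
         paste(dup, collapse = ", "))
  }

  st <- data.frame(source = m[, "source_id"],
                   sign = unname(sign_tokens[m[, "sign"]]),
                   target = m[, "target_id"],
                   citation = m[, "citation"],
                   quote = m[, "quote"])
  kb <- causal_kb(st, ent)
  attr(kb, "report") <- list(n_entities = nrow(kb$entities),
                             n_statements = nrow(kb$statements),
                             n_transcripts = length(kb$transcript_index),
                             n_lines = length(raw) - 1L,
                             n_rejected = n_rejected)
  kb
}

#' Write a knowledge graph to the tab-separated statement format
#'
#' One line per (statement, evidence entry); statements without evidence
#' produce a single line with empty citation/quote. The output re-parses to
#' an identical graph.
#'
#' @param kg a `causal_kb`.
#' @param path output file path.
#' @param sign_tokens named vector as in [parse_kb()]; the first token of
#'   each sign is used when writing.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kg, path, sign_tokens = default_sign_tokens) {
  stopifnot(inherits(kg, "causal_kb"))
  kind <- setNames(kg$entities$kind, kg$entities$id)
  tok_plus <- names(sign_tokens)[match(1L, sign_tokens)]
  tok_minus <- names(sign_tokens)[match(-1L, sign_tokens)]
  rows <- lapply(seq_len(nrow(kg$statements)), function(i) {
    s <- kg$statements[i, ]
    ev <- s$evidence[[1]]
    if (nrow(ev) == 0) ev <- data.frame(citation = "", quote = "")
    data.frame(source_id = s$source,
               source_kind = unname(kind[s$source]),
               sign = if (s$sign > 0) tok_plus else tok_minus,
               target_id = s$target,
               target_kind = unname(kind[s$target]),
               citation = ev$citation,
               quote = ev$quote)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a knowledge graph to an igraph object
#'
#' Vertices carry `kind` and `label`; edges carry `sign`, `relation`
#' (`"increases"`/`"decreases"`) and `n_evidence`.
#' @param kg a `causal_kb`.
#' @return an [igraph::igraph] directed graph.
#' @export
kb_to_igraph <- function(kg) {
  stopifnot(inherits(kg, "causal_kb"))
  edges <- data.frame(from = kg$statements$source,
                      to = kg$statements$target,
                      sign = kg$statements$sign,
                      relation = ifelse(kg$statements$sign > 0,
                                        "increases", "decreases"),
                      n_evidence = kg$statements$n_evidence)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = kg$entities$id,
                                                      kind = kg$entities$kind,
                                                      label = kg$entities$label))
}

#' Export the raw knowledge graph for network viewers
#'
#' `"sif"` writes `source <tab> relation <tab> target` with relation
#' `increases`/`decreases`; `"graphml"` writes GraphML with sign and
#' evidence-count edge attributes (via igraph).
#'
#' @param kg a `causal_kb`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_kb <- function(kg, path, format = c("sif", "graphml")) {
  stopifnot(inherits(kg, "causal_kb"))
  format <- match.arg(format)
  if (format == "sif") {
    rel <- ifelse(kg$statements$sign > 0, "increases", "decreases")
    writeLines(paste(kg$statements$source, rel, kg$statements$target,
                     sep = "\t"), path)
  } else {
    igraph::write_graph(kb_to_igraph(kg), path, format = "graphml")
  }
  invisible(path)
}

#' Map observed expression changes onto the knowledge base
#'
#' Restricts the measured universe to transcripts present in the knowledge
#' base (opaque-string, case-sensitive identifier match) and reports the
#' mapping rate: the fraction of significant transcripts that mapped.
#'
#' @param kg a `causal_kb`.
#' @param oc an [observed_changes] object.
#' @return A `mapped_changes` object: `universe` (mapped measured ids),
#'   `direction` (named +1/-1 vector over mapped significant transcripts),
#'   `mapping_rate`, `unmapped` (significant ids absent from the KB), and
#'   the significance `thresholds` carried over.
#' @export
map_changes <- function(kg, oc) {
  stopifnot(inherits(kg, "causal_kb"), inherits(oc, "observed_changes"))
  if (length(oc$universe) == 0) stop("observed changes are empty")
  sig <- oc$direction
  if (length(sig) == 0) stop("no significant transcripts in observed changes")
  universe <- intersect(oc$universe, kg$transcript_index)
  mapped_sig <- sig[names(sig) %in% universe]
  if (length(mapped_sig) == 0)
    stop("zero significant transcripts mapped to the knowledge base; ",
         "check that expression and knowledge-base identifiers share a namespace")
  structure(list(universe = universe,
                 direction = mapped_sig,
                 mapping_rate = length(mapped_sig) / length(sig),
                 unmapped = setdiff(names(sig), universe),
                 thresholds = oc$thresholds),
            class = "mapped_changes")
}

#' @export
print.mapped_changes <- function(x, ...) {
  cat("Mapped expression changes\n")
  cat("  mapped universe:      ", length(x$universe), "transcripts\n")
  cat("  significant (mapped): ", length(x$direction),
      sprintf(" (%d up, %d down)\n", sum(x$direction == 1), sum(x$direction == -1)))
  cat("  mapping rate:         ", sprintf("%.3f", x$mapping_rate), "\n")
  invisible(x)
}
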