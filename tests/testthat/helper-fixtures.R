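# Fixture builders shared across tests. All fixtures are constructed in
# code; the only files read are the packaged demo TSVs.

# Build a causal_kb from a triples data.frame (source, sign, target).
# Kinds: explicit named vector wins; otherwise ids that never appear as a
# source are transcripts, the rest proteins.
toy_kb <- function(triples, kinds = NULL, extra_entities = NULL) {
  ids <- unique(c(triples$source, triples$target, names(kinds),
                  extra_entities))
  kind <- setNames(ifelse(ids %in% triples$source, "protein", "transcript"),
                   ids)
  if (!is.null(kinds)) kind[names(kinds)] <- kinds
  causal_kb(triples, data.frame(id = ids, kind = unname(kind[ids])))
}

# mapped_changes built directly from up/down significant id vectors.
make_mapped <- function(universe, up = character(), down = character()) {
  structure(list(universe = universe,
                 direction = c(setNames(rep(1, length(up)), up),
                               setNames(rep(-1, length(down)), down)),
                 mapping_rate = 1, unmapped = character(),
                 thresholds = c(adj_p = 0.05, fold_change = 1.3)),
            class = "mapped_changes")
}

# A cre_prediction with prescribed signs (named +1/-1/0 vector).
make_prediction <- function(signs, entity = "H", direction = 1L) {
  structure(list(entity = entity, direction = as.integer(direction),
                 depth = 1L, signs = signs, paths = NULL),
            class = "cre_prediction")
}

# Minimal cre_results rows from parallel vectors; list-columns derived
# from the given sets.
make_results <- function(entity, direction, correctness_p, enrichment_p,
                         n_correct, n_incorrect = 0L, n_ambiguous = 0L,
                         correct_set = NULL, incorrect_set = NULL,
                         ambiguous_set = NULL, obs_dir = NULL) {
  n <- length(entity)
  blank <- replicate(n, character(), simplify = FALSE)
  correct_set <- correct_set %||% blank
  incorrect_set <- incorrect_set %||% blank
  ambiguous_set <- ambiguous_set %||% blank
  dirvec <- function(ids) {
    if (is.null(obs_dir)) setNames(rep(1, length(ids)), ids) else
      obs_dir[ids]
  }
  out <- data.frame(entity = entity, direction = as.integer(direction),
                    label = paste0(entity, ifelse(direction > 0, "+", "-")),
                    n_correct = as.integer(n_correct),
                    n_incorrect = as.integer(n_incorrect),
                    n_ambiguous = as.integer(n_ambiguous),
                    score = as.integer(n_correct) - as.integer(n_incorrect),
                    correctness_p = correctness_p,
                    enrichment_p = enrichment_p,
                    percent_correct = ifelse(n_correct + n_incorrect > 0,
                                             n_correct / (n_correct + n_incorrect),
                                             NA_real_),
                    n_downstream = as.integer(n_correct) +
                      as.integer(n_incorrect))
  out$correct_set <- lapply(correct_set, sort)
  out$incorrect_set <- lapply(incorrect_set, sort)
  out$ambiguous_set <- lapply(ambiguous_set, sort)
  out$evidence <- lapply(correct_set, function(ids) {
    d <- dirvec(ids); paste0(sort(ids), ifelse(d[sort(ids)] > 0, "/+", "/-"))
  })
  out$contra <- lapply(incorrect_set, function(ids) {
    d <- dirvec(ids); paste0(sort(ids), ifelse(d[sort(ids)] > 0, "/-", "/+"))
  })
  class(out) <- c("cre_results", "data.frame")
  out
}

# Results rows with prescribed evidence feature sets (for clustering).
make_evidence_results <- function(feats) {
  n <- length(feats)
  out <- make_results(entity = names(feats), direction = rep(1L, n),
                      correctness_p = seq(1e-6, 1e-3, length.out = n),
                      enrichment_p = rep(1e-4, n),
                      n_correct = lengths(feats))
  out$evidence <- lapply(feats, unique)
  out
}

demo_kg <- function() parse_kb(system.file("extdata", "demo_kb.tsv",
                                           package = "upcause"))
demo_mapped <- function(kg = demo_kg()) {
  map_changes(kg, read_expression(system.file("extdata",
                                              "demo_expression.tsv",
                                              package = "upcause")))
}

# Write KB lines (list of character vectors of 7 fields) to a temp file.
write_kb_file <- function(rows, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- vapply(rows, paste, character(1), collapse = "\t")
  if (header)
    lines <- c(paste(c("source_id", "source_kind", "sign", "target_id",
                       "target_kind", "citation", "quote"), collapse = "\t"),
               lines)
  writeLines(lines, path)
  path
}

kb_row <- function(src, sgn, tgt, src_kind = "protein",
                   tgt_kind = "transcript", cit = "", quo = "") {
  c(src, src_kind, sgn, tgt, tgt_kind, cit, quo)
}
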