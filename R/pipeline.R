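# End-to-end workflow: score -> filter -> rank -> cluster -> merge ->
# export, with a YAML-serializable run configuration.

#' Run configuration
#'
#' @param kb path to the knowledge-base TSV.
#' @param expression path to the differential-expression TSV.
#' @param out_dir output directory.
#' @param gene_sets optional path to a gene-set table (columns `term`,
#'   `gene`) for GO-style enrichment.
#' @param depth maximum statement-chain length.
#' @param min_targets minimum reachable transcripts to enumerate a
#'   hypothesis.
#' @param p_cutoff,fc_cutoff significance thresholds for the expression
#'   calls.
#' @param filter a [filter_config()].
#' @param cluster_threshold minimum average evidence similarity to merge
#'   clusters.
#' @param verbose log progress to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(kb, expression, out_dir, gene_sets = NULL,
                       depth = 1L, min_targets = 3L,
                       p_cutoff = 0.05, fc_cutoff = 1.3,
                       filter = filter_config(), cluster_threshold = 0.15,
                       verbose = TRUE) {
  stopifnot(inherits(filter, "filter_config"),
            cluster_threshold >= 0, cluster_threshold <= 1)
  structure(list(kb = kb, expression = expression, out_dir = out_dir,
                 gene_sets = gene_sets, depth = as.integer(depth),
                 min_targets = as.integer(min_targets),
                 p_cutoff = p_cutoff, fc_cutoff = fc_cutoff,
                 filter = filter, cluster_threshold = cluster_threshold,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' CLI flags are expected to override file values; the round trip
#' preserves all fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  flt <- do.call(filter_config, y$filter %||% list())
  y$filter <- NULL
  do.call(run_config, c(y, list(filter = flt)))
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- unclass(cfg)
  y$filter <- unclass(y$filter)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full causal-reasoning workflow
#'
#' Parses the knowledge base, calls and maps the expression changes,
#' scores all enumerated hypotheses, applies the admission filter, ranks
#' and clusters the survivors, merges them into one model, and writes:
#' `hypotheses.tsv` (filtered, ranked, clustered results),
#' `hypotheses_all.tsv` (every scored hypothesis), `clusters.tsv`,
#' `evidence_matrix.tsv`, model exports (`model.sif`, `model.graphml`,
#' node/edge TSVs), optionally `go_enrichment.tsv`, the effective
#' configuration (`config.yaml`) and a `run.log` recording mapping rate,
#' universe sizes and the configuration file's checksum. Repeated
#' invocations on the same inputs are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the knowledge graph, mapped changes,
#'   scored/filtered results, merged model and output paths.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (cfg$verbose) message(sprintf(...))
  for (p in c(cfg$kb, cfg$expression, cfg$gene_sets))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  kg <- parse_kb(cfg$kb)
  say("knowledge base: %d entities, %d statements, %d transcripts",
      nrow(kg$entities), nrow(kg$statements), length(kg$transcript_index))
  oc <- read_expression(cfg$expression, cfg$p_cutoff, cfg$fc_cutoff)
  mapped <- map_changes(kg, oc)
  say("mapped %d/%d significant transcripts (rate %.3f), universe %d",
      length(mapped$direction), length(oc$direction),
      mapped$mapping_rate, length(mapped$universe))

  scored <- score_hypotheses(kg, mapped, depth = cfg$depth,
                             min_targets = cfg$min_targets)
  say("scored %d hypotheses", nrow(scored))
  kept <- rank_hypotheses(filter_hypotheses(scored, cfg$filter))
  say("%d hypotheses pass the admission filter", nrow(kept))
  kept <- cluster_hypotheses(kept, cfg$cluster_threshold)

  paths <- list(
    hypotheses = file.path(cfg$out_dir, "hypotheses.tsv"),
    all = file.path(cfg$out_dir, "hypotheses_all.tsv"),
    clusters = file.path(cfg$out_dir, "clusters.tsv"),
    config = file.path(cfg$out_dir, "config.yaml"),
    log = file.path(cfg$out_dir, "run.log"))
  results_table(kept, paths$hypotheses)
  results_table(scored, paths$all)
  model <- NULL
  if (nrow(kept) > 0) {
    cluster_table(kept, paths$clusters)
    model <- merge_hypotheses(kept, mapped)
    write_evidence_matrix(evidence_matrix(kept),
                          file.path(cfg$out_dir, "evidence_matrix.tsv"))
    export_model(model, mapped, cfg$out_dir, name = "model", kg = kg)
    say("merged model explains %.1f%% of significant mapped changes",
        100 * model$pct_unique_correct)
  }
  if (!is.null(cfg$gene_sets)) {
    sets <- read.delim(cfg$gene_sets, sep = "\t", quote = "",
                       stringsAsFactors = FALSE)
    go <- go_enrichment(sets, mapped)
    write.table(go, file.path(cfg$out_dir, "go_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_config(cfg, paths$config)
  writeLines(c(
    sprintf("config_md5: %s", unname(tools::md5sum(paths$config))),
    sprintf("measured_universe: %d", length(oc$universe)),
    sprintf("mapped_universe: %d", length(mapped$universe)),
    sprintf("significant: %d", length(oc$direction)),
    sprintf("significant_mapped: %d", length(mapped$direction)),
    sprintf("mapping_rate: %.6f", mapped$mapping_rate),
    sprintf("hypotheses_scored: %d", nrow(scored)),
    sprintf("hypotheses_filtered: %d", nrow(kept)),
    sprintf("clusters: %d",
            if (nrow(kept)) length(attr(kept, "clusters")) else 0L)),
    paths$log)
  invisible(list(kg = kg, observed = oc, mapped = mapped, scored = scored,
                 filtered = kept, model = model, paths = paths))
}
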