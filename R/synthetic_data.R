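# Synthetic knowledge bases and differential-expression profiles with
# planted upstream perturbations, so every stage of the pipeline is
# testable without licensed content.

#' Simulation configuration
#'
#' Defaults are sized to a desk-scale study: 200 regulators with a mean of
#' 15 transcript targets each over a 2,000-transcript universe, 5 planted
#' active regulators whose targets respond consistently 80% of the time
#' and with flipped sign 5% of the time, a 2% background significance
#' rate, and 2% contradictory duplicate statements. Identical seed and
#' configuration give identical outputs.
#'
#' @param n_regulators number of regulator entities.
#' @param n_transcripts number of transcript entities.
#' @param out_degree mean number of transcript targets per regulator
#'   (Poisson).
#' @param p_negative_edge probability a statement sign is -1.
#' @param n_active number of planted active regulators.
#' @param tpr fraction of a planted regulator's targets responding
#'   consistently with the propagated sign.
#' @param flip_rate fraction responding with the opposite sign.
#' @param background_rate probability an unrelated transcript is called
#'   significant (random direction).
#' @param ambiguity_rate probability a statement gets a contradictory
#'   opposite-sign duplicate.
#' @param reg_out_degree mean number of regulator-to-regulator edges per
#'   regulator (Poisson; 0 disables, useful only for depth > 1 testing).
#' @param mapping_rate target fraction of significant transcripts that map
#'   to the knowledge base; below 1, extra measured-but-unmapped
#'   significant transcripts are injected to emulate incomplete coverage.
#' @param seed integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regulators = 200, n_transcripts = 2000,
                       out_degree = 15, p_negative_edge = 0.3,
                       n_active = 5, tpr = 0.8, flip_rate = 0.05,
                       background_rate = 0.02, ambiguity_rate = 0.02,
                       reg_out_degree = 0, mapping_rate = 1, seed = 1L) {
  rates <- c(p_negative_edge = p_negative_edge, tpr = tpr,
             flip_rate = flip_rate, background_rate = background_rate,
             ambiguity_rate = ambiguity_rate, mapping_rate = mapping_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (tpr + flip_rate > 1) stop("tpr + flip_rate must not exceed 1")
  if (n_regulators < 1 || n_transcripts < 1)
    stop("degenerate configuration: need at least 1 regulator and 1 transcript")
  if (mapping_rate == 0) stop("mapping_rate must be positive")
  stopifnot(n_active >= 0, n_active <= n_regulators,
            out_degree >= 0, reg_out_degree >= 0)
  structure(list(n_regulators = as.integer(n_regulators),
                 n_transcripts = as.integer(n_transcripts),
                 out_degree = out_degree,
                 p_negative_edge = p_negative_edge,
                 n_active = as.integer(n_active),
                 tpr = tpr, flip_rate = flip_rate,
                 background_rate = background_rate,
                 ambiguity_rate = ambiguity_rate,
                 reg_out_degree = reg_out_degree,
                 mapping_rate = mapping_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a knowledge base
#'
#' Random bipartite-plus-chain graph: each regulator receives a
#' Poisson(`out_degree`) set of distinct transcript targets (and, when
#' `reg_out_degree > 0`, Poisson regulator-to-regulator edges for
#' depth testing). Signs are negative with probability `p_negative_edge`;
#' a contradictory opposite-sign duplicate is injected per statement with
#' probability `ambiguity_rate`.
#'
#' @param cfg a [sim_config()].
#' @return A `causal_kb` with regulators of kind `"protein"` and targets
#'   of kind `"transcript"`.
#' @export
simulate_kb <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  regs <- sprintf("R%04d", seq_len(cfg$n_regulators))
  txs <- sprintf("T%05d", seq_len(cfg$n_transcripts))
  ks <- pmin(rpois(cfg$n_regulators, cfg$out_degree), cfg$n_transcripts)
  src <- rep(regs, ks)
  tgt <- unlist(lapply(ks, function(k) sample(txs, k)), use.names = FALSE)
  if (cfg$reg_out_degree > 0 && cfg$n_regulators > 1) {
    kr <- pmin(rpois(cfg$n_regulators, cfg$reg_out_degree),
               cfg$n_regulators - 1L)
    src <- c(src, rep(regs, kr))
    tgt <- c(tgt, unlist(lapply(seq_along(kr), function(i)
      sample(setdiff(regs, regs[i]), kr[i])), use.names = FALSE))
  }
  if (length(src) == 0)
    stop("degenerate configuration produced an empty statement set; ",
         "increase out_degree")
  sgn <- ifelse(runif(length(src)) < cfg$p_negative_edge, -1L, 1L)
  dup <- runif(length(src)) < cfg$ambiguity_rate
  st <- data.frame(source = c(src, src[dup]),
                   sign = c(sgn, -sgn[dup]),
                   target = c(tgt, tgt[dup]),
                   citation = paste0("SIM-", seq_len(length(src) + sum(dup))),
                   quote = "")
  ents <- data.frame(id = c(regs, txs),
                     kind = c(rep("protein", length(regs)),
                              rep("transcript", length(txs))))
  causal_kb(st, ents)
}

#' Simulate an experiment with planted upstream perturbations
#'
#' Picks `n_active` regulators (among those with at least one transcript
#' target) with random directions. Each unambiguous direct target of a
#' planted regulator is called significant with the propagated sign with
#' probability `tpr`, with the opposite sign with probability `flip_rate`,
#' and is otherwise unchanged; ambiguous targets respond with a random
#' direction with probability `tpr`. Each transcript is assigned by at
#' most one planted regulator (first in planting order wins). All other
#' transcripts are significant with probability `background_rate` and
#' random direction. With `mapping_rate < 1`, extra unmapped significant
#' transcripts are injected so the mapped fraction approximates the
#' target.
#'
#' @param kg a `causal_kb` from [simulate_kb()].
#' @param cfg the same [sim_config()].
#' @return List with `changes` (an [observed_changes]) and `truth`
#'   (data.frame `entity`, `direction`, `label` of planted hypotheses).
#' @export
simulate_experiment <- function(kg, cfg) {
  stopifnot(inherits(kg, "causal_kb"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  txs <- kg$transcript_index
  st <- kg$statements
  cand <- sort(unique(st$source[st$target %in% txs & !(st$source %in% txs)]))
  if (cfg$n_active > length(cand))
    stop("fewer eligible regulators than n_active")
  active <- if (cfg$n_active > 0) sample(cand, cfg$n_active) else character()
  dirs <- if (cfg$n_active > 0) sample(c(1L, -1L), cfg$n_active, TRUE) else
    integer()

  assigned <- numeric(0)
  for (j in seq_along(active)) {
    rows <- st$source == active[j] & st$target %in% txs
    sgn_by_tgt <- tapply(st$sign[rows], st$target[rows],
                         function(s) if (length(unique(s)) > 1) 0L else s[1])
    tgts <- setdiff(names(sgn_by_tgt), names(assigned))
    for (t in tgts) {
      s <- sgn_by_tgt[[t]]
      u <- runif(1)
      if (s == 0L) {
        if (u < cfg$tpr) assigned[t] <- sample(c(1, -1), 1)
      } else if (u < cfg$tpr) {
        assigned[t] <- dirs[j] * s
      } else if (u < cfg$tpr + cfg$flip_rate) {
        assigned[t] <- -dirs[j] * s
      }
    }
  }
  rest <- setdiff(txs, names(assigned))
  hit <- rest[runif(length(rest)) < cfg$background_rate]
  if (length(hit))
    assigned[hit] <- sample(c(1, -1), length(hit), TRUE)

  universe <- txs
  if (cfg$mapping_rate < 1 && length(assigned) > 0) {
    n_extra <- round(length(assigned) * (1 - cfg$mapping_rate) /
                       cfg$mapping_rate)
    if (n_extra > 0) {
      extra <- sprintf("U%05d", seq_len(n_extra))
      universe <- c(universe, extra)
      assigned[extra] <- sample(c(1, -1), n_extra, TRUE)
    }
  }
  list(changes = observed_changes(universe, assigned),
       truth = data.frame(entity = active, direction = dirs,
                          label = paste0(active,
                                         ifelse(dirs > 0, "+", "-"))))
}

#' Write simulated fixtures to disk
#'
#' Writes the knowledge base, expression table and planted ground truth in
#' the same dialects the parsers read.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths (`kb`, `expression`, `truth`),
#'   invisibly.
#' @export
simulate_fixtures <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kg <- simulate_kb(cfg)
  exp <- simulate_experiment(kg, cfg)
  paths <- c(kb = file.path(dir, "kb.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_kb(kg, paths["kb"])
  write_expression(exp$changes, paths["expression"])
  write.table(exp$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
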