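# Differential-expression calls: the measured universe and per-transcript
# direction calls for significant transcripts.

#' Construct an observed-changes object
#'
#' @param universe character vector of all measured transcript ids.
#' @param direction named numeric vector (+1 up / -1 down) over the
#'   significant transcripts only; names must be a subset of `universe`.
#' @param p_cutoff,fc_cutoff the significance thresholds that produced the
#'   calls, recorded as metadata.
#' @return An object of class `observed_changes`.
#' @export
observed_changes <- function(universe, direction,
                             p_cutoff = 0.05, fc_cutoff = 1.3) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  direction <- setNames(as.numeric(direction), names(direction))
  if (length(direction) && is.null(names(direction)))
    stop("direction must be a named vector")
  if (!all(direction %in% c(-1, 1)))
    stop("direction values must be +1 or -1")
  if (!all(names(direction) %in% universe))
    stop("directed transcripts must belong to the measured universe")
  structure(list(universe = universe,
                 direction = direction,
                 thresholds = c(adj_p = p_cutoff, fold_change = fc_cutoff)),
            class = "observed_changes")
}

#' @export
print.observed_changes <- function(x, ...) {
  cat("Observed expression changes\n")
  cat("  measured:    ", length(x$universe), "transcripts\n")
  cat("  significant: ", length(x$direction),
      sprintf(" (%d up, %d down) at adj p < %g, |FC| >= %g\n",
              sum(x$direction == 1), sum(x$direction == -1),
              x$thresholds["adj_p"], x$thresholds["fold_change"]))
  invisible(x)
}

#' Read a differential-expression table and call significance
#'
#' Expects a tab-separated file with header columns
#' `gene_id, log2_fc, adj_p`. A transcript is called significant when
#' `adj_p < p_cutoff` and `|log2_fc| >= log2(fc_cutoff)`; its direction is
#' the sign of `log2_fc`.
#'
#' @param path file path.
#' @param p_cutoff adjusted p-value cutoff (default 0.05).
#' @param fc_cutoff fold-change cutoff on the linear scale (default 1.3).
#' @return An [observed_changes] object.
#' @export
read_expression <- function(path, p_cutoff = 0.05, fc_cutoff = 1.3) {
  tab <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2_fc", "adj_p")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  tab$gene_id <- as.character(tab$gene_id)
  sig <- tab$adj_p < p_cutoff & abs(tab$log2_fc) >= log2(fc_cutoff)
  observed_changes(universe = tab$gene_id,
                   direction = setNames(sign(tab$log2_fc[sig]),
                                        tab$gene_id[sig]),
                   p_cutoff = p_cutoff, fc_cutoff = fc_cutoff)
}

#' Write an observed-changes object as an expression table
#'
#' Synthesizes deterministic `log2_fc`/`adj_p` columns consistent with the
#' recorded thresholds (significant transcripts get `adj_p` at a fifth of
#' the cutoff and a unit log2 fold change in the called direction), so the
#' file round-trips through [read_expression()].
#'
#' @param oc an [observed_changes] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(oc, path) {
  stopifnot(inherits(oc, "observed_changes"))
  dir <- oc$direction[match(oc$universe, names(oc$direction))]
  sig <- !is.na(dir)
  out <- data.frame(gene_id = oc$universe,
                    log2_fc = ifelse(sig, ifelse(dir > 0, 1, -1), 0),
                    adj_p = ifelse(sig, oc$thresholds[["adj_p"]] / 5, 0.9))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
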