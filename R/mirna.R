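# All-tools consensus of miRNA-target predictions.  Relation identity is the
# (mirna_id, gene_id) pair: the predictors report incompatible binding-site
# coordinates, so intersection is taken at the relation level.

#' Consensus miRNA-target relations across prediction tools
#'
#' Exact intersection of per-tool relation sets: a relation is kept iff every
#' tool predicted it.
#'
#' @param sets Either a long-format data.frame with columns tool, mirna_id,
#'   gene_id (as from [read_target_table()] or [simulate_target_sets()]), or
#'   a list of per-tool data.frames with columns mirna_id, gene_id.
#' @return data.frame (mirna_id, gene_id) sorted by miRNA then gene.
#' @export
consensus_targets <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("tool", "mirna_id", "gene_id") %in% names(sets)))
    sets <- split(sets[c("mirna_id", "gene_id")], sets$tool)
  }
  if (!is.list(sets) || length(sets) == 0L)
    stop("need at least one prediction set")
  keysets <- lapply(sets, function(s) {
    k <- paste(s$mirna_id, s$gene_id, sep = "\t")
    if (anyDuplicated(k))
      stop("duplicate relation within one tool's set: ",
           sub("\t", " -> ", k[duplicated(k)][1], fixed = TRUE))
    k
  })
  keep <- sort(Reduce(intersect, keysets))
  if (length(keep) == 0L)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(keep, "\t", fixed = TRUE))
  out <- data.frame(mirna_id = parts[, 1], gene_id = parts[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
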