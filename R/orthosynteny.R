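# Best-reciprocal-hit (BRH) orthology and microsynteny block detection.
#
# Orthologous counterparts between two proteomes are defined as best
# reciprocal hits after a strict e-value filter.  Each kept pair carries a
# similarity score: aligning ratio (aligned columns / length of the shorter
# protein) times fractional identity.  Microsynteny blocks are clusters of
# at least `min_anchors` ortholog anchors whose genes sit on one scaffold per
# species with at most `max_gap` intervening genes between linked anchors in
# BOTH species.  Intervening genes are counted on the scaffold's full gene
# list, so non-ortholog genes interrupt a block.  Blocks are proximity
# clusters (connected components of the anchor link graph); whether the
# anchor order is also collinear between the species is reported per block
# as the `order_consistent` flag, not required.

#' Parameters of the synteny detection rule
#'
#' Defaults are the standard microsynteny rule for wasp comparative analyses:
#' at least 3 orthologous counterparts, not interrupted by more than 5 genes,
#' e-value cutoff 0.01.
#'
#' @param min_anchors Minimum ortholog anchors per block (>= 1, default 3).
#' @param max_gap Maximum intervening genes between linked anchors
#'   (>= 0, default 5).
#' @param evalue_cutoff Strict upper bound on hit e-values (default 0.01).
#' @return Object of class `synteny_params`.
#' @export
synteny_params <- function(min_anchors = 3L, max_gap = 5L,
                           evalue_cutoff = 0.01) {
  if (min_anchors < 1L) stop("min_anchors must be >= 1")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0")
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 evalue_cutoff = as.numeric(evalue_cutoff)),
            class = "synteny_params")
}

#' Aligning-ratio times identity similarity score
#'
#' (align_len / min(q_len, s_len)) * (identity_pct / 100).  The aligning
#' ratio may exceed 1 for gapped alignments longer than the shorter protein.
#'
#' @param align_len Alignment length in columns.
#' @param identity_pct Percent identity in [0, 100].
#' @param q_len,s_len Query and subject sequence lengths (> 0).
#' @return Numeric similarity score (vectorised).
#' @export
similarity_score <- function(align_len, identity_pct, q_len, s_len) {
  shorter <- pmin(q_len, s_len)
  if (any(shorter <= 0)) stop("sequence lengths must be > 0")
  if (any(align_len <= 0)) stop("align_len must be > 0")
  if (any(identity_pct < 0 | identity_pct > 100))
    stop("identity_pct must be in [0, 100]")
  (align_len / shorter) * (identity_pct / 100)
}

# single best hit per query: highest bitscore, ties by lowest evalue, then
# lexicographically smallest subject id
.best_per_query <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Best reciprocal hits between two proteomes
#'
#' Hits are first filtered to `evalue < params$evalue_cutoff` (strict).  For
#' each query the single best hit is kept (highest bitscore; ties broken by
#' lowest e-value, then smallest subject id).  A pair (a, b) is returned iff
#' a's best hit in A->B is b and b's best hit in B->A is a; identical ids are
#' excluded.  The A->B best-hit row supplies the recorded e-value and the
#' similarity score.
#'
#' @param hits_ab,hits_ba Hit tables ([read_hit_table()] layout) for the
#'   A->B and B->A searches.
#' @param len_a,len_b Named numeric vectors of protein lengths for species A
#'   and B (from the sequence files).
#' @param params A [synteny_params()].
#' @return data.frame with columns gene_a, gene_b, evalue, bitscore,
#'   similarity, sorted by gene_a.
#' @export
best_reciprocal_hits <- function(hits_ab, hits_ba, len_a, len_b,
                                 params = synteny_params()) {
  stopifnot(inherits(params, "synteny_params"))
  hits_ab <- hits_ab[hits_ab$evalue < params$evalue_cutoff, , drop = FALSE]
  hits_ba <- hits_ba[hits_ba$evalue < params$evalue_cutoff, , drop = FALSE]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      similarity = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L) return(empty)
  best_ab <- .best_per_query(hits_ab)
  best_ba <- .best_per_query(hits_ba)
  back <- best_ba$sseqid[match(best_ab$sseqid, best_ba$qseqid)]
  keep <- !is.na(back) & back == best_ab$qseqid &
    best_ab$qseqid != best_ab$sseqid
  best_ab <- best_ab[keep, , drop = FALSE]
  if (nrow(best_ab) == 0L) return(empty)
  ql <- len_a[best_ab$qseqid]
  sl <- len_b[best_ab$sseqid]
  if (anyNA(ql))
    stop("no sequence length for gene(s): ",
         paste(unique(best_ab$qseqid[is.na(ql)]), collapse = ", "))
  if (anyNA(sl))
    stop("no sequence length for gene(s): ",
         paste(unique(best_ab$sseqid[is.na(sl)]), collapse = ", "))
  out <- data.frame(
    gene_a = best_ab$qseqid, gene_b = best_ab$sseqid,
    evalue = best_ab$evalue, bitscore = best_ab$bitscore,
    similarity = similarity_score(best_ab$length, best_ab$pident,
                                  as.numeric(ql), as.numeric(sl)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinal gene order per scaffold
#'
#' Assigns each gene a dense 0-based ordinal index within its scaffold, by
#' ascending start coordinate with ties broken by gene_id.
#'
#' @param loci Gene table ([read_gene_table()] layout).
#' @return data.frame of class `gene_order` with columns gene_id, scaffold,
#'   ord.
#' @export
build_gene_order <- function(loci) {
  dup <- unique(loci$gene_id[duplicated(loci$gene_id)])
  if (length(dup) > 0L)
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  o <- order(loci$scaffold, loci$start, loci$gene_id)
  out <- data.frame(gene_id = loci$gene_id[o], scaffold = loci$scaffold[o],
                    stringsAsFactors = FALSE)
  out$ord <- stats::ave(seq_len(nrow(out)), out$scaffold,
                        FUN = seq_along) - 1L
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Detect microsynteny blocks
#'
#' Anchors are 1:1 ortholog pairs placed on the two species' gene orders.
#' Two anchors are linked iff their genes share a scaffold in each species
#' and the number of intervening genes between them is at most
#' `params$max_gap` in species A and in species B.  Blocks are connected
#' components of this link graph (within each scaffold pair) with at least
#' `params$min_anchors` anchors; each anchor belongs to at most one block.
#'
#' @param order_a,order_b [build_gene_order()] results for species A and B.
#' @param pairs Ortholog pairs (gene_a, gene_b), e.g. from
#'   [best_reciprocal_hits()]; must be 1:1.
#' @param params A [synteny_params()].
#' @return Object of class `synteny_blocks`: a list with `blocks` (one row
#'   per block: block_id, scaffold_a, scaffold_b, n_anchors, first_a, last_a,
#'   first_b, last_b, order_consistent) and `anchors` (block_id, gene_a,
#'   gene_b, ord_a, ord_b), both sorted deterministically.
#' @export
detect_synteny_blocks <- function(order_a, order_b, pairs,
                                  params = synteny_params()) {
  stopifnot(inherits(params, "synteny_params"))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("ortholog pairs must be 1:1; run best_reciprocal_hits() first")
  ia <- match(pairs$gene_a, order_a$gene_id)
  ib <- match(pairs$gene_b, order_b$gene_id)
  if (anyNA(ia))
    stop("pair references unknown species-A gene(s): ",
         paste(unique(pairs$gene_a[is.na(ia)]), collapse = ", "))
  if (anyNA(ib))
    stop("pair references unknown species-B gene(s): ",
         paste(unique(pairs$gene_b[is.na(ib)]), collapse = ", "))
  anc <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    scaffold_a = order_a$scaffold[ia],
                    ord_a = order_a$ord[ia],
                    scaffold_b = order_b$scaffold[ib],
                    ord_b = order_b$ord[ib], stringsAsFactors = FALSE)
  blocks <- list(); anchors <- list(); nb <- 0L
  for (grp in split(seq_len(nrow(anc)),
                    paste(anc$scaffold_a, anc$scaffold_b, sep = "\r"))) {
    a <- anc[grp, , drop = FALSE]
    m <- nrow(a)
    if (m < params$min_anchors) next
    # link graph: proximity in both species (gap = index difference - 1)
    da <- abs(outer(a$ord_a, a$ord_a, "-")) - 1L
    db <- abs(outer(a$ord_b, a$ord_b, "-")) - 1L
    adj <- da <= params$max_gap & db <= params$max_gap
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      members <- a[comp == cid, , drop = FALSE]
      if (nrow(members) < params$min_anchors) next
      members <- members[order(members$ord_a), , drop = FALSE]
      nb <- nb + 1L
      db_ord <- diff(members$ord_b)
      blocks[[nb]] <- data.frame(
        scaffold_a = members$scaffold_a[1], scaffold_b = members$scaffold_b[1],
        n_anchors = nrow(members),
        first_a = members$ord_a[1], last_a = members$ord_a[nrow(members)],
        first_b = min(members$ord_b), last_b = max(members$ord_b),
        order_consistent = all(db_ord > 0) || all(db_ord < 0),
        stringsAsFactors = FALSE)
      anchors[[nb]] <- members
    }
  }
  if (nb == 0L) {
    bl <- data.frame(block_id = integer(), scaffold_a = character(),
                     scaffold_b = character(), n_anchors = integer(),
                     first_a = integer(), last_a = integer(),
                     first_b = integer(), last_b = integer(),
                     order_consistent = logical(), stringsAsFactors = FALSE)
    an <- data.frame(block_id = integer(), gene_a = character(),
                     gene_b = character(), scaffold_a = character(),
                     ord_a = integer(), scaffold_b = character(),
                     ord_b = integer(), stringsAsFactors = FALSE)
    return(structure(list(blocks = bl, anchors = an, params = params),
                     class = "synteny_blocks"))
  }
  bl <- do.call(rbind, blocks)
  o <- order(bl$scaffold_a, bl$first_a, bl$scaffold_b, bl$first_b)
  bl <- bl[o, , drop = FALSE]
  bl <- cbind(block_id = seq_len(nrow(bl)), bl)
  an <- do.call(rbind, lapply(seq_along(o), function(i)
    cbind(block_id = i, anchors[[o[i]]])))
  rownames(bl) <- rownames(an) <- NULL
  structure(list(blocks = bl, anchors = an, params = params),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf(paste0("%d synteny block(s), %d anchor pair(s) ",
                     "(min_anchors %d, max_gap %d)\n"),
              nrow(x$blocks), nrow(x$anchors), x$params$min_anchors,
              x$params$max_gap))
  if (nrow(x$blocks) > 0L) print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Consensus gene-order fraction from counts
#'
#' Fraction of ortholog pairs that fall inside any synteny block; the
#' standard summary of how much microsynteny two genomes retain.
#'
#' @param n_syntenic_pairs Ortholog pairs inside blocks.
#' @param n_ortholog_pairs Total ortholog pairs (> 0).
#' @return n_syntenic_pairs / n_ortholog_pairs (a fraction in [0, 1]).
#' @export
consensus_fraction_from_counts <- function(n_syntenic_pairs,
                                           n_ortholog_pairs) {
  if (n_ortholog_pairs <= 0) stop("n_ortholog_pairs must be > 0")
  if (n_syntenic_pairs < 0 || n_syntenic_pairs > n_ortholog_pairs)
    stop("n_syntenic_pairs must be in [0, n_ortholog_pairs]")
  n_syntenic_pairs / n_ortholog_pairs
}

#' Summarise synteny blocks against the ortholog set
#'
#' @param blocks A [detect_synteny_blocks()] result.
#' @param pairs The ortholog pairs the blocks were built from.
#' @return Object of class `synteny_summary` with n_blocks,
#'   n_syntenic_pairs, n_ortholog_pairs and consensus_fraction.
#' @export
synteny_summary <- function(blocks, pairs) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  if (nrow(pairs) == 0L) stop("zero ortholog pairs")
  structure(list(
    n_blocks = nrow(blocks$blocks),
    n_syntenic_pairs = nrow(blocks$anchors),
    n_ortholog_pairs = nrow(pairs),
    consensus_fraction = consensus_fraction_from_counts(nrow(blocks$anchors),
                                                        nrow(pairs))),
    class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat(sprintf(paste0("%d ortholog pair(s); %d in %d synteny block(s); ",
                     "consensus gene-order fraction %.1f%%\n"),
              x$n_ortholog_pairs, x$n_syntenic_pairs, x$n_blocks,
              100 * x$consensus_fraction))
  invisible(x)
}
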