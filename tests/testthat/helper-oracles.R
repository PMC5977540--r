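# Independent brute-force oracles and random-instance generators.  These
# deliberately re-derive each quantity by naive enumeration so the package
# implementation is checked against a different code path.

# N50 by explicit prefix enumeration over the descending-sorted lengths
oracle_n50 <- function(lens) {
  sorted <- sort(lens, decreasing = TRUE)
  total <- sum(sorted)
  acc <- 0
  for (i in seq_along(sorted)) {
    acc <- acc + sorted[i]
    if (acc >= total / 2) return(sorted[i])
  }
}

# best reciprocal hits by naive double loop with explicit tie rules
oracle_brh <- function(ab, ba, cutoff) {
  ab <- ab[ab$evalue < cutoff, , drop = FALSE]
  ba <- ba[ba$evalue < cutoff, , drop = FALSE]
  best <- function(h) {
    out <- character(0)
    for (q in unique(h$qseqid)) {
      rows <- h[h$qseqid == q, , drop = FALSE]
      pick <- 1
      for (r in seq_len(nrow(rows))) {
        better <- rows$bitscore[r] > rows$bitscore[pick] ||
          (rows$bitscore[r] == rows$bitscore[pick] &&
             rows$evalue[r] < rows$evalue[pick]) ||
          (rows$bitscore[r] == rows$bitscore[pick] &&
             rows$evalue[r] == rows$evalue[pick] &&
             rows$sseqid[r] < rows$sseqid[pick])
        if (better) pick <- r
      }
      out[q] <- rows$sseqid[pick]
    }
    out
  }
  best_ab <- best(ab)
  best_ba <- best(ba)
  pairs <- character(0)
  for (a in names(best_ab)) {
    b <- best_ab[[a]]
    if (!is.na(best_ba[b]) && identical(unname(best_ba[b]), a) && a != b)
      pairs <- c(pairs, paste(a, b))
  }
  sort(pairs)
}

# synteny blocks by explicit pairwise linking and depth-first component
# search; returns the canonical set of blocks as sorted gene_a signatures
oracle_blocks <- function(order_a, order_b, pairs, min_anchors, max_gap) {
  ia <- match(pairs$gene_a, order_a$gene_id)
  ib <- match(pairs$gene_b, order_b$gene_id)
  n <- nrow(pairs)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (order_a$scaffold[ia[i]] != order_a$scaffold[ia[j]]) next
    if (order_b$scaffold[ib[i]] != order_b$scaffold[ib[j]]) next
    gap_a <- abs(order_a$ord[ia[i]] - order_a$ord[ia[j]]) - 1
    gap_b <- abs(order_b$ord[ib[i]] - order_b$ord[ib[j]]) - 1
    if (gap_a <= max_gap && gap_b <= max_gap) linked[i, j] <- TRUE
  }
  seen <- rep(FALSE, n)
  sigs <- character(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(linked[v, ] & !seen))
    }
    if (length(comp) >= min_anchors)
      sigs <- c(sigs, paste(sort(pairs$gene_a[comp]), collapse = ","))
  }
  sort(sigs)
}

block_signatures <- function(blocks) {
  if (nrow(blocks$anchors) == 0L) return(character(0))
  sort(unname(vapply(split(blocks$anchors$gene_a, blocks$anchors$block_id),
                     function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

# intersection across sets by explicit occurrence counting
oracle_intersect <- function(keysets) {
  all_keys <- unique(unlist(keysets))
  keep <- character(0)
  for (k in all_keys) {
    n_with <- 0
    for (s in keysets) if (k %in% s) n_with <- n_with + 1
    if (n_with == length(keysets)) keep <- c(keep, k)
  }
  sort(keep)
}

# random 12-column hit tables over small gene universes, with deliberate
# bitscore/evalue ties and e-values straddling the cutoff
rand_hit_table <- function(genes_q, genes_s, n) {
  data.frame(
    qseqid = sample(genes_q, n, replace = TRUE),
    sseqid = sample(genes_s, n, replace = TRUE),
    pident = round(runif(n, 30, 100), 1),
    length = sample(50:300, n, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 50L,
    sstart = 1L, send = 50L,
    evalue = sample(c(1e-50, 1e-10, 1e-3, 0.005, 0.02, 0.5), n,
                    replace = TRUE),
    bitscore = sample(c(50, 100, 150, 200), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# random paired gene orders plus a random 1:1 pairing
rand_synteny_instance <- function(max_genes = 30) {
  n_a <- sample(5:max_genes, 1)
  n_b <- sample(5:max_genes, 1)
  genes_a <- data.frame(
    gene_id = sprintf("a%02d", seq_len(n_a)),
    scaffold = sample(paste0("sA", 1:2), n_a, replace = TRUE),
    start = sample.int(10000, n_a), end = 1L, strand = "+",
    stringsAsFactors = FALSE)
  genes_a$end <- genes_a$start + 10L
  genes_b <- data.frame(
    gene_id = sprintf("b%02d", seq_len(n_b)),
    scaffold = sample(paste0("sB", 1:2), n_b, replace = TRUE),
    start = sample.int(10000, n_b), end = 1L, strand = "+",
    stringsAsFactors = FALSE)
  genes_b$end <- genes_b$start + 10L
  k <- sample(2:min(10, n_a, n_b), 1)
  pairs <- data.frame(gene_a = sample(genes_a$gene_id, k),
                      gene_b = sample(genes_b$gene_id, k),
                      stringsAsFactors = FALSE)
  list(order_a = build_gene_order(genes_a),
       order_b = build_gene_order(genes_b),
       pairs = pairs,
       params = synteny_params(min_anchors = sample(1:4, 1),
                               max_gap = sample(0:6, 1)))
}
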