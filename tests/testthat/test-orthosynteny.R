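# BRH orthology, similarity scoring, gene orders and microsynteny blocks.

make_hits <- function(q, s, evalue = 1e-30, bitscore = 100, pident = 90,
                      length = 50) {
  data.frame(qseqid = q, sseqid = s,
             pident = rep_len(pident, length(q)),
             length = rep_len(length, length(q)),
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 50L,
             sstart = 1L, send = 50L,
             evalue = rep_len(evalue, length(q)),
             bitscore = rep_len(bitscore, length(q)),
             stringsAsFactors = FALSE)
}

test_that("similarity is aligning ratio times fractional identity", {
  expect_equal(similarity_score(100, 100, 100, 100), 1.0)
  expect_equal(similarity_score(50, 80, 120, 100), 0.4)
  expect_equal(similarity_score(110, 90, 150, 100), 0.99)  # ratio can be > 1
  expect_error(similarity_score(50, 80, 0, 100), "> 0")
})

test_that("reciprocal best hits are kept and strict e-value filtering
           applies before best-hit selection", {
  lens <- c(a = 100, b = 100, c = 100)
  pairs <- best_reciprocal_hits(make_hits("a", "b"), make_hits("b", "a"),
                                lens, lens)
  expect_identical(pairs$gene_a, "a")
  expect_identical(pairs$gene_b, "b")
  expect_equal(pairs$similarity, (50 / 100) * 0.9)

  # a's best would be c at e-value 0.5, but it is excluded by the strict
  # filter, so b (the surviving hit) pairs reciprocally with a
  ab <- rbind(make_hits("a", "c", evalue = 0.5, bitscore = 500),
              make_hits("a", "b", bitscore = 100))
  ba <- make_hits("b", "a")
  pairs2 <- best_reciprocal_hits(ab, ba, lens, lens)
  expect_identical(pairs2$gene_b, "b")

  # at the boundary the filter is strict: evalue == cutoff is excluded
  ab3 <- make_hits("a", "b", evalue = 0.01)
  expect_identical(nrow(best_reciprocal_hits(ab3, ba, lens, lens)), 0L)

  # unresolvable sequence length is a hard error naming the gene
  expect_error(best_reciprocal_hits(make_hits("a", "b"), make_hits("b", "a"),
                                    lens, c(x = 100)), "b")
})

test_that("BRH matches a naive double-loop oracle on random hit tables", {
  set.seed(7)
  genes_a <- sprintf("a%d", 1:8)
  genes_b <- sprintf("b%d", 1:8)
  lens <- setNames(rep(100, 16), c(genes_a, genes_b))
  for (i in 1:100) {
    ab <- rand_hit_table(genes_a, genes_b, sample(5:40, 1))
    ba <- rand_hit_table(genes_b, genes_a, sample(5:40, 1))
    got <- best_reciprocal_hits(ab, ba, lens, lens)
    expect_identical(sort(paste(got$gene_a, got$gene_b)),
                     oracle_brh(ab, ba, 0.01))
  }
})

test_that("BRH is symmetric: swapping the tables transposes the pair set", {
  set.seed(8)
  genes_a <- sprintf("a%d", 1:8)
  genes_b <- sprintf("b%d", 1:8)
  lens <- setNames(rep(100, 16), c(genes_a, genes_b))
  for (i in 1:25) {
    ab <- rand_hit_table(genes_a, genes_b, 30)
    ba <- rand_hit_table(genes_b, genes_a, 30)
    fwd <- best_reciprocal_hits(ab, ba, lens, lens)
    rev <- best_reciprocal_hits(ba, ab, lens, lens)
    expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                    paste(rev$gene_b, rev$gene_a))
  }
})

test_that("gene orders index by start with deterministic tie-breaking", {
  loci <- data.frame(gene_id = c("g3", "g1", "g2"), scaffold = "s1",
                     start = c(200L, 100L, 50L), end = c(210L, 110L, 60L),
                     strand = "+", stringsAsFactors = FALSE)
  ord <- build_gene_order(loci)
  expect_identical(ord$gene_id, c("g2", "g1", "g3"))
  expect_identical(ord$ord, c(0L, 1L, 2L))

  ties <- data.frame(gene_id = c("gB", "gA"), scaffold = "s1",
                     start = c(100L, 100L), end = c(110L, 110L),
                     strand = "+", stringsAsFactors = FALSE)
  expect_identical(build_gene_order(ties)$gene_id, c("gA", "gB"))

  two <- data.frame(gene_id = c("x1", "y1"), scaffold = c("s1", "s2"),
                    start = 100L, end = 110L, strand = "+",
                    stringsAsFactors = FALSE)
  expect_identical(build_gene_order(two)$ord, c(0L, 0L))
  expect_error(build_gene_order(rbind(loci, loci[1, ])), "duplicate")
})

# three orthologs at consecutive positions on one scaffold per species,
# with an optional inter-anchor gap inserted in species A
toy_instance <- function(gap_at_2 = 0L) {
  mk <- function(prefix, n) data.frame(
    gene_id = sprintf("%s%02d", prefix, seq_len(n)),
    scaffold = paste0(prefix, "s"), start = seq_len(n) * 100L,
    end = seq_len(n) * 100L + 10L, strand = "+", stringsAsFactors = FALSE)
  genes_a <- mk("a", 10L + gap_at_2)
  genes_b <- mk("b", 10L)
  anchors_a <- c("a01", "a02", sprintf("a%02d", 3L + gap_at_2))
  pairs <- data.frame(gene_a = anchors_a, gene_b = c("b01", "b02", "b03"),
                      stringsAsFactors = FALSE)
  list(order_a = build_gene_order(genes_a),
       order_b = build_gene_order(genes_b), pairs = pairs)
}

test_that("three consecutive anchors form one block; a gap beyond max_gap
           breaks the chain", {
  t0 <- toy_instance()
  bl <- detect_synteny_blocks(t0$order_a, t0$order_b, t0$pairs)
  expect_identical(nrow(bl$blocks), 1L)
  expect_identical(bl$blocks$n_anchors, 3L)
  expect_true(bl$blocks$order_consistent)

  # 6 intervening genes in species A between anchors 2 and 3
  t6 <- toy_instance(gap_at_2 = 6L)
  bl6 <- detect_synteny_blocks(t6$order_a, t6$order_b, t6$pairs)
  expect_identical(nrow(bl6$blocks), 0L)
  # ... but a larger max_gap re-joins it
  bl6b <- detect_synteny_blocks(t6$order_a, t6$order_b, t6$pairs,
                                synteny_params(max_gap = 6))
  expect_identical(nrow(bl6b$blocks), 1L)

  bad <- data.frame(gene_a = "zz", gene_b = "b01", stringsAsFactors = FALSE)
  expect_error(detect_synteny_blocks(t0$order_a, t0$order_b, bad), "zz")
  multi <- rbind(t0$pairs, data.frame(gene_a = "a01", gene_b = "b09"))
  expect_error(detect_synteny_blocks(t0$order_a, t0$order_b, multi), "1:1")
})

test_that("reversed anchor order is a block with order_consistent flagged", {
  t0 <- toy_instance()
  pairs_rev <- data.frame(gene_a = c("a01", "a02", "a03"),
                          gene_b = c("b03", "b02", "b01"),
                          stringsAsFactors = FALSE)
  bl <- detect_synteny_blocks(t0$order_a, t0$order_b, pairs_rev)
  expect_true(bl$blocks$order_consistent)
  pairs_mix <- data.frame(gene_a = c("a01", "a02", "a03"),
                          gene_b = c("b02", "b01", "b03"),
                          stringsAsFactors = FALSE)
  bl2 <- detect_synteny_blocks(t0$order_a, t0$order_b, pairs_mix)
  expect_false(bl2$blocks$order_consistent)
})

test_that("block detection matches the exhaustive component oracle on
           random instances", {
  set.seed(31)
  for (i in 1:200) {
    inst <- rand_synteny_instance()
    got <- detect_synteny_blocks(inst$order_a, inst$order_b, inst$pairs,
                                 inst$params)
    expect_identical(block_signatures(got),
                     oracle_blocks(inst$order_a, inst$order_b, inst$pairs,
                                   inst$params$min_anchors,
                                   inst$params$max_gap))
    # anchor partition: each pair in at most one block
    expect_false(anyDuplicated(got$anchors$gene_a) > 0)
  }
})

test_that("synteny is monotone in max_gap and min_anchors", {
  set.seed(32)
  for (i in 1:30) {
    inst <- rand_synteny_instance()
    n_pairs_at <- function(g) nrow(detect_synteny_blocks(
      inst$order_a, inst$order_b, inst$pairs,
      synteny_params(min_anchors = 2, max_gap = g))$anchors)
    expect_true(all(diff(vapply(0:6, n_pairs_at, numeric(1))) >= 0))
    n_blocks_at <- function(m) nrow(detect_synteny_blocks(
      inst$order_a, inst$order_b, inst$pairs,
      synteny_params(min_anchors = m, max_gap = 5))$blocks)
    expect_true(all(diff(vapply(1:5, n_blocks_at, numeric(1))) <= 0))
  }
})

test_that("planted-truth scenarios are recovered exactly", {
  for (seed in 1:10) {
    sc <- simulate_ortholog_scenario(seed = seed)
    bl <- detect_synteny_blocks(build_gene_order(sc$genes_a),
                                build_gene_order(sc$genes_b),
                                sc$true_pairs, sc$params)
    truth <- sort(vapply(sc$true_blocks,
                         function(b) paste(sort(b$gene_a), collapse = ","),
                         character(1)))
    expect_identical(block_signatures(bl), truth)
  }
})

test_that("the synteny summary reports the consensus gene-order fraction", {
  t0 <- toy_instance()
  bl <- detect_synteny_blocks(t0$order_a, t0$order_b, t0$pairs)
  s <- synteny_summary(bl, t0$pairs)
  expect_identical(s$n_blocks, 1L)
  expect_equal(s$consensus_fraction, 1.0)       # every pair is in a block

  far <- data.frame(gene_a = c("a01", "a09"), gene_b = c("b01", "b09"),
                    stringsAsFactors = FALSE)
  bl0 <- detect_synteny_blocks(t0$order_a, t0$order_b, far)
  expect_equal(synteny_summary(bl0, far)$consensus_fraction, 0.0)

  expect_equal(consensus_fraction_from_counts(1950, 7284), 1950 / 7284)
  expect_identical(sprintf("%.1f%%", 100 * consensus_fraction_from_counts(
    1950, 7284)), "26.8%")
  expect_error(consensus_fraction_from_counts(1, 0), "> 0")
  expect_error(synteny_summary(bl, t0$pairs[0, ]), "zero ortholog pairs")
})
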