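# Synthetic-data generators: determinism contracts, target recovery against
# the generators' own parameters, and planted-truth construction guarantees.

test_that("all generators are pure functions of parameters and seed", {
  expect_identical(simulate_genome(2000, 0.4, 0.6, seed = 9),
                   simulate_genome(2000, 0.4, 0.6, seed = 9))
  expect_identical(simulate_kmer_spectrum(5000, 30, 0.2, seed = 9),
                   simulate_kmer_spectrum(5000, 30, 0.2, seed = 9))
  pk <- data.frame(mean_channel = 82, sd = 3, events = 500)
  expect_identical(simulate_flow_histogram(pk, seed = 9),
                   simulate_flow_histogram(pk, seed = 9))
  expect_identical(simulate_ortholog_scenario(seed = 9),
                   simulate_ortholog_scenario(seed = 9))
  expect_identical(simulate_target_sets(seed = 9),
                   simulate_target_sets(seed = 9))
  # and they do not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_genome(100, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulated genomes hit their GC and CpG-depletion targets", {
  g <- simulate_genome(1e6, gc_fraction = 0.35, cpg_depletion = 1, seed = 2)
  ws <- window_stats(g)
  expect_lt(abs(mean(ws$gc) - 0.35), 0.01 * 0.35 + 0.005)
  expect_lt(abs(mean(ws$cpg_ratio, na.rm = TRUE) - 1), 0.05)

  g2 <- simulate_genome(1e6, gc_fraction = 0.35, cpg_depletion = 0.5,
                        seed = 2)
  ws2 <- window_stats(g2)
  expect_lt(abs(mean(ws2$cpg_ratio, na.rm = TRUE) - 0.5), 0.05)
  expect_lt(abs(mean(ws2$gc) - 0.35), 0.01)
})

test_that("genome simulator validates its parameters", {
  expect_error(simulate_genome(0), "length_bp")
  expect_error(simulate_genome(100, gc_fraction = 1), "gc_fraction")
  expect_error(simulate_genome(100, cpg_depletion = 1.2), "cpg_depletion")
})

test_that("k-mer spectra concentrate at the coverage peak and conserve
           distinct-k-mer counts", {
  for (seed in 1:20) {
    sp <- simulate_kmer_spectrum(1e5, 50, 0, seed = seed)
    mode <- sp$depth[which.max(sp$count)]
    expect_lte(abs(mode - 50), 2)
    expect_equal(sum(sp$count), 1e5)   # zero-truncation conserves k-mers
  }
  expect_error(simulate_kmer_spectrum(0, 50), "genome_size_bp")
  sp <- simulate_kmer_spectrum(1e4, 50, 0.4, seed = 1)
  err_mass <- sum(sp$count[sp$depth <= 2])
  expect_lt(abs(err_mass / sum(sp$count) - 0.4), 0.02)
})

test_that("flow peaks land on their generator targets", {
  h <- simulate_flow_histogram(
    data.frame(mean_channel = 82, sd = 3, events = 1e4), seed = 3)
  pk <- flow_peak_mean(h, c(70, 95))
  expect_lt(abs(pk$mean_channel - 82), 0.5)

  empty <- simulate_flow_histogram(
    data.frame(mean_channel = 82, sd = 3, events = 0), seed = 3)
  expect_identical(length(empty$channel), 0L)

  h2 <- simulate_flow_histogram(
    data.frame(mean_channel = c(82, 160), sd = c(3, 3), events = c(1e4, 1e4)),
    seed = 3)
  r <- flow_peak_mean(h2, c(140, 180))$mean_channel /
    flow_peak_mean(h2, c(70, 95))$mean_channel
  expect_lt(abs(r - 160 / 82) / (160 / 82), 0.01)
})

test_that("ortholog scenarios plant exactly the blocks the rule detects", {
  sc <- simulate_ortholog_scenario(n_blocks = 2, anchors_per_block = 4,
                                   gap_genes = 2, seed = 5)
  bl <- detect_synteny_blocks(build_gene_order(sc$genes_a),
                              build_gene_order(sc$genes_b),
                              sc$true_pairs, sc$params)
  expect_identical(nrow(bl$blocks), 2L)
  expect_true(all(bl$blocks$n_anchors == 4L))

  # blocks below the anchor threshold are planted but not detectable
  sc2 <- simulate_ortholog_scenario(n_blocks = 2, anchors_per_block = 2,
                                    gap_genes = 2, seed = 5)
  bl2 <- detect_synteny_blocks(build_gene_order(sc2$genes_a),
                               build_gene_order(sc2$genes_b),
                               sc2$true_pairs, synteny_params(min_anchors = 3))
  expect_identical(nrow(bl2$blocks), 0L)

  expect_error(simulate_ortholog_scenario(n_genes = 20, n_blocks = 4,
                                          anchors_per_block = 6),
               "infeasible packing")
})

test_that("simulated hit tables make the truth the exact BRH set", {
  sc <- simulate_ortholog_scenario(seed = 6)
  ht <- simulate_hit_tables(sc, seed = 6)
  pairs <- best_reciprocal_hits(ht$ab, ht$ba, sc$len_a, sc$len_b)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(sc$true_pairs$gene_a, sc$true_pairs$gene_b))

  # true-pair e-values failing the strict cutoff leave nothing
  ht2 <- simulate_hit_tables(sc, evalue_true = 0.5, evalue_spurious = 0.9,
                             seed = 6)
  expect_identical(nrow(best_reciprocal_hits(ht2$ab, ht2$ba, sc$len_a,
                                             sc$len_b)), 0L)

  # spurious-only tables yield no reciprocal pairs
  sc0 <- simulate_ortholog_scenario(n_blocks = 0, n_noise_orthologs = 0,
                                    seed = 6)
  ht0 <- simulate_hit_tables(sc0, seed = 6)
  expect_gt(nrow(ht0$ab), 0L)
  expect_identical(nrow(best_reciprocal_hits(ht0$ab, ht0$ba, sc0$len_a,
                                             sc0$len_b)), 0L)

  expect_error(simulate_hit_tables(sc, evalue_true = 1e-3,
                                   evalue_spurious = 1e-5), "must be <")
})

test_that("target sets share exactly the planted consensus core", {
  tt <- simulate_target_sets(n_tools = 5, n_relations = 100,
                             consensus_fraction = 0.2, seed = 7)
  expect_identical(nrow(consensus_targets(tt)), 20L)
  per_tool <- table(tt$tool)
  expect_true(all(per_tool == 100))

  one <- simulate_target_sets(n_tools = 1, n_relations = 50,
                              consensus_fraction = 0.1, seed = 7)
  cons <- consensus_targets(one)
  expect_identical(nrow(cons), 50L)   # one tool: consensus is its whole set
})
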