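# Synthetic-data generators with ground truth for parameter-recovery tests.
# Every generator is a pure function of its parameters and an explicit seed
# (the caller's RNG state is left untouched).

#' Simulate a genome sequence with controlled GC and CpG depletion
#'
#' First-order Markov chain over {A,C,G,T} whose stationary base composition
#' matches `gc_fraction` exactly and whose CpG dinucleotide rate equals
#' `cpg_depletion` times the iid expectation `P(C) * P(G)`.  The transition
#' matrix thins C->G transitions by the depletion factor and redistributes
#' the removed mass so the stationary distribution is preserved, so realized
#' GC and the window-mean CpG observed/expected ratio converge on their
#' targets as length grows.
#'
#' @param length_bp Sequence length (>= 1).
#' @param gc_fraction Target GC content, in (0, 1).
#' @param cpg_depletion Factor in [0, 1] multiplying the iid-expected CpG
#'   rate (1 = no depletion).
#' @param seed Integer seed.
#' @param id Record id of the returned sequence.
#' @return Named character vector of length 1 (a FASTA-ready record).
#' @export
simulate_genome <- function(length_bp, gc_fraction = 0.35, cpg_depletion = 1,
                            seed = 1L, id = "synthetic_1") {
  if (length_bp < 1L) stop("length_bp must be >= 1")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (cpg_depletion < 0 || cpg_depletion > 1)
    stop("cpg_depletion must be in [0, 1]")
  # states 1=A, 2=C, 3=G, 4=T
  pi <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
          (1 - gc_fraction) / 2)
  d <- cpg_depletion
  row_c <- pi * (1 - d * pi[3]) / (1 - pi[3])   # from C: thinned C->G
  row_c[3] <- d * pi[3]
  boost <- 1 + pi[2] * (1 - d) / (1 - pi[2])    # others compensate G mass
  row_o <- pi * (1 - pi[3] * boost) / (1 - pi[3])
  row_o[3] <- pi[3] * boost
  if (any(row_c < 0) || any(row_o < 0) || row_o[3] > 1)
    stop("infeasible gc_fraction/cpg_depletion combination")
  x <- withr::with_seed(seed, {
    n <- as.integer(length_bp)
    u <- stats::runif(n)
    pick <- function(u, p) {
      cum <- cumsum(p)
      1L + (u > cum[1]) + (u > cum[2]) + (u > cum[3])
    }
    cand_c <- pick(u, row_c)
    cand_o <- pick(u, row_o)
    x <- cand_o
    x[1] <- pick(u[1], pi)
    if (n > 1L) {
      # fixed-point iteration: position i is drawn from the row selected by
      # x[i-1]; changes propagate forward and die out within a few passes
      for (pass in seq_len(64L)) {
        prev_c <- c(FALSE, x[-n] == 2L)
        xn <- ifelse(prev_c, cand_c, cand_o)
        xn[1] <- x[1]
        if (identical(xn, x)) break
        x <- xn
      }
      if (!identical(xn, x) || any(xn != ifelse(c(FALSE, x[-n] == 2L),
                                                cand_c, cand_o) &
                                   seq_len(n) > 1L)) {
        for (i in 2:n)           # sequential fallback, exact by construction
          x[i] <- if (x[i - 1L] == 2L) cand_c[i] else cand_o[i]
      }
    }
    x
  })
  seq <- paste(c("A", "C", "G", "T")[x], collapse = "")
  names(seq) <- id
  seq
}

#' Simulate a k-mer depth spectrum
#'
#' `genome_size_bp` distinct genomic k-mers receive depths from a
#' zero-truncated Poisson with mean `mean_depth` (every genomic k-mer is
#' observed at least once, so total distinct-k-mer count is conserved);
#' error k-mers add a low-depth noise component at depths 1-2 making up
#' `error_kmer_fraction` of all distinct k-mers.
#'
#' @param genome_size_bp Number of distinct genomic k-mers (>= 1).
#' @param mean_depth Mean sequencing depth (> 0).
#' @param error_kmer_fraction Fraction in [0, 1) of all distinct k-mers that
#'   are sequencing-error artifacts.
#' @param seed Integer seed.
#' @param k k-mer length recorded on the spectrum (default 17).
#' @return A [kmer_spectrum()].
#' @export
simulate_kmer_spectrum <- function(genome_size_bp, mean_depth,
                                   error_kmer_fraction = 0, seed = 1L,
                                   k = 17L) {
  if (genome_size_bp < 1L) stop("genome_size_bp must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (error_kmer_fraction < 0 || error_kmer_fraction >= 1)
    stop("error_kmer_fraction must be in [0, 1)")
  withr::with_seed(seed, {
    depth <- stats::rpois(genome_size_bp, mean_depth)
    while (any(depth == 0L))    # zero-truncation: genomic k-mers are observed
      depth[depth == 0L] <- stats::rpois(sum(depth == 0L), mean_depth)
    f <- error_kmer_fraction
    n_err <- round(genome_size_bp * f / (1 - f))
    if (n_err > 0)
      depth <- c(depth, 1L + stats::rbinom(n_err, 1L, 0.3))
    tab <- table(depth)
    kmer_spectrum(as.integer(names(tab)), as.numeric(tab), k = k)
  })
}

#' Simulate a flow-cytometry histogram
#'
#' Each peak contributes `events` draws from a Gaussian centred on
#' `mean_channel`, rounded to integer channels (clamped at 1).
#'
#' @param peaks data.frame (or list coercible to one) with columns
#'   mean_channel, sd (> 0) and events (>= 0).
#' @param seed Integer seed.
#' @return A [flow_histogram()] (empty when total events is zero).
#' @export
simulate_flow_histogram <- function(peaks, seed = 1L) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mean_channel", "sd", "events") %in% names(peaks)))
  if (any(peaks$sd <= 0)) stop("peak sd must be > 0")
  if (any(peaks$events < 0)) stop("peak events must be >= 0")
  withr::with_seed(seed, {
    ch <- unlist(lapply(seq_len(nrow(peaks)), function(i)
      pmax(1L, as.integer(round(stats::rnorm(peaks$events[i],
                                             peaks$mean_channel[i],
                                             peaks$sd[i]))))))
    if (length(ch) == 0L) return(flow_histogram())
    tab <- table(ch)
    flow_histogram(as.integer(names(tab)), as.numeric(tab))
  })
}

#' Simulate a paired-species ortholog scenario with planted synteny blocks
#'
#' Builds gene tables for two species, plants `n_blocks` synteny blocks
#' (each `anchors_per_block` 1:1 ortholog anchors separated by `gap_genes`
#' intervening filler genes in both species, satisfying the detection rule
#' `min_anchors`/`max_gap`), and adds `n_noise_orthologs` 1:1 pairs placed so
#' that, in species A, each noise anchor is farther than `max_gap` from every
#' other anchor on its scaffold; noise can therefore neither join a planted
#' block nor form a block of its own, and the planted truth is exactly the
#' detectable block set.  A validator pass re-checks both guarantees.
#'
#' @param n_genes Genes per species (split evenly across scaffolds).
#' @param n_scaffolds Scaffolds per species.
#' @param n_blocks Number of planted blocks.
#' @param anchors_per_block Ortholog anchors per planted block (>= 1).
#' @param gap_genes Intervening filler genes between consecutive anchors
#'   (>= 0; must be <= `max_gap` for the blocks to be detectable).
#' @param n_noise_orthologs Isolated 1:1 ortholog pairs outside any block.
#' @param seed Integer seed.
#' @param min_anchors,max_gap Detection rule the planted blocks must trigger
#'   (defaults 3 and 5).
#' @return Object of class `ortholog_scenario`: gene tables `genes_a` /
#'   `genes_b`, protein lengths `len_a` / `len_b`, `true_pairs` (gene_a,
#'   gene_b, block_id with NA for noise), `true_blocks` (list of per-block
#'   anchor data.frames), `params`, `seed`.
#' @export
simulate_ortholog_scenario <- function(n_genes = 100L, n_scaffolds = 2L,
                                       n_blocks = 2L, anchors_per_block = 4L,
                                       gap_genes = 2L,
                                       n_noise_orthologs = 5L, seed = 1L,
                                       min_anchors = 3L, max_gap = 5L) {
  if (anchors_per_block < 1L) stop("anchors_per_block must be >= 1")
  if (gap_genes < 0L) stop("gap_genes must be >= 0")
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  buffer <- max_gap + 2L                       # breaks any cross-anchor link
  span <- anchors_per_block + (anchors_per_block - 1L) * gap_genes

  # slot layout for one species: returns per-gene scaffold and slot index,
  # plus slot positions of each block's anchors and of the noise anchors.
  layout_species <- function(block_order, reverse_within) {
    per_scaf <- rep(n_genes %/% n_scaffolds, n_scaffolds)
    extra <- n_genes %% n_scaffolds
    if (extra > 0) per_scaf[seq_len(extra)] <- per_scaf[seq_len(extra)] + 1L
    scaf_of_block <- ((seq_len(n_blocks) - 1L) %% n_scaffolds) + 1L
    anchor_slot <- vector("list", n_blocks)
    noise_slot <- integer(0); noise_scaf <- integer(0)
    cursor <- integer(n_scaffolds)             # next free slot per scaffold
    for (b in block_order) {
      s <- scaf_of_block[b]
      first <- cursor[s] + buffer + 1L
      slots <- first + (seq_len(anchors_per_block) - 1L) * (gap_genes + 1L)
      if (reverse_within[b]) slots <- rev(slots)
      anchor_slot[[b]] <- cbind(scaf = s, slot = slots)
      cursor[s] <- max(slots) + 0L
      if (cursor[s] > per_scaf[s])
        stop("infeasible packing: scaffold ", s, " needs ", cursor[s],
             " slots for blocks but has ", per_scaf[s], " genes")
    }
    for (k in seq_len(n_noise_orthologs)) {
      s <- ((k - 1L) %% n_scaffolds) + 1L
      slot <- cursor[s] + buffer + 1L
      if (slot > per_scaf[s])
        stop("infeasible packing: scaffold ", s, " cannot isolate noise ",
             "ortholog ", k, " (needs slot ", slot, " of ", per_scaf[s], ")")
      noise_slot <- c(noise_slot, slot); noise_scaf <- c(noise_scaf, s)
      cursor[s] <- slot
    }
    list(per_scaf = per_scaf, anchor_slot = anchor_slot,
         noise = cbind(scaf = noise_scaf, slot = noise_slot))
  }

  build_genes <- function(prefix, lay) {
    do.call(rbind, lapply(seq_len(n_scaffolds), function(s) {
      n <- lay$per_scaf[s]
      if (n == 0L) return(NULL)
      data.frame(
        gene_id = sprintf("%s_s%d_g%03d", prefix, s, seq_len(n)),
        scaffold = sprintf("%s_scaf%d", prefix, s),
        start = (seq_len(n) - 1L) * 1000L + 1L,
        end = (seq_len(n) - 1L) * 1000L + 600L,
        strand = "+", stringsAsFactors = FALSE)
    }))
  }
  gene_at <- function(prefix, scaf, slot) sprintf("%s_s%d_g%03d", prefix,
                                                  scaf, slot)

  withr::with_seed(seed, {
    reverse_within <- stats::runif(n_blocks) < 0.5
    lay_a <- layout_species(seq_len(n_blocks), rep(FALSE, n_blocks))
    lay_b <- layout_species(rev(seq_len(n_blocks)), reverse_within)
    genes_a <- build_genes("A", lay_a)
    genes_b <- build_genes("B", lay_b)
    genes_a$strand <- sample(c("+", "-"), nrow(genes_a), replace = TRUE)
    genes_b$strand <- sample(c("+", "-"), nrow(genes_b), replace = TRUE)
    true_blocks <- lapply(seq_len(n_blocks), function(b) {
      sa <- lay_a$anchor_slot[[b]]; sb <- lay_b$anchor_slot[[b]]
      data.frame(gene_a = gene_at("A", sa[, "scaf"], sa[, "slot"]),
                 gene_b = gene_at("B", sb[, "scaf"], sb[, "slot"]),
                 block_id = b, stringsAsFactors = FALSE)
    })
    noise_pairs <- if (n_noise_orthologs > 0L) {
      na <- lay_a$noise; nb <- lay_b$noise
      data.frame(gene_a = gene_at("A", na[, "scaf"], na[, "slot"]),
                 gene_b = gene_at("B", nb[, "scaf"], nb[, "slot"]),
                 block_id = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_a = character(), gene_b = character(),
                 block_id = integer(), stringsAsFactors = FALSE)
    }
    true_pairs <- rbind(do.call(rbind, true_blocks), noise_pairs)
    len_a <- stats::setNames(sample(100:600, nrow(genes_a), replace = TRUE),
                             genes_a$gene_id)
    len_b <- stats::setNames(sample(100:600, nrow(genes_b), replace = TRUE),
                             genes_b$gene_id)
    len_b[true_pairs$gene_b] <- pmax(100L, len_a[true_pairs$gene_a] +
                                       sample(-20:20, nrow(true_pairs),
                                              replace = TRUE))
    scen <- structure(list(genes_a = genes_a, genes_b = genes_b,
                           len_a = len_a, len_b = len_b,
                           true_pairs = true_pairs,
                           true_blocks = true_blocks,
                           params = synteny_params(min_anchors, max_gap),
                           seed = seed),
                      class = "ortholog_scenario")
    .validate_scenario(scen, gap_genes)
    scen
  })
}

# truth-consistency validator: planted blocks satisfy the detection rule and
# noise anchors are isolated in species A
.validate_scenario <- function(scen, gap_genes) {
  ord_a <- build_gene_order(scen$genes_a)
  ord_b <- build_gene_order(scen$genes_b)
  p <- scen$params
  for (blk in scen$true_blocks) {
    ia <- sort(ord_a$ord[match(blk$gene_a, ord_a$gene_id)])
    ib <- sort(ord_b$ord[match(blk$gene_b, ord_b$gene_id)])
    if (length(unique(ord_a$scaffold[match(blk$gene_a,
                                           ord_a$gene_id)])) != 1L ||
        length(unique(ord_b$scaffold[match(blk$gene_b,
                                           ord_b$gene_id)])) != 1L)
      stop("internal error: planted block spans multiple scaffolds")
    if (nrow(blk) > 1L &&
        (any(diff(ia) - 1L > p$max_gap) || any(diff(ib) - 1L > p$max_gap)))
      stop("internal error: planted block violates max_gap")
  }
  all_a <- ord_a[match(scen$true_pairs$gene_a, ord_a$gene_id), ]
  noise <- which(is.na(scen$true_pairs$block_id))
  for (k in noise) {
    same <- setdiff(which(all_a$scaffold == all_a$scaffold[k]), k)
    if (length(same) > 0L &&
        min(abs(all_a$ord[same] - all_a$ord[k])) - 1L <= p$max_gap)
      stop("internal error: noise ortholog not isolated in species A")
  }
  invisible(TRUE)
}

#' @export
print.ortholog_scenario <- function(x, ...) {
  cat(sprintf(paste0("ortholog scenario (seed %d): %d + %d genes, ",
                     "%d planted block(s), %d true pair(s) ",
                     "(%d noise)\n"),
              x$seed, nrow(x$genes_a), nrow(x$genes_b),
              length(x$true_blocks), nrow(x$true_pairs),
              sum(is.na(x$true_pairs$block_id))))
  invisible(x)
}

#' Simulate reciprocal hit tables for an ortholog scenario
#'
#' Every true ortholog pair appears in both search directions as the unique
#' best reciprocal hit (e-value `evalue_true`, high bit score); spurious hits
#' to wrong partners get `evalue_spurious` and strictly lower bit scores, and
#' any reciprocal spurious pair is dropped so the BRH output equals the
#' truth exactly at the default e-value cutoff.
#'
#' @param scenario An [simulate_ortholog_scenario()] result.
#' @param evalue_true E-value of true-pair hits (default 1e-80).
#' @param evalue_spurious E-value of spurious hits (default 1e-3); must be
#'   larger than `evalue_true`.
#' @param seed Integer seed.
#' @param spurious_per_gene Expected spurious hits per species-A gene
#'   (default 0.5).
#' @return List with hit tables `ab` and `ba` ([read_hit_table()] layout).
#' @export
simulate_hit_tables <- function(scenario, evalue_true = 1e-80,
                                evalue_spurious = 1e-3, seed = 1L,
                                spurious_per_gene = 0.5) {
  stopifnot(inherits(scenario, "ortholog_scenario"))
  if (evalue_true >= evalue_spurious)
    stop("evalue_true must be < evalue_spurious")
  tp <- scenario$true_pairs
  withr::with_seed(seed, {
    hit_row <- function(q, s, qlen, slen, evalue, bitscore) {
      alen <- pmax(30L, as.integer(round(0.9 * pmin(qlen, slen))))
      pid <- round(stats::runif(length(q), 70, 99), 1)
      data.frame(qseqid = q, sseqid = s, pident = pid, length = alen,
                 mismatch = as.integer(round(alen * (1 - pid / 100))),
                 gapopen = rep_len(0L, length(q)),
                 qstart = rep_len(1L, length(q)), qend = alen,
                 sstart = rep_len(1L, length(q)), send = alen,
                 evalue = rep_len(evalue, length(q)),
                 bitscore = rep_len(bitscore, length(q)),
                 stringsAsFactors = FALSE)
    }
    n <- nrow(tp)
    ab <- ba <- NULL
    if (n > 0L) {
      bs <- round(stats::runif(n, 400, 600), 1)
      ab <- hit_row(tp$gene_a, tp$gene_b, scenario$len_a[tp$gene_a],
                    scenario$len_b[tp$gene_b], evalue_true, bs)
      ba <- hit_row(tp$gene_b, tp$gene_a, scenario$len_b[tp$gene_b],
                    scenario$len_a[tp$gene_a], evalue_true,
                    round(bs + stats::runif(n, -5, 5), 1))
    }
    n_spur <- stats::rpois(1, spurious_per_gene * nrow(scenario$genes_a))
    if (n_spur > 0L) {
      qa <- sample(scenario$genes_a$gene_id, n_spur, replace = TRUE)
      sb <- sample(scenario$genes_b$gene_id, n_spur, replace = TRUE)
      truth_key <- paste(tp$gene_a, tp$gene_b)
      keep <- !paste(qa, sb) %in% truth_key
      spur_ab <- hit_row(qa[keep], sb[keep], scenario$len_a[qa[keep]],
                         scenario$len_b[sb[keep]], evalue_spurious,
                         round(stats::runif(sum(keep), 30, 80), 1))
      qb <- sample(scenario$genes_b$gene_id, n_spur, replace = TRUE)
      sa <- sample(scenario$genes_a$gene_id, n_spur, replace = TRUE)
      keep2 <- !paste(sa, qb) %in% truth_key &
        !paste(sa, qb) %in% paste(qa[keep], sb[keep])  # no reciprocal spurious
      spur_ba <- hit_row(qb[keep2], sa[keep2], scenario$len_b[qb[keep2]],
                         scenario$len_a[sa[keep2]], evalue_spurious,
                         round(stats::runif(sum(keep2), 30, 80), 1))
      ab <- rbind(ab, spur_ab)
      ba <- rbind(ba, spur_ba)
    }
    empty <- read_hit_table_empty()
    list(ab = if (is.null(ab)) empty else ab,
         ba = if (is.null(ba)) empty else ba)
  })
}

read_hit_table_empty <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = 12))
  names(out) <- HIT_COLS
  out
}

#' Simulate per-tool miRNA-target prediction sets
#'
#' Exactly `round(consensus_fraction * n_relations)` relations are shared by
#' every tool; the remainder of each tool's table is tool-specific (never
#' shared by any two tools), so the all-tools intersection equals the shared
#' core by construction.
#'
#' @param n_tools Number of predictors (default 5).
#' @param n_relations Relations per tool.
#' @param consensus_fraction Fraction in [0, 1] of each tool's relations
#'   that all tools share.
#' @param seed Integer seed.
#' @return data.frame (tool, mirna_id, gene_id) in long format; the shared
#'   core is attached as attribute `"consensus"`.
#' @export
simulate_target_sets <- function(n_tools = 5L, n_relations = 100L,
                                 consensus_fraction = 0.2, seed = 1L) {
  if (n_tools < 1L) stop("n_tools must be >= 1")
  if (consensus_fraction < 0 || consensus_fraction > 1)
    stop("consensus_fraction must be in [0, 1]")
  n_core <- round(consensus_fraction * n_relations)
  n_specific <- n_relations - n_core
  withr::with_seed(seed, {
    draw_pairs <- function(n, taken) {
      out <- character(0)
      while (length(out) < n) {
        cand <- paste(sprintf("mir-%03d", sample.int(500L, n, TRUE)),
                      sprintf("gene%04d", sample.int(5000L, n, TRUE)),
                      sep = "\t")
        cand <- setdiff(unique(cand), c(taken, out))
        out <- c(out, cand)[seq_len(min(n, length(out) + length(cand)))]
      }
      out
    }
    core <- draw_pairs(n_core, character(0))
    taken <- core
    tabs <- lapply(seq_len(n_tools), function(t) {
      spec <- draw_pairs(n_specific, taken)
      taken <<- c(taken, spec)
      keys <- c(core, spec)
      parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
      if (length(keys) == 0L)
        return(data.frame(tool = character(), mirna_id = character(),
                          gene_id = character(), stringsAsFactors = FALSE))
      data.frame(tool = sprintf("tool%d", t), mirna_id = parts[, 1],
                 gene_id = parts[, 2], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    core_parts <- if (n_core > 0)
      do.call(rbind, strsplit(sort(core), "\t", fixed = TRUE))
    attr(out, "consensus") <- if (n_core > 0)
      data.frame(mirna_id = core_parts[, 1], gene_id = core_parts[, 2],
                 stringsAsFactors = FALSE)
    else data.frame(mirna_id = character(), gene_id = character(),
                    stringsAsFactors = FALSE)
    out
  })
}
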