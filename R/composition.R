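# Windowed GC / CpG composition and assembly contiguity statistics.
#
# CpG observed/expected ratio per window: P[CpG] / (P[C] * P[G]), where P[C]
# and P[G] are mononucleotide frequencies over the window's valid (ACGT)
# positions and P[CpG] is the overlapping CpG dinucleotide frequency over
# valid adjacent pairs (both positions ACGT and consecutive).  Values below 1
# indicate CpG depletion, the signature of germ-line cytosine methylation.

#' Windowed GC content and CpG observed/expected ratio
#'
#' Cuts each scaffold into consecutive non-overlapping windows of
#' `window_bp`; trailing partial windows are dropped.  Frequencies are
#' computed over valid (ACGT) positions only; dinucleotide frequencies over
#' valid adjacent pairs within the window (no cross-window pairs).
#'
#' @param sequences Named character vector of nucleotide sequences (as from
#'   [read_fasta()]); non-ACGTN symbols are mapped to N with a warning.
#' @param window_bp Window size in bp (>= 2, default 500).
#' @return data.frame with one row per window: scaffold, window_index
#'   (0-based), start_bp (1-based), gc, p_c, p_g, p_cpg, cpg_ratio,
#'   valid_bases.  `cpg_ratio` is `NA` when `p_c * p_g` is zero.
#' @export
window_stats <- function(sequences, window_bp = 500L) {
  window_bp <- as.integer(window_bp)
  if (is.na(window_bp) || window_bp < 2L) stop("window_bp must be >= 2")
  sequences <- clean_dna(sequences)
  out <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    len <- nchar(sequences[[i]])
    nwin <- len %/% window_bp
    if (nwin == 0L) next
    starts <- (seq_len(nwin) - 1L) * window_bp + 1L
    win <- Biostrings::DNAStringSet(substring(sequences[[i]], starts,
                                              starts + window_bp - 1L))
    mono <- Biostrings::letterFrequency(win, c("A", "C", "G", "T"))
    dinu <- Biostrings::dinucleotideFrequency(win, step = 1)
    valid <- rowSums(mono)
    pairs_valid <- rowSums(dinu)   # pairs containing N are never counted
    p_c <- ifelse(valid > 0, mono[, "C"] / valid, NA_real_)
    p_g <- ifelse(valid > 0, mono[, "G"] / valid, NA_real_)
    gc <- ifelse(valid > 0, (mono[, "C"] + mono[, "G"]) / valid, NA_real_)
    p_cpg <- ifelse(pairs_valid > 0, dinu[, "CG"] / pairs_valid, NA_real_)
    denom <- p_c * p_g
    cpg_ratio <- ifelse(!is.na(denom) & denom > 0 & !is.na(p_cpg),
                        p_cpg / denom, NA_real_)
    out[[i]] <- data.frame(
      scaffold = names(sequences)[i], window_index = seq_len(nwin) - 1L,
      start_bp = starts, gc = gc, p_c = p_c, p_g = p_g, p_cpg = p_cpg,
      cpg_ratio = cpg_ratio, valid_bases = as.integer(valid),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(scaffold = character(), window_index = integer(),
                      start_bp = integer(), gc = numeric(), p_c = numeric(),
                      p_g = numeric(), p_cpg = numeric(),
                      cpg_ratio = numeric(), valid_bases = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assembly summary statistics
#'
#' N50 is the length of the shortest sequence in the smallest prefix of the
#' descending-length-sorted sequence list whose cumulative length reaches
#' half the total assembly length.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return Object of class `assembly_stats` with fields n_seqs, total_bp,
#'   gap_bp (N count), gc_overall (over ACGT positions), n50_bp, longest_bp.
#' @export
assembly_stats <- function(sequences) {
  if (length(sequences) == 0L) stop("no sequences")
  sequences <- clean_dna(sequences)
  dna <- Biostrings::DNAStringSet(sequences)
  mono <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T", "N"))
  lens <- Biostrings::width(dna)
  total <- sum(as.numeric(lens))
  acgt <- sum(mono[, c("A", "C", "G", "T")])
  sorted <- sort(lens, decreasing = TRUE)
  idx <- which(cumsum(as.numeric(sorted)) >= total / 2)[1]
  structure(list(
    n_seqs = length(sequences), total_bp = total,
    gap_bp = sum(mono[, "N"]),
    gc_overall = if (acgt > 0) sum(mono[, c("C", "G")]) / acgt else NA_real_,
    n50_bp = sorted[idx], longest_bp = sorted[1]),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("Assembly: %d sequences, %.0f bp (%.0f bp gaps)\n",
                     "  N50 %.0f bp, longest %.0f bp, GC %.2f%%\n"),
              x$n_seqs, x$total_bp, x$gap_bp, x$n50_bp, x$longest_bp,
              100 * x$gc_overall))
  invisible(x)
}

#' Percentage of a whole
#'
#' Convenience for reporting assembly fractions (repeat content, BUSCO
#' completeness and the like) on the percent scale.
#'
#' @param part Numerator (>= 0).
#' @param whole Denominator (> 0), same units as `part`.
#' @return 100 * part / whole.
#' @export
fraction_pct <- function(part, whole) {
  if (whole <= 0) stop("whole must be > 0")
  if (part < 0) stop("part must be >= 0")
  100 * part / whole
}
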