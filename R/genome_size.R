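# Genome-size estimation from k-mer depth spectra and from flow-cytometry
# channel ratios, plus fold-coverage.
#
# The spectrum estimator assumes single-copy k-mer depths concentrate around
# the mean sequencing depth (approximately Poisson), with error k-mers piling
# up at depth 1-2.  Genome size is the total k-mer mass above the error
# cutoff divided by the depth of the signal peak (the histogram mode); the
# peak is not fitted, so the estimate is fully deterministic in its input.
#
# The flow-cytometry estimator is the classic internal-standard ratio: DNA
# amount of the sample equals the mean channel of its gated peak divided by
# the mean channel of the standard's peak, times the standard's DNA amount.
# Ploidy (1C/2C) is carried as an explicit tag and never converted silently:
# a 2C-vs-1C comparison is the caller's explicit decision.

#' k-mer depth spectrum
#'
#' Histogram of how many distinct k-mers occur at each sequencing depth.
#'
#' @param depth Integer vector of depths (>= 1), strictly increasing.
#' @param count Numeric vector of distinct-k-mer counts (>= 0).
#' @param k k-mer length (default 17).
#' @return Object of class `kmer_spectrum`.
#' @export
kmer_spectrum <- function(depth, count, k = 17L) {
  depth <- as.integer(depth)
  count <- as.numeric(count)
  stopifnot(length(depth) == length(count))
  if (length(depth) > 0L) {
    if (any(depth < 1L)) stop("depths must be >= 1")
    if (is.unsorted(depth, strictly = TRUE)) {
      o <- order(depth)
      depth <- depth[o]; count <- count[o]
      if (anyDuplicated(depth)) stop("duplicate depths in spectrum")
    }
    if (any(count < 0)) stop("negative counts in spectrum")
  }
  if (k < 1L) stop("k must be >= 1")
  structure(list(k = as.integer(k), depth = depth, count = count),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum (k = %d): %d depth bins, %.3g distinct k-mers\n",
              x$k, length(x$depth), sum(x$count)))
  invisible(x)
}

#' Flow-cytometry channel histogram
#'
#' @param channel Integer vector of fluorescence channels (>= 1).
#' @param events Numeric vector of event counts (>= 0).
#' @return Object of class `flow_histogram`.
#' @export
flow_histogram <- function(channel = integer(), events = numeric()) {
  channel <- as.integer(channel)
  events <- as.numeric(events)
  stopifnot(length(channel) == length(events))
  if (length(channel) > 0L) {
    if (any(channel < 1L)) stop("channels must be >= 1")
    if (any(events < 0)) stop("negative event counts")
    o <- order(channel)
    channel <- channel[o]; events <- events[o]
    if (anyDuplicated(channel)) stop("duplicate channels in histogram")
  }
  structure(list(channel = channel, events = events),
            class = "flow_histogram")
}

#' @export
print.flow_histogram <- function(x, ...) {
  cat(sprintf("flow histogram: %d channels, %.0f events\n",
              length(x$channel), sum(x$events)))
  invisible(x)
}

# Resolve the error-peak cutoff.  Explicit d_min wins; otherwise the first
# local minimum of the count curve (scanning ascending depth, the depth where
# counts first start rising again) separates the error component from the
# signal peak.  A spectrum with no rise and no mass above depth 2 has no
# signal peak at all.
.resolve_dmin <- function(spectrum, d_min = NULL) {
  depth <- spectrum$depth
  count <- spectrum$count
  if (length(depth) == 0L || sum(count) == 0) stop("empty k-mer spectrum")
  if (!is.null(d_min)) {
    if (d_min < 1L) stop("d_min must be >= 1")
    return(as.integer(d_min))
  }
  if (length(depth) >= 2L) {
    rise <- which(diff(count) > 0)
    if (length(rise) > 0L) return(depth[rise[1] + 1L])
  }
  # no local minimum: either a pure signal spectrum (starts above the
  # error-depth range) or a pure error curve (all mass piled at low depth)
  if (min(depth) > 2L) return(min(depth))
  stop("no signal peak in spectrum (counts decrease monotonically from the ",
       "error-depth range); supply d_min explicitly")
}

#' Depth of the k-mer signal peak
#'
#' Mode of the depth histogram at depths >= `d_min`.  When `d_min` is `NULL`
#' it defaults to the first local minimum of the count curve, the conventional
#' cutoff separating the error-k-mer component from the coverage peak.
#'
#' @param spectrum A [kmer_spectrum()].
#' @param d_min Minimum depth to consider, or `NULL` for the automatic cutoff.
#' @return Integer depth of the signal peak (ties go to the smaller depth).
#' @export
kmer_peak_depth <- function(spectrum, d_min = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  dm <- .resolve_dmin(spectrum, d_min)
  sel <- spectrum$depth >= dm
  if (!any(sel) || sum(spectrum$count[sel]) == 0)
    stop("no spectrum mass at depths >= ", dm)
  d <- spectrum$depth[sel]
  cnt <- spectrum$count[sel]
  d[which.max(cnt)]
}

#' Genome size from a k-mer spectrum
#'
#' size_bp = sum over depths d >= d_min of d * count(d), divided by the depth
#' of the signal peak.  The numerator is the total sequenced k-mer mass
#' attributable to the genome; dividing by the per-copy depth converts it to a
#' count of genomic k-mer positions, the spectrum proxy for genome size.
#'
#' @inheritParams kmer_peak_depth
#' @return A `size_estimate` (method `"kmer"`) whose diagnostics record the
#'   peak depth and the cutoff used.
#' @export
kmer_genome_size <- function(spectrum, d_min = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  dm <- .resolve_dmin(spectrum, d_min)
  peak <- kmer_peak_depth(spectrum, dm)
  sel <- spectrum$depth >= dm
  mass <- sum(as.numeric(spectrum$depth[sel]) * spectrum$count[sel])
  size_estimate(mass / peak, method = "kmer",
                diagnostics = list(k = spectrum$k, peak_depth = peak,
                                   d_min = dm))
}

#' Gated mean channel of a flow-cytometry peak
#'
#' Event-weighted mean channel within a gate, tagged with the ploidy of the
#' nuclei population the gate captures.
#'
#' @param histogram A [flow_histogram()].
#' @param gate Numeric length-2 vector `c(lo, hi)`, channels inclusive.
#' @param ploidy `"2C"` (default) or `"1C"`.
#' @return Object of class `flow_peak` with fields gate, mean_channel,
#'   ploidy and n_events.
#' @export
flow_peak_mean <- function(histogram, gate, ploidy = c("2C", "1C")) {
  stopifnot(inherits(histogram, "flow_histogram"), length(gate) == 2L)
  ploidy <- match.arg(ploidy)
  if (gate[1] > gate[2]) stop("gate lo > hi")
  sel <- histogram$channel >= gate[1] & histogram$channel <= gate[2]
  if (!any(sel) || sum(histogram$events[sel]) == 0)
    stop("no events within gate [", gate[1], ", ", gate[2], "]")
  mean_channel <- stats::weighted.mean(histogram$channel[sel],
                                       histogram$events[sel])
  structure(list(gate = as.numeric(gate), mean_channel = mean_channel,
                 ploidy = ploidy, n_events = sum(histogram$events[sel])),
            class = "flow_peak")
}

#' @export
print.flow_peak <- function(x, ...) {
  cat(sprintf("%s peak: mean channel %.2f (gate [%g, %g], %.0f events)\n",
              x$ploidy, x$mean_channel, x$gate[1], x$gate[2], x$n_events))
  invisible(x)
}

.peak_channel <- function(x) {
  if (inherits(x, "flow_peak")) x$mean_channel
  else if (is.numeric(x) && length(x) == 1L) as.numeric(x)
  else stop("expected a flow_peak or a single mean-channel number")
}

#' Genome size from flow-cytometry peak channels
#'
#' DNA amount of the sample = reference amount x (sample mean channel /
#' reference mean channel).  The result is at the sample peak's ploidy; no
#' implicit 1C/2C conversion is performed (convert explicitly by a factor of
#' 2 when needed).
#'
#' @param sample_peak [flow_peak_mean()] result (or bare mean channel) of the
#'   sample.
#' @param reference_peak Peak (or bare mean channel) of the internal standard.
#' @param reference_amount_bp DNA amount in bp of the standard at the
#'   reference peak's ploidy.
#' @return A `size_estimate` (method `"flow"`).
#' @export
flow_genome_size <- function(sample_peak, reference_peak,
                             reference_amount_bp) {
  sc <- .peak_channel(sample_peak)
  rc <- .peak_channel(reference_peak)
  if (rc <= 0) stop("reference mean channel must be > 0")
  if (reference_amount_bp <= 0) stop("reference_amount_bp must be > 0")
  size_estimate(reference_amount_bp * sc / rc, method = "flow",
                diagnostics = list(
                  sample_channel = sc, reference_channel = rc,
                  sample_ploidy = if (inherits(sample_peak, "flow_peak"))
                    sample_peak$ploidy else NA_character_,
                  reference_ploidy = if (inherits(reference_peak, "flow_peak"))
                    reference_peak$ploidy else NA_character_,
                  reference_amount_bp = reference_amount_bp))
}

#' Sequencing fold-coverage
#'
#' @param total_bases Total sequenced bases.
#' @param genome_size_bp Genome size in bp (> 0).
#' @return total_bases / genome_size_bp (full precision; display rounding is
#'   left to the caller).
#' @export
fold_coverage <- function(total_bases, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0")
  if (total_bases < 0) stop("total_bases must be >= 0")
  total_bases / genome_size_bp
}

#' Genome-size estimate container
#'
#' @param size_bp Estimated size in bp (> 0).
#' @param method `"kmer"` or `"flow"`.
#' @param diagnostics List of method-specific diagnostics (peak depth or peak
#'   channels used).
#' @return Object of class `size_estimate`.
#' @export
size_estimate <- function(size_bp, method = c("kmer", "flow"),
                          diagnostics = list()) {
  method <- match.arg(method)
  if (!is.numeric(size_bp) || length(size_bp) != 1L || size_bp <= 0)
    stop("size_bp must be a single positive number")
  structure(list(size_bp = as.numeric(size_bp), method = method,
                 diagnostics = diagnostics),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("Genome size estimate (%s): %.0f bp (%.0f Mb)\n",
              x$method, x$size_bp, round(x$size_bp / 1e6)))
  if (x$method == "kmer")
    cat(sprintf("  k = %d, signal peak depth %d, error cutoff d_min = %d\n",
                x$diagnostics$k, x$diagnostics$peak_depth,
                x$diagnostics$d_min))
  else
    cat(sprintf("  sample channel %.2f / reference channel %.2f x %.0f bp\n",
                x$diagnostics$sample_channel, x$diagnostics$reference_channel,
                x$diagnostics$reference_amount_bp))
  invisible(x)
}
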