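# Readers and writers for every external representation the pipeline touches.
# Coordinates are 1-based inclusive everywhere (GFF3 convention); the TSV gene
# dialect states this in its header line so files are self-describing.

GENE_TSV_HEADER <- "#gene_id\tscaffold\tstart\tend\tstrand (coordinates 1-based inclusive)"
TARGET_TSV_HEADER <- "#tool\tmirna_id\tgene_id"
HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a FASTA file
#'
#' Loads sequence records (nucleotide or protein) from a FASTA file.  The
#' record id is the first whitespace-delimited token of the header; residues
#' are mapped to upper case.  Duplicate ids and empty files are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record ids, values are upper-case
#'   residue strings, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("zero-length FASTA record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Replace non-ACGTN nucleotides by N
#'
#' Composition stages assume a closed {A,C,G,T,N} alphabet; IUPAC ambiguity
#' codes and other symbols are mapped to N with a warning giving the count.
#'
#' @param seqs Named character vector of upper-case nucleotide strings.
#' @return The same vector with every character outside ACGTN replaced by N.
#' @export
clean_dna <- function(seqs) {
  n_bad <- sum(vapply(seqs,
                      function(s) nchar(gsub("[ACGTN]", "", s)), integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN nucleotide(s) mapped to N")
    seqs[] <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  seqs
}

# split non-comment lines into fields, tracking original line numbers
.read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = lineno[keep])
}

#' Read a gene-coordinate table
#'
#' Two dialects are supported.  `"gff3"` is a GFF3 subset: only rows with
#' feature type `gene` are kept (other feature rows are ignored, with a
#' warning if nothing remains) and each kept row must carry an `ID` attribute.
#' `"tsv"` is a 5-column table (gene_id, scaffold, start, end, strand) whose
#' header line documents the 1-based inclusive coordinate convention.
#'
#' @param path Path to the table.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return data.frame with columns gene_id, scaffold, start, end, strand.
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  tab <- .read_table_lines(path)
  if (dialect == "gff3") {
    rows <- vector("list", length(tab$fields))
    kept <- 0L
    for (i in seq_along(tab$fields)) {
      f <- tab$fields[[i]]
      ln <- tab$lineno[i]
      if (length(f) != 9L)
        stop("line ", ln, ": expected 9 GFF3 columns, got ", length(f))
      if (f[3] != "gene") next
      id <- regmatches(f[9], regexpr("(?:^|;)\\s*ID=[^;]+", f[9]))
      if (length(id) == 0L) stop("line ", ln, ": gene row without ID attribute")
      id <- sub("^.*ID=", "", id)
      kept <- kept + 1L
      rows[[kept]] <- .validate_locus(id, f[1], f[4], f[5], f[7], ln)
    }
    if (kept == 0L) {
      warning("no gene-type rows in ", path)
      return(data.frame(gene_id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    genes <- do.call(rbind, rows[seq_len(kept)])
  } else {
    if (length(tab$fields) == 0L)
      return(data.frame(gene_id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    rows <- vector("list", length(tab$fields))
    for (i in seq_along(tab$fields)) {
      f <- tab$fields[[i]]
      ln <- tab$lineno[i]
      if (length(f) != 5L)
        stop("line ", ln, ": expected 5 columns (gene_id, scaffold, start, ",
             "end, strand), got ", length(f))
      rows[[i]] <- .validate_locus(f[1], f[2], f[3], f[4], f[5], ln)
    }
    genes <- do.call(rbind, rows)
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L)
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  rownames(genes) <- NULL
  genes
}

.validate_locus <- function(id, scaffold, start, end, strand, ln) {
  start <- suppressWarnings(as.integer(start))
  end <- suppressWarnings(as.integer(end))
  if (is.na(start) || is.na(end))
    stop("line ", ln, ": non-integer coordinate")
  if (start > end)
    stop("line ", ln, ": start (", start, ") > end (", end, ")")
  if (start < 1L) stop("line ", ln, ": coordinates must be >= 1")
  if (!strand %in% c("+", "-"))
    stop("line ", ln, ": strand must be '+' or '-', got '", strand, "'")
  if (!nzchar(id)) stop("line ", ln, ": empty gene_id")
  data.frame(gene_id = id, scaffold = scaffold, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write a gene-coordinate table
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"gff3"`.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(genes, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines(c(GENE_TSV_HEADER,
                 paste(genes$gene_id, genes$scaffold, genes$start, genes$end,
                       genes$strand, sep = "\t")), con, sep = "\n")
  } else {
    writeLines(c("##gff-version 3",
                 paste(genes$scaffold, "waspcomp", "gene", genes$start,
                       genes$end, ".", genes$strand, ".",
                       paste0("ID=", genes$gene_id), sep = "\t")),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a 12-column tabular protein hit table
#'
#' Standard tabular alignment-hit format (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score).  Query/subject sequence lengths are not part of this
#' format; they are attached later from the sequence files.
#'
#' @param path Path to the table.
#' @return data.frame with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  tab <- .read_table_lines(path)
  n <- length(tab$fields)
  if (n == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- HIT_COLS
    return(out)
  }
  bad <- which(lengths(tab$fields) != 12L)
  if (length(bad) > 0L)
    stop("line ", tab$lineno[bad[1]], ": expected 12 columns, got ",
         length(tab$fields[[bad[1]]]))
  m <- matrix(unlist(tab$fields), nrow = n, byrow = TRUE)
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(hits$pident) || anyNA(hits$evalue) || anyNA(hits$bitscore))
    stop("non-numeric pident/evalue/bitscore in ", path)
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("pident outside [0,100] in ", path)
  if (any(hits$evalue < 0)) stop("negative evalue in ", path)
  if (any(hits$bitscore <= 0)) stop("non-positive bitscore in ", path)
  hits
}

#' Write a 12-column tabular hit table
#'
#' @param hits data.frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cols <- lapply(hits[HIT_COLS], function(x) vapply(x, format, character(1)))
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a 2-column histogram (k-mer spectrum or flow-cytometry events)
#'
#' Rows are (depth, count) or (channel, events).  Rows are sorted by the first
#' column and duplicate keys are summed; negative counts are an error.
#'
#' @param path Path to the 2-column TSV.
#' @param kind `"kmer"` for a [kmer_spectrum()], `"flow"` for a
#'   [flow_histogram()].
#' @param k k-mer length recorded on the spectrum (default 17).
#' @return A `kmer_spectrum` or `flow_histogram` object.
#' @export
read_histogram <- function(path, kind = c("kmer", "flow"), k = 17L) {
  kind <- match.arg(kind)
  tab <- .read_table_lines(path)
  n <- length(tab$fields)
  key <- integer(n); val <- numeric(n)
  for (i in seq_len(n)) {
    f <- tab$fields[[i]]
    ln <- tab$lineno[i]
    if (length(f) != 2L)
      stop("line ", ln, ": expected 2 columns, got ", length(f))
    key[i] <- suppressWarnings(as.integer(f[1]))
    val[i] <- suppressWarnings(as.numeric(f[2]))
    if (is.na(key[i]) || is.na(val[i]))
      stop("line ", ln, ": non-numeric value")
    if (val[i] < 0) stop("line ", ln, ": negative count")
    if (key[i] < 1L) stop("line ", ln, ": first column must be >= 1")
  }
  agg <- rowsum(val, key)             # sums duplicate keys, sorted keys
  key <- as.integer(rownames(agg))
  val <- as.numeric(agg[, 1])
  if (kind == "kmer") kmer_spectrum(key, val, k = k)
  else flow_histogram(key, val)
}

#' Write a 2-column histogram
#'
#' @param hist A `kmer_spectrum` or `flow_histogram`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_histogram <- function(hist, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(hist, "kmer_spectrum"))
    writeLines(paste(hist$depth, format(hist$count, scientific = FALSE,
                                        trim = TRUE), sep = "\t"),
               con, sep = "\n")
  else
    writeLines(paste(hist$channel, format(hist$events, scientific = FALSE,
                                          trim = TRUE), sep = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' Read miRNA-target relation tables
#'
#' Long-format 3-column TSV (tool, mirna_id, gene_id); several files are
#' concatenated.  A duplicated (mirna, gene) relation within one tool's set is
#' an error.
#'
#' @param paths Character vector of paths.
#' @return data.frame with columns tool, mirna_id, gene_id.
#' @export
read_target_table <- function(paths) {
  out <- do.call(rbind, lapply(paths, function(path) {
    tab <- .read_table_lines(path)
    bad <- which(lengths(tab$fields) != 3L)
    if (length(bad) > 0L)
      stop(path, " line ", tab$lineno[bad[1]], ": expected 3 columns (tool, ",
           "mirna_id, gene_id)")
    m <- matrix(unlist(tab$fields), ncol = 3, byrow = TRUE)
    data.frame(tool = m[, 1], mirna_id = m[, 2], gene_id = m[, 3],
               stringsAsFactors = FALSE)
  }))
  key <- paste(out$tool, out$mirna_id, out$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate relation within one tool's table: ",
         sub("\r", " ", key[duplicated(key)][1], fixed = TRUE))
  out
}

#' Write miRNA-target relation tables
#'
#' @param relations data.frame with columns tool, mirna_id, gene_id.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_target_table <- function(relations, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(TARGET_TSV_HEADER,
               paste(relations$tool, relations$mirna_id, relations$gene_id,
                     sep = "\t")), con, sep = "\n")
  invisible(path)
}
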