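# Standard-format I/O, 16S extraction from annotated genomes, and the
# database-level length / ambiguity quality filters.

#' Read / write FASTA as record data.frames
#'
#' Records are plain data.frames with columns `id` and `sequence`
#' (uppercase); round trips preserve both.
#'
#' @param path file path.
#' @return `read_fasta()`: data.frame with columns `id`, `sequence`.
#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(set), sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @param records data.frame with columns `id`, `sequence`.
#' @param width line-wrap width for the sequence lines.
#' @rdname fasta_io
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stopf("duplicate record ids")
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write FASTQ as record data.frames
#'
#' @param path file path.
#' @return `read_fastq()`: data.frame with columns `id`, `sequence`,
#'   `quality` (Phred+33 strings).
#' @rdname fastq_io
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(set), sequence = toupper(as.character(set)),
             quality = as.character(S4Vectors::mcols(set)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @param records data.frame with columns `id`, `sequence`, `quality`.
#' @rdname fastq_io
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(records$quality))
  invisible(path)
}

#' Extract 16S rRNA genes from an annotated genome
#'
#' Pulls every GFF3 feature of type `"rRNA"` whose `product` attribute is
#' exactly `"16S ribosomal RNA"` (RefSeq convention, case-sensitive,
#' URL-decoded by the GFF parser). Coordinates are 1-based inclusive;
#' minus-strand features are reverse-complemented.
#'
#' @param gff_path GFF3 annotation path.
#' @param genome_fasta_path genome FASTA path (sequence names matched on
#'   the first whitespace-separated token of the FASTA header).
#' @return data.frame with columns `id`, `sequence`, `source_id`, `strand`.
#' @export
extract_16s_from_genome <- function(gff_path, genome_fasta_path) {
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  product <- if ("product" %in% names(meta)) as.character(meta$product) else
    rep(NA_character_, length(gr))
  keep <- as.character(meta$type) == "rRNA" & !is.na(product) &
    product == "16S ribosomal RNA"
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      source_id = character(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqid), names(genome))
  if (length(unknown)) stopf("GFF feature references unknown sequence id: %s", unknown[1])
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  lens <- Biostrings::width(genome)[match(seqid, names(genome))]
  if (any(starts < 1L | ends > lens)) stopf("GFF feature coordinates out of bounds")
  strand <- as.character(GenomicRanges::strand(gr))
  seqs <- character(length(gr))
  for (i in seq_along(gr)) {
    s <- Biostrings::subseq(genome[[seqid[i]]], starts[i], ends[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  ids <- if ("ID" %in% names(meta) && !anyNA(meta$ID)) as.character(meta$ID) else
    sprintf("%s:%d-%d(%s)", seqid, starts, ends, strand)
  data.frame(id = ids, sequence = toupper(seqs), source_id = seqid,
             strand = strand, stringsAsFactors = FALSE)
}

#' Length statistics of a record set
#'
#' Arithmetic mean and *population* standard deviation of the sequence
#' lengths (database-scale statistics; the sample/population difference is
#' negligible and a fixed choice is testable).
#'
#' @param records record data.frame with a `sequence` column.
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
length_stats <- function(records) {
  lens <- nchar(records$sequence)
  if (length(lens) < 2L) stopf("length_stats needs at least 2 records")
  m <- mean(lens)
  c(mean = m, sd = sqrt(mean((lens - m)^2)))
}

#' Length / ambiguity quality filter
#'
#' Keeps records whose length lies within `k_sd` standard deviations of
#' the mean (closed interval; `upper_only` mode enforces only the upper
#' bound) and which contain no ambiguous nucleotide (anything outside
#' A/C/G/T, e.g. N). `kept` plus `dropped` always partition the input.
#'
#' @param records record data.frame with a `sequence` column.
#' @param k_sd number of standard deviations (3 for full-length database
#'   sequences, 2 for region fragments and merged reads).
#' @param mode `"two_sided"` or `"upper_only"`.
#' @param stats optional `c(mean = , sd = )`; computed from `records` when
#'   missing.
#' @return list with data.frames `kept` and `dropped`.
#' @export
qc_filter <- function(records, k_sd = 3, mode = c("two_sided", "upper_only"),
                      stats = NULL) {
  mode <- match.arg(mode)
  stopifnot(k_sd > 0)
  if (is.null(stats)) stats <- length_stats(records)
  lens <- nchar(records$sequence)
  lo <- stats[["mean"]] - k_sd * stats[["sd"]]
  hi <- stats[["mean"]] + k_sd * stats[["sd"]]
  in_range <- if (mode == "two_sided") lens >= lo & lens <= hi else lens <= hi
  ambiguous <- grepl("[^ACGT]", records$sequence)
  keep <- in_range & !ambiguous
  list(kept = records[keep, , drop = FALSE],
       dropped = records[!keep, , drop = FALSE])
}
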