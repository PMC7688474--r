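# Paired-end merging by overlap (FLASH-style) and merged-read filters.

#' Merge policy for paired-end reads
#'
#' Defaults follow FLASH with the overlap bounds used for V3-V4 MiSeq
#' data: minimum overlap 20 bp, maximum overlap 300 bp, and FLASH's
#' default maximum mismatch ratio of 0.25.
#'
#' @param min_overlap,max_overlap candidate overlap bounds (bp).
#' @param max_mismatch_ratio maximum fraction of mismatching positions in
#'   the accepted overlap.
#' @return an object of class `merge_policy`.
#' @export
merge_policy <- function(min_overlap = 20L, max_overlap = 300L,
                         max_mismatch_ratio = 0.25) {
  stopifnot(min_overlap > 0, min_overlap <= max_overlap,
            max_mismatch_ratio >= 0, max_mismatch_ratio <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap = as.integer(max_overlap),
                 max_mismatch_ratio = max_mismatch_ratio),
            class = "merge_policy")
}

#' Merge one read pair by overlap
#'
#' The reverse read is reverse-complemented; candidate overlaps within the
#' policy bounds are scored by mismatch ratio, the best (lowest ratio,
#' ties to the longest overlap) is accepted if the ratio is within
#' `max_mismatch_ratio`. At overlap mismatches the base with the higher
#' Phred score wins (ties keep the forward base).
#'
#' @param forward_seq,forward_qual,reverse_seq,reverse_qual the pair
#'   (Phred+33 quality strings, same length as their sequence).
#' @param policy a [merge_policy()].
#' @return list with `sequence`, `quality`, `overlap`, `mismatch_ratio`,
#'   or `NULL` on merge failure.
#' @export
merge_pair <- function(forward_seq, forward_qual, reverse_seq, reverse_qual,
                       policy = merge_policy()) {
  stopifnot(nchar(forward_seq) == nchar(forward_qual),
            nchar(reverse_seq) == nchar(reverse_qual))
  res <- merge_pair_cpp(toupper(forward_seq), forward_qual,
                        toupper(reverse_seq), reverse_qual,
                        policy$min_overlap, policy$max_overlap,
                        policy$max_mismatch_ratio)
  if (!isTRUE(res$merged)) return(NULL)
  res$merged <- NULL
  res
}

#' Merge a table of read pairs
#'
#' @param forward,reverse FASTQ record data.frames (`id`, `sequence`,
#'   `quality`), matched by position; ids must agree up to a `/1` / `/2`
#'   suffix.
#' @param policy a [merge_policy()].
#' @return data.frame of merged reads (`id`, `sequence`, `quality`,
#'   `overlap`, `mismatch_ratio`); failed count in `attr(, "n_failed")`.
#' @export
merge_pairs <- function(forward, reverse, policy = merge_policy()) {
  stopifnot(nrow(forward) == nrow(reverse))
  out <- vector("list", nrow(forward))
  for (i in seq_len(nrow(forward))) {
    m <- merge_pair(forward$sequence[i], forward$quality[i],
                    reverse$sequence[i], reverse$quality[i], policy)
    if (!is.null(m)) {
      out[[i]] <- data.frame(id = sub("/[12]$", "", forward$id[i]),
                             sequence = m$sequence, quality = m$quality,
                             overlap = m$overlap,
                             mismatch_ratio = m$mismatch_ratio,
                             stringsAsFactors = FALSE)
    }
  }
  ok <- !vapply(out, is.null, TRUE)
  merged <- do.call(rbind, out[ok])
  if (is.null(merged)) {
    merged <- data.frame(id = character(0), sequence = character(0),
                         quality = character(0), overlap = integer(0),
                         mismatch_ratio = numeric(0), stringsAsFactors = FALSE)
  }
  attr(merged, "n_failed") <- sum(!ok)
  merged
}

#' Merged-read quality filter
#'
#' Drops merged reads containing an ambiguous base and reads *longer*
#' than `mean + 2 sd` of the hypervariable-region length (upper bound
#' only, exactly as applied to assembled contigs; the V3-V4 region stats
#' are mean 421, sd 11, so 443 is the longest kept read).
#'
#' @param reads merged-read data.frame with a `sequence` column.
#' @param region_stats named numeric `c(mean = , sd = )` of the region
#'   length distribution.
#' @return the kept reads (dropped count in `attr(, "n_dropped")`).
#' @export
merged_qc <- function(reads, region_stats = c(mean = 421, sd = 11)) {
  res <- qc_filter(reads, k_sd = 2, mode = "upper_only", stats = region_stats)
  out <- res$kept
  attr(out, "n_dropped") <- nrow(res$dropped)
  out
}
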