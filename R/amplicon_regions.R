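# In-silico extraction of hypervariable regions by degenerate-primer
# matching with an edit-distance error budget, plus fragment-level QC.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Degenerate primer pair
#'
#' The shipped default is the V3-V4 pair 337F (`CCTACGGGAGGCWGCAG`) / 806R
#' (`GACTACHVGGGTMTCTAAT`), reverse primer given 5'->3' on the reverse
#' strand, with a 20% per-primer error budget (2-3 nt for these lengths).
#'
#' @param name region name.
#' @param forward,reverse IUPAC primer sequences.
#' @param max_error_rate allowed edits as a fraction of primer length.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_error_rate = 0.2) {
  stopifnot(nzchar(forward), nzchar(reverse),
            max_error_rate >= 0, max_error_rate <= 1)
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse), max_error_rate = max_error_rate),
            class = "primer_pair")
}

#' @rdname primer_pair
#' @export
v3v4_primer_pair <- function(max_error_rate = 0.2) {
  primer_pair("V3V4", "CCTACGGGAGGCWGCAG", "GACTACHVGGGTMTCTAAT", max_error_rate)
}

#' IUPAC compatibility of a primer base with a target base
#'
#' A degenerate code matches a target base iff their expansions intersect
#' (`W` = A/T, `M` = A/C, `H` = A/C/T, `V` = A/C/G, `N` = any, ...).
#'
#' @param primer_base single IUPAC code.
#' @param target_base single IUPAC code (usually A/C/G/T).
#' @return logical.
#' @export
iupac_compatible <- function(primer_base, target_base) {
  p <- IUPAC_EXPANSION[[toupper(primer_base)]]
  t <- IUPAC_EXPANSION[[toupper(target_base)]]
  if (is.null(p)) stopf("invalid IUPAC code: '%s'", primer_base)
  if (is.null(t)) stopf("invalid IUPAC code: '%s'", target_base)
  length(intersect(p, t)) > 0L
}

#' Edit budget for a primer at a given error rate
#'
#' `floor(rate * nchar(primer))`; at the default 20% this gives 3 edits for
#' both 17-nt and 19-nt primers, consistent with a 2-3 nt mismatch
#' allowance.
#'
#' @param primer primer sequence.
#' @param rate error rate in `[0, 1]`.
#' @return integer number of allowed edits.
#' @export
max_allowed_edits <- function(primer, rate) {
  stopifnot(rate >= 0, rate <= 1)
  as.integer(floor(rate * nchar(primer)))
}

#' Locate a degenerate primer in a sequence
#'
#' Finds the substring minimising the degenerate-aware edit distance
#' (substitutions, insertions, deletions, unit costs) to the primer,
#' provided the distance is within `budget`. Ties break to the leftmost
#' start, then the shortest span.
#'
#' @param seq target sequence.
#' @param primer IUPAC primer sequence.
#' @param budget maximum allowed edits.
#' @return list with `start`, `end` (1-based inclusive) and `edits`, or
#'   `NULL` when no locus is within budget.
#' @export
find_primer <- function(seq, primer, budget) {
  stopifnot(budget >= 0)
  hit <- primer_search_cpp(toupper(seq), toupper(primer), as.integer(budget))
  if (length(hit) == 0L) return(NULL)
  list(start = hit[1], end = hit[2], edits = hit[3])
}

#' Extract the hypervariable region between a primer pair
#'
#' Locates the forward primer, then the reverse complement of the reverse
#' primer strictly downstream of it, and returns the sequence between the
#' two primer loci (primers excluded). Returns `NULL` when either site is
#' missing (within its edit budget) or the ordering is violated.
#'
#' @param sequence template sequence (full-length 16S).
#' @param pair a [primer_pair()].
#' @return list with `sequence`, `fwd_edits`, `rev_edits`, `fwd_locus`,
#'   `rev_locus` (absolute 1-based coordinates), or `NULL`.
#' @export
extract_region <- function(sequence, pair) {
  sequence <- toupper(sequence)
  fb <- max_allowed_edits(pair$forward, pair$max_error_rate)
  rb <- max_allowed_edits(pair$reverse, pair$max_error_rate)
  fwd <- find_primer(sequence, pair$forward, fb)
  if (is.null(fwd)) return(NULL)
  tail_seq <- substr(sequence, fwd$end + 1L, nchar(sequence))
  if (!nzchar(tail_seq)) return(NULL)
  rev <- find_primer(tail_seq, revcomp(pair$reverse), rb)
  if (is.null(rev)) return(NULL)
  region <- substr(tail_seq, 1L, rev$start - 1L)
  if (!nzchar(region)) return(NULL)
  list(sequence = region,
       fwd_edits = fwd$edits, rev_edits = rev$edits,
       fwd_locus = c(fwd$start, fwd$end),
       rev_locus = c(fwd$end + rev$start, fwd$end + rev$end))
}

#' Extract regions from a set of records
#'
#' @param records record data.frame (`id`, `sequence`, extra columns are
#'   carried through).
#' @param pair a [primer_pair()].
#' @return data.frame of fragments (`id`, `sequence`, `fwd_edits`,
#'   `rev_edits`, carried columns); records without a valid amplicon are
#'   dropped, their count attached as `attr(, "n_failed")`.
#' @export
extract_regions <- function(records, pair) {
  hits <- lapply(records$sequence, extract_region, pair = pair)
  ok <- !vapply(hits, is.null, TRUE)
  out <- records[ok, setdiff(names(records), "sequence"), drop = FALSE]
  out$sequence <- vapply(hits[ok], `[[`, "", "sequence")
  out$fwd_edits <- vapply(hits[ok], `[[`, 0L, "fwd_edits")
  out$rev_edits <- vapply(hits[ok], `[[`, 0L, "rev_edits")
  rownames(out) <- NULL
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Fragment-level quality filter
#'
#' Two-sided `k_sd`-standard-deviation length filter plus the ambiguity
#' (N) filter, delegated to [qc_filter()]. Default `k_sd = 2` as used for
#' extracted hypervariable-region fragments.
#'
#' @param fragments fragment data.frame with a `sequence` column.
#' @param k_sd standard-deviation multiplier.
#' @param stats optional precomputed `c(mean = , sd = )`.
#' @return the kept fragments (dropped count in `attr(, "n_dropped")`).
#' @export
fragment_qc <- function(fragments, k_sd = 2, stats = NULL) {
  res <- qc_filter(fragments, k_sd = k_sd, mode = "two_sided", stats = stats)
  out <- res$kept
  attr(out, "n_dropped") <- nrow(res$dropped)
  out
}
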