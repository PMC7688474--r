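# Per-species consensus models of a hypervariable region and homologous
# species groups: connected components of the >=99%-identity graph over
# species consensus sequences.

#' Needleman-Wunsch global alignment (needle-style)
#'
#' Affine-gap global alignment with EMBOSS-needle default DNA scoring:
#' match +5, mismatch -4, a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`, terminal gaps free
#' (endweight=false) but still counted in the alignment length. Ambiguity
#' codes (N etc.) score -2 against everything and never count as
#' identical. Identity percent is
#' `100 * identical_positions / alignment_length`.
#'
#' Among equal-score alignments the reported one maximises the number of
#' identical columns and then minimises the alignment length -- a
#' deterministic refinement that is invariant under swapping `a` and `b`,
#' so score and identity are symmetric.
#'
#' @param a,b nucleotide sequences.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param end_gaps_free logical; free terminal gaps.
#' @param alignment if `TRUE` the aligned strings are returned too.
#' @return list with `score`, `identity_pct`, `alignment_length`,
#'   `n_identical` and (optionally) `aligned_a`, `aligned_b`.
#' @export
needleman_wunsch <- function(a, b, match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.5,
                             end_gaps_free = TRUE, alignment = FALSE) {
  stopifnot(nzchar(a), nzchar(b))
  res <- nw_align_cpp(toupper(a), toupper(b), match, mismatch,
                      gap_open, gap_extend, end_gaps_free)
  if (!alignment) res[c("aligned_a", "aligned_b")] <- NULL
  res
}

#' Center-star multiple alignment
#'
#' The longest sequence (ties to the lexicographically smallest name) is
#' the center; every other sequence is pairwise-aligned to it with
#' [needleman_wunsch()] and the pairwise gaps are merged into common
#' coordinates. Adequate for the tight within-species alignments feeding
#' the consensus model; not a general-purpose MSA.
#'
#' @param seqs named character vector of sequences (unnamed input is
#'   named by position).
#' @return named character vector of equal-length aligned rows (center
#'   first).
#' @export
star_msa <- function(seqs) {
  if (length(seqs) == 0L) stopf("star_msa needs at least one sequence")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  if (length(seqs) == 1L) return(seqs)
  ord <- order(-nchar(seqs), names(seqs))
  center_name <- names(seqs)[ord[1]]
  center <- seqs[[center_name]]
  others <- seqs[setdiff(names(seqs), center_name)]
  lc <- nchar(center)

  alns <- lapply(others, function(s) {
    r <- needleman_wunsch(center, s, alignment = TRUE)
    list(a = strsplit(r$aligned_a, "")[[1]], b = strsplit(r$aligned_b, "")[[1]])
  })
  # insertions relative to the center: slot i = gap run before center
  # base i (slot lc + 1 = after the last base)
  ins_of <- function(aln) {
    ins <- integer(lc + 1L)
    slot <- 1L
    for (k in seq_along(aln$a)) {
      if (aln$a[k] == "-") ins[slot] <- ins[slot] + 1L else slot <- slot + 1L
    }
    ins
  }
  ins <- lapply(alns, ins_of)
  master <- Reduce(pmax, ins, integer(lc + 1L))

  center_chars <- strsplit(center, "")[[1]]
  build_center <- function() {
    out <- character(0)
    for (i in seq_len(lc)) out <- c(out, rep("-", master[i]), center_chars[i])
    c(out, rep("-", master[lc + 1L]))
  }
  build_other <- function(aln, my_ins) {
    out <- character(0)
    k <- 1L
    for (i in seq_len(lc + 1L)) {
      run <- character(0)
      while (k <= length(aln$a) && aln$a[k] == "-") {
        run <- c(run, aln$b[k]); k <- k + 1L
      }
      out <- c(out, rep("-", master[i] - my_ins[i]), run)
      if (i <= lc) {  # the center base column itself
        out <- c(out, aln$b[k]); k <- k + 1L
      }
    }
    out
  }
  rows <- c(setNames(list(build_center()), center_name),
            mapply(build_other, alns, ins, SIMPLIFY = FALSE))
  vapply(rows, paste, "", collapse = "")
}

#' Plurality consensus of an alignment
#'
#' Per column, the most frequent non-gap residue wins if its count is at
#' least `plurality_fraction` of the rows; otherwise the column is `N`.
#' Ties go to the lexicographically smallest residue; all-gap columns are
#' removed. This reproduces the behaviour of a default plurality
#' consensus (EMBOSS cons-style) on DNA.
#'
#' @param msa character vector of equal-length aligned rows.
#' @param plurality_fraction minimum fraction of rows the winner must
#'   reach.
#' @return consensus sequence (may contain `N`).
#' @export
consensus <- function(msa, plurality_fraction = 0.5) {
  stopifnot(length(msa) >= 1L, length(unique(nchar(msa))) == 1L)
  mat <- do.call(rbind, strsplit(msa, ""))
  nrows <- nrow(mat)
  cols <- apply(mat, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return("")          # all-gap column: removed
    tab <- table(res)
    top <- sort(names(tab)[tab == max(tab)])[1]  # tie -> lexicographic
    if (tab[[top]] >= plurality_fraction * nrows) top else "N"
  })
  paste(cols[cols != ""], collapse = "")
}

#' Build per-species consensus models
#'
#' All member sequences of a species are star-aligned and collapsed by
#' plurality (so a 2-vs-1 column keeps the majority base); `n_strains`
#' counts the non-redundant (deduplicated) member sequences.
#'
#' @param fragments fragment data.frame with columns `species`, `genus`,
#'   `sequence` (one row per strain fragment).
#' @param region region name recorded on the output.
#' @param plurality_fraction passed to [consensus()].
#' @return a `species_consensus_db`: data.frame with columns `species`,
#'   `genus`, `region`, `consensus_seq`, `n_strains`.
#' @export
build_species_consensus <- function(fragments, region = "V3V4",
                                    plurality_fraction = 0.5) {
  stopifnot(all(c("species", "genus", "sequence") %in% names(fragments)))
  species <- sort(unique(fragments$species))
  rows <- lapply(species, function(sp) {
    sub <- fragments[fragments$species == sp, , drop = FALSE]
    msa <- star_msa(setNames(sub$sequence, sprintf("m%04d", seq_len(nrow(sub)))))
    data.frame(species = sp, genus = sub$genus[1], region = region,
               consensus_seq = consensus(msa, plurality_fraction),
               n_strains = length(unique(sub$sequence)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("species_consensus_db", "data.frame")
  out
}

#' Pairwise similarity graph over species consensus sequences
#'
#' An undirected edge connects two species whose consensus sequences
#' share at least `threshold` percent identity ([needleman_wunsch()]
#' identity over the alignment length, terminal gaps included). By
#' default only same-genus pairs are compared, reflecting that 16S
#' indistinguishability is a within-genus phenomenon; `scope = "all"`
#' compares every pair.
#'
#' @param consensus_db a [build_species_consensus()] table.
#' @param threshold identity percent threshold (default 99).
#' @param scope `"within_genus"` or `"all"`.
#' @return data.frame of edges (`species1`, `species2`, `identity`).
#' @export
similarity_graph <- function(consensus_db, threshold = 99,
                             scope = c("within_genus", "all")) {
  scope <- match.arg(scope)
  n <- nrow(consensus_db)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (scope == "within_genus" &&
            consensus_db$genus[i] != consensus_db$genus[j]) next
        r <- needleman_wunsch(consensus_db$consensus_seq[i],
                              consensus_db$consensus_seq[j])
        if (r$identity_pct >= threshold - 1e-9) {
          edges[[length(edges) + 1L]] <- data.frame(
            species1 = consensus_db$species[i],
            species2 = consensus_db$species[j],
            identity = r$identity_pct, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, edges)
  if (is.null(out)) {
    out <- data.frame(species1 = character(0), species2 = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Homologous species groups as connected components
#'
#' Species linked (directly or transitively) by similarity-graph edges
#' form one group; species without edges form singleton groups. The
#' groups partition the species set.
#'
#' @param species character vector of all species.
#' @param edges edge data.frame (`species1`, `species2`).
#' @return list of character vectors (members, sorted), ordered by first
#'   member.
#' @export
build_groups <- function(species, edges) {
  stopifnot(all(c(edges$species1, edges$species2) %in% species))
  g <- igraph::graph_from_data_frame(
    edges[, c("species1", "species2"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = species))
  comp <- igraph::components(g)
  groups <- unname(split(names(comp$membership), comp$membership))
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[[`, "", 1L))]
}

#' Name a homologous species group
#'
#' A singleton keeps its species name; a multi-member group is named
#' after the member with the most strains, extended with `"+"` (ties go
#' to the lexicographically smallest tied member).
#'
#' @param members character vector of member species.
#' @param strain_counts named integer vector, species -> strain count.
#' @return the group name.
#' @export
name_group <- function(members, strain_counts) {
  if (length(members) == 1L) return(members)
  counts <- strain_counts[members]
  if (anyNA(counts)) stopf("missing strain count for group member")
  top <- sort(members[counts == max(counts)])[1]
  paste0(top, "+")
}

#' Group table with names and strain counts
#'
#' Convenience wrapper: builds the similarity graph, the connected
#' components and the named group table in one step.
#'
#' @param consensus_db a [build_species_consensus()] table.
#' @param threshold,scope passed to [similarity_graph()].
#' @return list with `edges` (data.frame), `groups` (list of members) and
#'   `table` (data.frame: `group_name`, `member`, `n_strains`).
#' @export
build_group_table <- function(consensus_db, threshold = 99,
                              scope = "within_genus") {
  edges <- similarity_graph(consensus_db, threshold = threshold, scope = scope)
  groups <- build_groups(consensus_db$species, edges)
  counts <- setNames(consensus_db$n_strains, consensus_db$species)
  rows <- lapply(groups, function(members) {
    data.frame(group_name = name_group(members, counts), member = members,
               n_strains = unname(counts[members]), stringsAsFactors = FALSE)
  })
  list(edges = edges, groups = groups, table = do.call(rbind, rows))
}

#' Export / read the group similarity graph as an edge list
#'
#' @param edges edge data.frame (`species1`, `species2`, `identity`).
#' @param path TSV path.
#' @rdname group_graph_io
#' @export
export_group_graph <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname group_graph_io
#' @export
read_group_graph <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric"))
}

#' Write / read a species consensus database as FASTA
#'
#' Headers encode `species|genus|region|n_strains`.
#'
#' @param consensus_db a [build_species_consensus()] table.
#' @param path FASTA path.
#' @rdname consensus_fasta
#' @export
write_consensus_fasta <- function(consensus_db, path) {
  ids <- sprintf("%s|%s|%s|%d", consensus_db$species, consensus_db$genus,
                 consensus_db$region, consensus_db$n_strains)
  write_fasta(data.frame(id = ids, sequence = consensus_db$consensus_seq,
                         stringsAsFactors = FALSE), path)
}

#' @rdname consensus_fasta
#' @export
read_consensus_fasta <- function(path) {
  recs <- read_fasta(path)
  parts <- strsplit(recs$id, "|", fixed = TRUE)
  out <- data.frame(
    species = vapply(parts, `[[`, "", 1L),
    genus = vapply(parts, `[[`, "", 2L),
    region = vapply(parts, `[[`, "", 3L),
    consensus_seq = recs$sequence,
    n_strains = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  class(out) <- c("species_consensus_db", "data.frame")
  out
}
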