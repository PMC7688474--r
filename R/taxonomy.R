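# Canonical taxonomy: taxdump loading, lowest-resolvable-rank lookup and
# 7-rank lineage re-annotation.

split_dmp_line <- function(line) {
  # taxdump rows are "\t|\t"-delimited and end with "\t|"
  line <- sub("\t\\|$", "", line)
  strsplit(line, "\t\\|\t")[[1]]
}

#' Load an NCBI-taxdump-style taxonomy
#'
#' Reads the pipe-delimited `nodes.dmp` / `names.dmp` dialect and builds a
#' taxonomy tree with a case-insensitive name index. Only rows whose name
#' class is `"scientific name"` populate the index; a name mapping to
#' several taxids keeps all candidates (resolution policy lives in
#' [resolve_lowest_rank()]).
#'
#' @param nodes_path path to a `nodes.dmp`-style file
#'   (`taxid | parent taxid | rank | ...`).
#' @param names_path path to a `names.dmp`-style file
#'   (`taxid | name | unique name | name class`).
#' @return an object of class `taxonomy_tree`: a list with `nodes`
#'   (data.frame: `taxid`, `parent_taxid`, `rank`, `scientific_name`) and
#'   `name_index` (list: lowercased name -> integer taxid vector).
#' @export
load_taxdump <- function(nodes_path, names_path) {
  if (!file.exists(nodes_path)) stopf("nodes file not found: %s", nodes_path)
  if (!file.exists(names_path)) stopf("names file not found: %s", names_path)
  node_lines <- readLines(nodes_path)
  name_lines <- readLines(names_path)
  node_lines <- node_lines[nzchar(node_lines)]
  name_lines <- name_lines[nzchar(name_lines)]
  if (length(node_lines) == 0L) stopf("empty nodes file: %s", nodes_path)
  if (length(name_lines) == 0L) stopf("empty names file: %s", names_path)

  parts <- lapply(node_lines, split_dmp_line)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad)) stopf("malformed nodes.dmp row at line %d", bad[1])
  taxid <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  rank <- vapply(parts, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent)) {
    stopf("malformed nodes.dmp row at line %d", which(is.na(taxid) | is.na(parent))[1])
  }
  if (anyDuplicated(taxid)) {
    stopf("duplicate taxid %d in nodes.dmp", taxid[anyDuplicated(taxid)])
  }
  rank[!rank %in% TAX_RANKS] <- "other"

  nparts <- lapply(name_lines, split_dmp_line)
  bad <- which(vapply(nparts, length, 0L) < 4L)
  if (length(bad)) stopf("malformed names.dmp row at line %d", bad[1])
  ntaxid <- suppressWarnings(as.integer(vapply(nparts, `[[`, "", 1L)))
  if (anyNA(ntaxid)) stopf("malformed names.dmp row at line %d", which(is.na(ntaxid))[1])
  nname <- vapply(nparts, `[[`, "", 2L)
  nclass <- vapply(nparts, `[[`, "", 4L)

  sci <- nclass == "scientific name"
  sci_name <- setNames(nname[sci], as.character(ntaxid[sci]))
  nodes <- data.frame(
    taxid = taxid,
    parent_taxid = parent,
    rank = rank,
    scientific_name = unname(sci_name[as.character(taxid)]),
    stringsAsFactors = FALSE
  )
  name_index <- split(ntaxid[sci], tolower(nname[sci]))

  # structural invariants
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1L) stopf("taxonomy must have exactly one root (its own parent)")
  missing_parent <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(missing_parent)) {
    stopf("parent taxid %d not present in nodes.dmp", missing_parent[1])
  }

  structure(list(nodes = nodes, name_index = name_index, root = root),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree: %d nodes, %d indexed names, root taxid %d>\n",
              nrow(x$nodes), length(x$name_index), x$root))
  invisible(x)
}

#' Look up a name in the taxonomy index
#'
#' @param tree a `taxonomy_tree`.
#' @param name a taxon name (matched case-insensitively, exact).
#' @return integer vector of candidate taxids (length 0 if unknown).
#' @export
lookup_name <- function(tree, name) {
  hits <- tree$name_index[[tolower(trimws(name))]]
  if (is.null(hits)) integer(0) else hits
}

#' Reduce a raw species label to its binomial
#'
#' Keeps the first two whitespace-separated tokens, dropping strain and
#' subspecies suffixes. Labels that carry no species information (a single
#' token, or a second token of `"sp."`/`"sp"`) are not binomials and yield
#' `NA_character_`.
#'
#' @param raw raw species label.
#' @return the binomial, or `NA_character_` if the label is not a binomial.
#' @export
normalize_species_label <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    stopf("empty species label")
  }
  tokens <- strsplit(trimws(raw), "\\s+")[[1]]
  if (length(tokens) < 2L || tolower(tokens[2]) %in% c("sp.", "sp")) {
    return(NA_character_)
  }
  paste(tokens[1], tokens[2])
}

#' Resolve a source annotation to its lowest-rank taxid
#'
#' Searches the provided labels from species up to superkingdom and
#' returns the taxid of the first rank whose label resolves in the name
#' index; unresolvable ranks are skipped. Species labels are first
#' reduced to binomials with [normalize_species_label()]; homonyms
#' (several taxids for one name) are kept only if exactly one candidate's
#' node rank equals the rank being searched. The merged genus label
#' `"Escherichia.Shigella"` (which is not an NCBI name) resolves via
#' `"Escherichia"` so that re-annotation is idempotent.
#'
#' @param tree a `taxonomy_tree`.
#' @param ann named character vector of per-rank labels (names among
#'   [TAX_RANKS]); `NA`/empty entries are skipped.
#' @return a single taxid, or `NA_integer_` if no rank resolves.
#' @export
resolve_lowest_rank <- function(tree, ann) {
  for (rank in rev(TAX_RANKS)) {
    label <- if (rank %in% names(ann)) ann[[rank]] else NA_character_
    if (is.na(label) || !nzchar(trimws(label))) next
    if (rank == "species") {
      label <- tryCatch(normalize_species_label(label), error = function(e) NA_character_)
      if (is.na(label)) next
    }
    if (rank == "genus" && tolower(trimws(label)) == "escherichia.shigella") {
      label <- "Escherichia"
    }
    hits <- lookup_name(tree, label)
    if (length(hits) == 0L) next
    if (length(hits) > 1L) {
      ranks <- tree$nodes$rank[match(hits, tree$nodes$taxid)]
      hits <- hits[ranks == rank]
      if (length(hits) != 1L) next  # still ambiguous: skip this rank
    }
    return(hits)
  }
  NA_integer_
}

#' Seven-rank lineage of a taxid
#'
#' Walks the ancestor path to the root and fills the seven canonical
#' ranks; ranks absent from the path are left `NA` (unannotated). A
#' species name under an unannotated genus is cleared, since group naming
#' and classifier training key on the genus.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a taxid present in the tree.
#' @return named character vector over [TAX_RANKS] (`NA` = unannotated).
#' @export
lineage_of <- function(tree, taxid) {
  idx <- match(taxid, tree$nodes$taxid)
  if (is.na(idx)) stopf("unknown taxid: %s", taxid)
  lin <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
  for (step in seq_len(nrow(tree$nodes) + 1L)) {
    rank <- tree$nodes$rank[idx]
    if (rank %in% TAX_RANKS) lin[[rank]] <- tree$nodes$scientific_name[idx]
    parent <- tree$nodes$parent_taxid[idx]
    if (parent == tree$nodes$taxid[idx]) break  # root
    idx <- match(parent, tree$nodes$taxid)
  }
  if (is.na(lin[["genus"]])) lin[["species"]] <- NA_character_
  lin
}

#' Merge Escherichia and Shigella into one genus label
#'
#' The 16S rRNA sequences of *Escherichia* and *Shigella* are essentially
#' identical, so both genera are collectively labelled
#' `"Escherichia.Shigella"`; the species rank is retained.
#'
#' @param lin a lineage (named character vector over [TAX_RANKS]).
#' @return the lineage with the merged genus label where applicable.
#' @export
merge_escherichia_shigella <- function(lin) {
  g <- lin[["genus"]]
  if (!is.na(g) && g %in% c("Escherichia", "Shigella")) {
    lin[["genus"]] <- "Escherichia.Shigella"
  }
  lin
}

#' Re-annotate reference records against a canonical taxonomy
#'
#' Each record's source annotation is resolved to the taxid of its lowest
#' resolvable rank ([resolve_lowest_rank()]); the canonical seven-rank
#' lineage is rebuilt from that taxid ([lineage_of()]) and the
#' Escherichia/Shigella merge applied. Records resolving nowhere are
#' flagged `"unannotated"` (their source columns are left untouched) and
#' should be excluded from downstream training.
#'
#' @param tree a `taxonomy_tree`.
#' @param records data.frame with a column `id`, any of the
#'   [TAX_RANKS] columns holding source labels, and optionally
#'   `raw_species_label` (preferred over the `species` column when
#'   resolving the species rank).
#' @return the records with refreshed rank columns and an added `status`
#'   column (`"ok"` / `"unannotated"`); the re-annotated vs dropped counts
#'   are attached as `attr(, "summary")` and emitted as a message.
#' @export
reannotate <- function(tree, records) {
  stopifnot(is.data.frame(records), "id" %in% names(records))
  for (rank in TAX_RANKS) {
    if (!rank %in% names(records)) records[[rank]] <- NA_character_
  }
  status <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ann <- setNames(as.character(records[i, TAX_RANKS]), TAX_RANKS)
    raw <- records$raw_species_label[i] %||% NA_character_
    if (!is.null(records$raw_species_label) && !is.na(raw) && nzchar(raw)) {
      ann[["species"]] <- raw
    }
    taxid <- resolve_lowest_rank(tree, ann)
    if (is.na(taxid)) {
      status[i] <- "unannotated"
      next
    }
    lin <- merge_escherichia_shigella(lineage_of(tree, taxid))
    records[i, TAX_RANKS] <- as.list(lin)
    status[i] <- "ok"
  }
  records$status <- status
  summary <- c(ok = sum(status == "ok"), unannotated = sum(status == "unannotated"))
  attr(records, "summary") <- summary
  message(sprintf("reannotate: %d re-annotated, %d unannotated (dropped downstream)",
                  summary[["ok"]], summary[["unannotated"]]))
  records
}

#' Read / write lineage tables
#'
#' TSV with columns `id`, the seven rank columns, `raw_species_label` and
#' (on output of [reannotate()]) `status`. Empty fields are unannotated
#' ranks (`NA`).
#'
#' @param path file path.
#' @rdname lineage_tsv
#' @export
read_lineage_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "",
             colClasses = "character")
}

#' @param records lineage data.frame.
#' @rdname lineage_tsv
#' @export
write_lineage_tsv <- function(records, path) {
  attr(records, "summary") <- NULL
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
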