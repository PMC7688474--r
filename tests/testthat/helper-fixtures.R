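# Shared fixtures, built in code. The default synthetic world is
# expensive enough to build once and reuse across test files (helpers are
# sourced into one session per test run).

write_taxdump_fixture <- function(dir, nodes, names_df) {
  # nodes: data.frame taxid, parent, rank; names_df: taxid, name, class
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(dir, "nodes.dmp")
  mp <- file.path(dir, "names.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nodes$taxid, nodes$parent, nodes$rank), np)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\t%s\t|", names_df$taxid, names_df$name,
                     names_df$class), mp)
  c(nodes = np, names = mp)
}

# toy tree: root / Bacteria / Firmicutes / Bacilli / Bacillales /
# Bacillaceae / Bacillus / B. subtilis, plus an order-level homonym
# "Duplex" at two ranks and a family-gap genus "Gapgenus"
toy_taxdump <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  nodes <- data.frame(
    taxid = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 20L, 21L, 30L),
    parent = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 4L, 5L, 4L),
    rank = c("no rank", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species", "order", "genus", "genus"),
    stringsAsFactors = FALSE)
  names_df <- data.frame(
    taxid = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 8L, 20L, 21L, 30L),
    name = c("root", "Bacteria", "Firmicutes", "Bacilli", "Bacillales",
             "Bacillaceae", "Bacillus", "Bacillus subtilis",
             "hay bacillus", "Duplex", "Duplex", "Gapgenus"),
    class = c(rep("scientific name", 8), "common name",
              rep("scientific name", 3)),
    stringsAsFactors = FALSE)
  paths <- write_taxdump_fixture(dir, nodes, names_df)
  load_taxdump(paths[["nodes"]], paths[["names"]])
}

# cached default synthetic world (spec defaults; used by several files
# and by the acceptance suite)
default_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synthetic_spec()
    refs <- simulate_references(spec)
    frags <- extract_regions(refs$records, spec$primer_pair)
    db <- build_species_consensus(frags)
    gt <- build_group_table(db)
    model <- train_classifier(frags)
    cache <<- list(spec = spec, refs = refs, frags = frags, db = db,
                   edges = gt$edges, groups = gt$groups, table = gt$table,
                   model = model,
                   group_of = setNames(gt$table$group_name, gt$table$member))
    cache
  }
})

# a small world for cheaper unit tests: 3 genera x 3 species x 2 strains,
# one planted pair
small_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- synthetic_spec(n_genera = 3, species_per_genus = 3,
                           strains_per_species = 2,
                           planted_groups = list(c("Genus01 species01",
                                                   "Genus01 species02")),
                           seed = 7)
    refs <- simulate_references(spec)
    frags <- extract_regions(refs$records, spec$primer_pair)
    db <- build_species_consensus(frags)
    gt <- build_group_table(db)
    cache <<- list(spec = spec, refs = refs, frags = frags, db = db,
                   edges = gt$edges, groups = gt$groups, table = gt$table,
                   group_of = setNames(gt$table$group_name, gt$table$member))
    cache
  }
})
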