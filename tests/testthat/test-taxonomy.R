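test_that("load_taxdump reads the taxdump dialect and indexes scientific names", {
  dir <- withr::local_tempdir()
  paths <- write_taxdump_fixture(
    dir,
    data.frame(taxid = c(1L, 2L, 3L), parent = c(1L, 1L, 2L),
               rank = c("no rank", "superkingdom", "phylum")),
    data.frame(taxid = c(1L, 2L, 3L),
               name = c("root", "Bacteria", "Firmicutes"),
               class = "scientific name"))
  tree <- load_taxdump(paths[["nodes"]], paths[["names"]])
  expect_equal(nrow(tree$nodes), 3L)
  expect_equal(lookup_name(tree, "Firmicutes"), 3L)
  expect_equal(lookup_name(tree, "firmicutes"), 3L)  # case-insensitive
  expect_length(lookup_name(tree, "Proteobacteria"), 0L)
})

test_that("load_taxdump rejects empty, malformed and duplicate input", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.dmp")
  names_f <- file.path(dir, "names.dmp")
  writeLines("1\t|\t1\t|\tno rank\t|", nodes)
  writeLines(character(0), names_f)
  expect_error(load_taxdump(nodes, names_f), "empty names")
  writeLines("1\t|\tscientific name\t|", names_f)  # too few fields
  expect_error(load_taxdump(nodes, names_f), "malformed names.*line 1")
  writeLines("1\t|\troot\t|\t\t|\tscientific name\t|", names_f)
  writeLines(c("1\t|\t1\t|\tno rank\t|", "1\t|\t1\t|\tno rank\t|"), nodes)
  expect_error(load_taxdump(nodes, names_f), "duplicate taxid")
})

test_that("homonyms keep all candidates and resolve by rank agreement", {
  tree <- toy_taxdump()
  hits <- lookup_name(tree, "Duplex")
  expect_setequal(hits, c(20L, 21L))
  # searching the genus rank picks the genus-ranked homonym
  expect_equal(resolve_lowest_rank(tree, c(genus = "Duplex")), 21L)
  expect_equal(resolve_lowest_rank(tree, c(order = "Duplex")), 20L)
})

test_that("normalize_species_label keeps the binomial and flags non-binomials", {
  expect_equal(normalize_species_label("Staphylococcus aureus subsp. aureus NCTC 8325"),
               "Staphylococcus aureus")
  expect_equal(normalize_species_label("Escherichia coli"), "Escherichia coli")
  expect_true(is.na(normalize_species_label("Clostridium sp.")))
  expect_true(is.na(normalize_species_label("Clostridium sp")))
  expect_true(is.na(normalize_species_label("Clostridium")))
  expect_error(normalize_species_label("  "), "empty")
})

test_that("resolve_lowest_rank searches species to superkingdom, skipping failures", {
  tree <- toy_taxdump()
  expect_equal(resolve_lowest_rank(tree, c(species = "Bacillus subtilis")), 8L)
  # strain suffix is normalised away before lookup
  expect_equal(resolve_lowest_rank(
    tree, c(species = "Bacillus subtilis strain 168")), 8L)
  # unresolvable species falls through to genus
  expect_equal(resolve_lowest_rank(
    tree, c(species = "Notaspecies xyz", genus = "Bacillus")), 7L)
  # common names are not indexed
  expect_equal(resolve_lowest_rank(
    tree, c(species = "hay bacillus", genus = "Bacillus")), 7L)
  expect_true(is.na(resolve_lowest_rank(tree, c(species = "No such thing"))))
})

test_that("lineage_of fills the seven ranks and marks gaps unannotated", {
  tree <- toy_taxdump()
  lin <- lineage_of(tree, 8L)
  expect_equal(unname(lin), c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
                              "Bacillaceae", "Bacillus", "Bacillus subtilis"))
  # genus-level taxid: species unannotated
  expect_true(is.na(lineage_of(tree, 7L)[["species"]]))
  # Gapgenus hangs off the class: family and order unannotated, genus named
  lin <- lineage_of(tree, 30L)
  expect_true(is.na(lin[["family"]]))
  expect_equal(lin[["genus"]], "Gapgenus")
  expect_error(lineage_of(tree, 999L), "unknown taxid")
})

test_that("Escherichia and Shigella merge; other genera unchanged", {
  base <- setNames(rep(NA_character_, 7), TAX_RANKS)
  for (g in c("Escherichia", "Shigella")) {
    lin <- base; lin[["genus"]] <- g; lin[["species"]] <- paste(g, "sp1")
    merged <- merge_escherichia_shigella(lin)
    expect_equal(merged[["genus"]], "Escherichia.Shigella")
    expect_equal(merged[["species"]], paste(g, "sp1"))  # species retained
  }
  lin <- base; lin[["genus"]] <- "Bacillus"
  expect_equal(merge_escherichia_shigella(lin), lin)
})

test_that("reannotate rebuilds lineages from the lowest resolvable rank", {
  tree <- toy_taxdump()
  records <- data.frame(
    id = c("r1", "r2", "r3"),
    order = c("Obsoletales", NA, NA),      # obsolete source order
    genus = c("Bacillus", NA, "Bacillus"),
    species = c(NA, "Nowhere atall", NA),
    raw_species_label = c(NA, NA, "Bacillus subtilis str. 168"),
    stringsAsFactors = FALSE)
  out <- suppressMessages(reannotate(tree, records))
  expect_equal(out$status, c("ok", "unannotated", "ok"))
  # r1: rebuilt from the genus taxid with the canonical order
  expect_equal(out$order[1], "Bacillales")
  expect_true(is.na(out$species[1]))
  # r3: resolved at species rank via the raw label
  expect_equal(out$species[3], "Bacillus subtilis")
  expect_equal(attr(out, "summary"), c(ok = 2L, unannotated = 1L))
  # conservation
  expect_equal(sum(attr(out, "summary")), nrow(records))
})

test_that("reannotate is idempotent and lineages are tree-consistent", {
  tree <- toy_taxdump()
  records <- data.frame(
    id = c("a", "b"),
    genus = c("Bacillus", "Gapgenus"),
    species = c("Bacillus subtilis", NA),
    stringsAsFactors = FALSE)
  once <- suppressMessages(reannotate(tree, records))
  twice <- suppressMessages(reannotate(tree, once))
  expect_equal(once, twice, ignore_attr = TRUE)
  # every named rank agrees with the root path of the resolved node
  for (i in seq_len(nrow(once))) {
    ann <- setNames(as.character(once[i, TAX_RANKS]), TAX_RANKS)
    taxid <- resolve_lowest_rank(tree, ann)
    ref <- lineage_of(tree, taxid)
    named <- !is.na(ann)
    expect_equal(ann[named], ref[named])
  }
})

test_that("lineage TSV round trip preserves unannotated ranks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = "x", superkingdom = "Bacteria", phylum = NA_character_,
                   class = NA_character_, order = NA_character_,
                   family = NA_character_, genus = "Bacillus",
                   species = NA_character_, raw_species_label = "Bacillus sp.",
                   stringsAsFactors = FALSE)
  write_lineage_tsv(df, path)
  back <- read_lineage_tsv(path)
  expect_equal(back, df)
})
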