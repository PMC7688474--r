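test_that("simulate_taxonomy writes a resolvable taxdump world", {
  spec <- synthetic_spec(n_genera = 2, species_per_genus = 3,
                         strains_per_species = 1, seed = 2)
  dir <- withr::local_tempdir()
  paths <- simulate_taxonomy(spec, dir)
  tree <- load_taxdump(paths[["nodes"]], paths[["names"]])
  expect_equal(sum(tree$nodes$rank == "species"), 6L)
  for (sp in spec$species) {
    taxid <- resolve_lowest_rank(tree, c(species = sp))
    expect_false(is.na(taxid))
    lin <- lineage_of(tree, taxid)
    expect_equal(lin[["species"]], sp)
    expect_false(anyNA(lin))
  }
  # the lineage TSV re-annotates cleanly and idempotently
  records <- read_lineage_tsv(paths[["lineage"]])
  out <- suppressMessages(reannotate(tree, records))
  expect_true(all(out$status == "ok"))
})

test_that("taxonomy files are byte-identical under a fixed seed", {
  spec <- synthetic_spec(n_genera = 2, species_per_genus = 2,
                         strains_per_species = 2, seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulate_taxonomy(spec, d1); p2 <- simulate_taxonomy(spec, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("Escherichia/Shigella can be planted to exercise the merge", {
  spec <- synthetic_spec(n_genera = 2, species_per_genus = 2,
                         strains_per_species = 1,
                         include_escherichia_shigella = TRUE, seed = 3)
  dir <- withr::local_tempdir()
  paths <- simulate_taxonomy(spec, dir)
  tree <- load_taxdump(paths[["nodes"]], paths[["names"]])
  records <- data.frame(id = c("e", "s"),
                        species = c("Escherichia coli", "Shigella flexneri"),
                        stringsAsFactors = FALSE)
  out <- suppressMessages(reannotate(tree, records))
  expect_equal(out$genus, rep("Escherichia.Shigella", 2))
  expect_false(any(out$genus %in% c("Escherichia", "Shigella")))
})

test_that("references embed extractable regions and pass the k=3 filter", {
  w <- small_world()
  expect_equal(nrow(w$frags), nrow(w$refs$records))   # no extraction failures
  expect_equal(attr(w$frags, "n_failed"), 0L)
  res <- qc_filter(w$refs$records, k_sd = 3)
  expect_equal(nrow(res$dropped), 0L)
  # extracted fragments are the planted strain cores (within-species
  # divergence only)
  sp <- w$spec$species[1]
  frag <- w$frags$sequence[w$frags$species == sp][1]
  core <- w$refs$cores[[sp]]
  expect_equal(nchar(frag), nchar(core))
})

test_that("planted structure: groups are close, non-groups are separated", {
  w <- small_world()
  L <- w$spec$region_core_length
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  grp <- w$spec$planted_groups[[1]]
  expect_lt(ham(w$refs$cores[[grp[1]]], w$refs$cores[[grp[2]]]) / L, 0.01)
  others <- setdiff(w$spec$species, grp)
  for (a in others) {
    for (b in setdiff(w$spec$species, a)) {
      if (all(c(a, b) %in% grp)) next
      if (sub(" .*", "", a) != sub(" .*", "", b)) next
      if (!(a %in% grp) || !(b %in% grp)) {
        expect_gt(ham(w$refs$cores[[a]], w$refs$cores[[b]]) / L, 0.02)
      }
    }
  }
})

test_that("simulate_community implements the three abundance models", {
  expect_equal(simulate_community(sprintf("sp%d", 1:4), "uniform")$abundance,
               rep(0.25, 4))
  lin <- simulate_community(sprintf("sp%d", 1:4), "linear", seed = 9)
  expect_setequal(round(lin$abundance, 10), c(0.4, 0.3, 0.2, 0.1))
  pl <- simulate_community(c("a", "b"), "powerlaw", p = 1, seed = 9)
  expect_setequal(round(pl$abundance, 10), round(c(2 / 3, 1 / 3), 10))
  pl2 <- simulate_community(sprintf("sp%d", 1:3), "powerlaw", p = 2, seed = 9)
  expect_equal(sum(pl2$abundance), 1)
  expect_setequal(round(pl2$abundance, 6),
                  round(c(1, 1 / 4, 1 / 9) / sum(c(1, 1 / 4, 1 / 9)), 6))
  expect_error(simulate_community("a", "powerlaw", p = 0), "positive")
  # the seeded order decouples species identity from abundance rank
  l1 <- simulate_community(sprintf("sp%d", 1:6), "linear", seed = 1)
  l2 <- simulate_community(sprintf("sp%d", 1:6), "linear", seed = 2)
  expect_false(identical(l1$abundance, l2$abundance))
})

test_that("error-free amplicons are exact region copies with complete truth", {
  w <- small_world()
  comm <- simulate_community(w$spec$species[1:3], "uniform", seed = 11)
  sim <- simulate_amplicons(w$refs, comm, error_rate = 0, n_reads = 30, seed = 12)
  expect_equal(nrow(sim$reads), 30L)
  expect_setequal(sim$truth$read_id, sim$reads$id)
  region_of <- setNames(w$frags$sequence, w$frags$id)
  for (i in seq_len(nrow(sim$reads))) {
    strain <- sim$truth$strain[sim$truth$read_id == sim$reads$id[i]]
    expect_equal(sim$reads$sequence[i], unname(region_of[strain]))
  }
})

test_that("copy-number bias weights read counts as expected", {
  w <- small_world()
  comm <- simulate_community(w$spec$species[1:2], "uniform", seed = 13)
  comm$copy_number <- c(4L, 1L)
  sim <- simulate_amplicons(w$refs, comm, error_rate = 0, n_reads = 600, seed = 14)
  counts <- table(sim$truth$species)[comm$species]
  ratio <- counts[[1]] / counts[[2]]
  expect_gt(ratio, 2.8)  # binomial tolerance around 4
  expect_lt(ratio, 5.6)
  # bias off: roughly equal
  sim <- simulate_amplicons(w$refs, comm, error_rate = 0, n_reads = 600,
                            copy_number_bias = FALSE, seed = 14)
  counts <- table(sim$truth$species)[comm$species]
  expect_lt(abs(counts[[1]] / sum(counts) - 0.5), 0.08)
})

test_that("amplicon output is deterministic under a seed, and errors are planted", {
  w <- small_world()
  comm <- simulate_community(w$spec$species[1:2], "uniform", seed = 15)
  s1 <- simulate_amplicons(w$refs, comm, n_reads = 50, seed = 16)
  s2 <- simulate_amplicons(w$refs, comm, n_reads = 50, seed = 16)
  expect_identical(s1, s2)
  path1 <- withr::local_tempfile(fileext = ".fastq")
  path2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, path1); write_fastq(s2$reads, path2)
  expect_identical(readLines(path1), readLines(path2))
  # at 0.5% error some reads differ from their template
  region_of <- setNames(w$frags$sequence, w$frags$id)
  n_changed <- sum(vapply(seq_len(nrow(s1$reads)), function(i) {
    strain <- s1$truth$strain[s1$truth$read_id == s1$reads$id[i]]
    s1$reads$sequence[i] != region_of[[strain]]
  }, TRUE))
  expect_gt(n_changed, 0)
})

test_that("paired amplicons carry >=20 nt overlaps and merge back", {
  w <- small_world()
  comm <- simulate_community(w$spec$species[1:2], "uniform", seed = 17)
  sim <- simulate_amplicons(w$refs, comm, error_rate = 0, n_reads = 10,
                            paired = TRUE, seed = 18)
  merged <- merge_pairs(sim$forward, sim$reverse)
  expect_equal(attr(merged, "n_failed"), 0L)
  expect_true(all(merged$overlap >= 20))
  region_of <- setNames(w$frags$sequence, w$frags$id)
  for (i in seq_len(nrow(merged))) {
    strain <- sim$truth$strain[sim$truth$read_id == merged$id[i]]
    expect_equal(merged$sequence[i], unname(region_of[strain]))
  }
})

test_that("a community species without a reference errors by name", {
  w <- small_world()
  comm <- simulate_community(c(w$spec$species[1], "Ghostus ghostus"),
                             "uniform", seed = 19)
  expect_error(simulate_amplicons(w$refs, comm, n_reads = 10, seed = 20),
               "Ghostus ghostus")
})

test_that("spec validation rejects incompatible divergences", {
  expect_error(synthetic_spec(group_divergence = 0.02), "below 1%")
  expect_error(synthetic_spec(group_divergence = 0.009, min_separation = 0.005),
               "below the separation")
  expect_error(synthetic_spec(region_core_length = 4), "too short")
  expect_error(synthetic_spec(planted_groups = list(
    c("Genus01 species01", "Genus02 species01"))), "share a genus")
  expect_error(synthetic_spec(planted_groups = list(
    c("Genus01 species01", "Genus01 species02"),
    c("Genus01 species02", "Genus01 species03"))), "disjoint")
})
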