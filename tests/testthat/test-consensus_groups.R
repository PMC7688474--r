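test_that("needleman_wunsch matches the frozen needle-style values", {
  r <- needleman_wunsch("AAAA", "AAAA")
  expect_equal(r$score, 20)
  expect_equal(r$identity_pct, 100)
  # with free end gaps the optimal AAAT/AAAA alignment is the one-base
  # shift (-AAAT / AAAA-): 3 matches, score 15, identity 3/5
  # (oracle-verified; a no-gap hand DP would give 11/75)
  r <- needleman_wunsch("AAAT", "AAAA")
  expect_equal(r$score, 15)
  expect_equal(r$identity_pct, 60)
  # terminal gap free, identity counted over the full alignment length
  r <- needleman_wunsch("AAAA", "AAA")
  expect_equal(r$score, 15)
  expect_equal(r$identity_pct, 75)
  expect_equal(r$alignment_length, 4L)
})

test_that("needleman_wunsch is symmetric and self-identity is 100", {
  withr::local_seed(14)
  for (k in 1:20) {
    a <- random_seq(sample(5:40, 1), c("A", "C", "G", "T", "N"))
    b <- random_seq(sample(5:40, 1), c("A", "C", "G", "T", "N"))
    ab <- needleman_wunsch(a, b); ba <- needleman_wunsch(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity_pct, ba$identity_pct)
    if (!grepl("N", a)) {
      expect_equal(needleman_wunsch(a, a)$identity_pct, 100)
    }
  }
})

test_that("aligner agrees with the independent 3-state DP oracle", {
  withr::local_seed(17)
  for (k in 1:60) {
    a <- random_seq(sample(1:40, 1), c("A", "C", "G", "T", "N"))
    b <- random_seq(sample(1:40, 1), c("A", "C", "G", "T", "N"))
    o <- oracle_nw(a, b)
    r <- needleman_wunsch(a, b)
    expect_equal(r$score, o$score)
    expect_equal(r$identity_pct, o$identity_pct)
  }
})

test_that("star_msa centers on the longest sequence and merges gaps", {
  expect_equal(unname(star_msa(c(a = "ACGT", b = "ACGT", c = "ACGT"))),
               c("ACGT", "ACGT", "ACGT"))
  msa <- star_msa(c(a = "ACGT", b = "ACT"))
  expect_equal(msa[["a"]], "ACGT")
  expect_equal(nchar(msa[["b"]]), 4L)
  expect_equal(gsub("-", "", msa[["b"]]), "ACT")
  expect_equal(star_msa(c(x = "ACGT")), c(x = "ACGT"))
})

test_that("consensus applies plurality, ties and the N rule per column", {
  expect_equal(consensus(c("A", "A", "T")), "A")          # 2/3 >= 1.5/3
  expect_equal(consensus(c("A", "T")), "A")               # tie -> lexicographic
  expect_equal(consensus(c("A", "C", "G", "T")), "N")     # max count 1 < 2
  expect_equal(consensus(c("AC-G", "AC-G", "AT-G")), "ACG")  # all-gap col removed
  # sub-plurality column with gaps: count measured against all rows
  expect_equal(consensus(c("A", "-", "-", "-")), "N")
})

test_that("build_species_consensus deduplicates and takes the majority", {
  frags <- data.frame(
    species = c(rep("Aus bus", 3), rep("Aus cus", 3)),
    genus = "Aus",
    sequence = c(rep("ACGTACGTAA", 3),
                 "ACGTACGTAA", "ACGTACGTAA", "ACTTACGTAA"),
    stringsAsFactors = FALSE)
  db <- build_species_consensus(frags)
  expect_equal(nrow(db), 2L)
  expect_equal(db$n_strains[db$species == "Aus bus"], 1L)  # identical strains dedup
  expect_equal(db$consensus_seq[db$species == "Aus bus"], "ACGTACGTAA")
  # 2-vs-1 column: the majority base wins (all members vote, dedup only
  # affects n_strains)
  expect_equal(db$consensus_seq[db$species == "Aus cus"], "ACGTACGTAA")
  expect_equal(db$n_strains[db$species == "Aus cus"], 2L)
})

test_that("similarity_graph applies the threshold and the genus scope", {
  withr::local_seed(19)
  s <- random_seq(100)
  db <- data.frame(species = c("Aus bus", "Aus cus", "Bus dus"),
                   genus = c("Aus", "Aus", "Bus"),
                   consensus_seq = c(s, s, s), stringsAsFactors = FALSE)
  edges <- similarity_graph(db)
  expect_equal(nrow(edges), 1L)  # identical cross-genus pair excluded
  expect_equal(sort(c(edges$species1, edges$species2)), c("Aus bus", "Aus cus"))
  edges <- similarity_graph(db, scope = "all")
  expect_equal(nrow(edges), 3L)
  # 98/100 identity: below the threshold
  db$consensus_seq[2] <- mutate_n(s, 2)
  expect_equal(nrow(similarity_graph(db[1:2, ])), 0L)
  # 99/100: at the threshold (inclusive)
  db$consensus_seq[2] <- mutate_n(s, 1)
  expect_equal(nrow(similarity_graph(db[1:2, ])), 1L)
})

test_that("build_groups matches the transitive-closure oracle", {
  species <- LETTERS[1:4]
  edges <- data.frame(species1 = c("A", "B"), species2 = c("B", "C"),
                      stringsAsFactors = FALSE)
  expect_equal(build_groups(species, edges), list(c("A", "B", "C"), "D"))
  no_edges <- data.frame(species1 = character(0), species2 = character(0))
  expect_equal(build_groups(species, no_edges), as.list(species))
  withr::local_seed(23)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    sp <- sprintf("sp%02d", seq_len(n))
    m <- sample(0:(n * 2), 1)
    edges <- data.frame(species1 = sample(sp, m, replace = TRUE),
                        species2 = sample(sp, m, replace = TRUE),
                        stringsAsFactors = FALSE)
    got <- build_groups(sp, edges)
    expect_equal(got, oracle_components(sp, edges))
    # partition property
    expect_setequal(unlist(got), sp)
    expect_equal(sum(lengths(got)), n)
  }
})

test_that("name_group follows the max-strain '+' rule", {
  counts <- c(X = 10L, Y = 3L, Z = 1L)
  expect_equal(name_group(c("X", "Y", "Z"), counts), "X+")
  expect_equal(name_group("Q", c(Q = 5L)), "Q")
  expect_equal(name_group(c("Y", "X"), c(X = 5L, Y = 5L)), "X+")  # tie: lexicographic
  expect_error(name_group(c("X", "W"), counts), "missing strain count")
})

test_that("raising the threshold never decreases the number of groups", {
  w <- small_world()
  n_prev <- 0L
  for (thr in c(95, 97, 99, 99.9)) {
    gt <- build_group_table(w$db, threshold = thr)
    expect_gte(length(gt$groups), n_prev)
    n_prev <- length(gt$groups)
  }
})

test_that("edge-list export round trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  edges <- data.frame(species1 = "Aus bus", species2 = "Aus cus",
                      identity = 99.5, stringsAsFactors = FALSE)
  export_group_graph(edges, path)
  expect_equal(read_group_graph(path), edges)
  empty <- edges[0, ]
  export_group_graph(empty, path)
  expect_equal(nrow(read_group_graph(path)), 0L)
  expect_equal(readLines(path), "species1\tspecies2\tidentity")  # header only
})

test_that("consensus FASTA round trips the species metadata", {
  w <- small_world()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_consensus_fasta(w$db, path)
  back <- read_consensus_fasta(path)
  expect_equal(as.data.frame(back), as.data.frame(w$db), ignore_attr = TRUE)
})
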