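# Generator for everything the pipeline consumes: toy taxonomies,
# reference sets with planted homologous groups, rank-abundance
# communities and error-bearing amplicon reads -- all deterministic under
# a seed, with complete ground truth.

#' Specification of a synthetic reference world
#'
#' The defaults describe the stated desk-scale world: 10 genera x 5
#' species x 3 strains, species cores of 400 nt flanked by the V3-V4
#' primer sites, two planted homologous groups whose members diverge from
#' their group leader by 0.5% (< 1%), all other species pairs separated
#' by > 2% (enforced by disjoint per-species mutation blocks on a shared
#' per-genus backbone), and 0.2% within-species strain divergence.
#'
#' @param n_genera,species_per_genus,strains_per_species world size.
#' @param within_species_divergence expected per-base strain divergence.
#' @param group_divergence substitutions from the group leader as a
#'   fraction of core length (must stay below 0.01).
#' @param min_separation guaranteed minimum divergence between species
#'   not sharing a planted group (> 0.02 required downstream).
#' @param region_core_length length of the species core between primers.
#' @param pad_length conserved pad length outside the primer sites.
#' @param planted_groups list of character vectors of species names;
#'   members of one group must share a genus and groups must be disjoint.
#' @param primer_pair a [primer_pair()] whose sites flank the core.
#' @param include_escherichia_shigella also plant *Escherichia* /
#'   *Shigella* nodes in the toy taxonomy (to exercise the merge rule).
#' @param seed integer seed; every generator below derives determinism
#'   from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genera = 10L, species_per_genus = 5L,
                           strains_per_species = 3L,
                           within_species_divergence = 0.002,
                           group_divergence = 0.005,
                           min_separation = 0.02,
                           region_core_length = 400L,
                           pad_length = 60L,
                           planted_groups = NULL,
                           primer_pair = v3v4_primer_pair(),
                           include_escherichia_shigella = FALSE,
                           seed = 1L) {
  stopifnot(within_species_divergence >= 0, within_species_divergence < 1,
            group_divergence >= 0, min_separation > 0)
  if (group_divergence >= 0.01) {
    stopf("planted within-group divergence must stay below 1%%")
  }
  if (group_divergence >= min_separation) {
    stopf("planted divergence (%.3f) must be below the separation (%.3f)",
          group_divergence, min_separation)
  }
  species <- outer(seq_len(n_genera), seq_len(species_per_genus),
                   function(g, s) sprintf("Genus%02d species%02d", g, s))
  species <- sort(as.vector(species))
  if (is.null(planted_groups)) {
    planted_groups <- list(
      c("Genus01 species01", "Genus01 species02"),
      c("Genus02 species01", "Genus02 species02", "Genus02 species03"))
    planted_groups <- lapply(planted_groups, intersect, x = species)
    planted_groups <- planted_groups[lengths(planted_groups) >= 2L]
  }
  members <- unlist(planted_groups)
  if (anyDuplicated(members)) stopf("planted groups must be disjoint")
  if (!all(members %in% species)) stopf("planted group member outside the species set")
  for (grp in planted_groups) {
    if (length(unique(sub(" .*$", "", grp))) != 1L) {
      stopf("planted group members must share a genus")
    }
  }
  block <- as.integer(ceiling(region_core_length * min_separation))
  if (species_per_genus * block > region_core_length) {
    stopf("region core too short for %d disjoint mutation blocks of %d nt",
          species_per_genus, block)
  }
  structure(list(
    n_genera = as.integer(n_genera),
    species_per_genus = as.integer(species_per_genus),
    strains_per_species = as.integer(strains_per_species),
    within_species_divergence = within_species_divergence,
    group_divergence = group_divergence,
    min_separation = min_separation,
    region_core_length = as.integer(region_core_length),
    pad_length = as.integer(pad_length),
    planted_groups = planted_groups,
    primer_pair = primer_pair,
    include_escherichia_shigella = include_escherichia_shigella,
    seed = as.integer(seed),
    species = species,
    block_size = block), class = "synthetic_spec")
}

#' Write a toy taxdump + lineage table for a synthetic world
#'
#' Emits `nodes.dmp`, `names.dmp` (taxdump dialect) and `lineage.tsv`
#' (one row per strain, with a strain-suffixed `raw_species_label` to
#' exercise binomial normalisation) into `dir`. The tree has a single
#' root/superkingdom/phylum/class/order path, one family per genus, and
#' one node per genus and species.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named file paths.
#' @export
simulate_taxonomy <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- list()  # taxid, parent, rank
  names_ <- list() # taxid, name
  add <- function(taxid, parent, rank, name) {
    nodes[[length(nodes) + 1L]] <<- c(taxid, parent, rank)
    names_[[length(names_) + 1L]] <<- c(taxid, name)
    as.integer(taxid)
  }
  root <- add(1L, 1L, "no rank", "root")
  sk <- add(2L, root, "superkingdom", "Bacteria")
  ph <- add(3L, sk, "phylum", "Phylum01")
  cl <- add(4L, ph, "class", "Class01")
  od <- add(5L, cl, "order", "Order01")
  nxt <- 6L
  genus_taxid <- integer(0)
  for (g in seq_len(spec$n_genera)) {
    fam <- add(nxt, od, "family", sprintf("Family%02d", g)); nxt <- nxt + 1L
    gen <- add(nxt, fam, "genus", sprintf("Genus%02d", g)); nxt <- nxt + 1L
    genus_taxid[sprintf("Genus%02d", g)] <- gen
    for (s in seq_len(spec$species_per_genus)) {
      add(nxt, gen, "species", sprintf("Genus%02d species%02d", g, s))
      nxt <- nxt + 1L
    }
  }
  if (spec$include_escherichia_shigella) {
    fam <- add(nxt, od, "family", "Enterobacteriaceae"); nxt <- nxt + 1L
    eg <- add(nxt, fam, "genus", "Escherichia"); nxt <- nxt + 1L
    add(nxt, eg, "species", "Escherichia coli"); nxt <- nxt + 1L
    sg <- add(nxt, fam, "genus", "Shigella"); nxt <- nxt + 1L
    add(nxt, sg, "species", "Shigella flexneri"); nxt <- nxt + 1L
  }
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(vapply(nodes, function(x)
    sprintf("%s\t|\t%s\t|\t%s\t|", x[1], x[2], x[3]), ""), nodes_path)
  writeLines(vapply(names_, function(x)
    sprintf("%s\t|\t%s\t|\t\t|\tscientific name\t|", x[1], x[2]), ""), names_path)

  lineage <- do.call(rbind, lapply(spec$species, function(sp) {
    genus <- sub(" .*$", "", sp)
    g <- as.integer(sub("Genus", "", genus))
    data.frame(
      id = sprintf("%s_t%d", gsub(" ", "_", sp), seq_len(spec$strains_per_species)),
      superkingdom = "Bacteria", phylum = "Phylum01", class = "Class01",
      order = "Order01", family = sprintf("Family%02d", g), genus = genus,
      species = sp,
      raw_species_label = sprintf("%s strain t%d", sp,
                                  seq_len(spec$strains_per_species)),
      stringsAsFactors = FALSE)
  }))
  lineage_path <- file.path(dir, "lineage.tsv")
  write_lineage_tsv(lineage, lineage_path)
  invisible(c(nodes = nodes_path, names = names_path, lineage = lineage_path))
}

# instantiate degenerate primer positions with concrete bases
instantiate_primer <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(c) sample(IUPAC_EXPANSION[[c]], 1L), ""),
        collapse = "")
}

#' Simulate full-length 16S-like reference sequences
#'
#' Per strain: `pad + forward-primer site + species core + reverse-primer
#' site (reverse complement) + pad`, degenerate primer positions
#' instantiated at random per record. Species cores sit on a shared
#' per-genus backbone mutated at disjoint per-species blocks (so
#' non-group species pairs differ by at least `2 * block / L` > 2%);
#' planted-group members instead derive from their group leader's core at
#' `group_divergence` substitutions. Strains mutate their species core at
#' `Binomial(L, within_species_divergence)` positions.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (data.frame: `id`, `sequence`, `species`,
#'   `genus`) and `cores` (named character: species -> core sequence).
#' @export
simulate_references <- function(spec) {
  withr::with_seed(spec$seed, {
    L <- spec$region_core_length
    B <- spec$block_size
    leaders <- vapply(spec$planted_groups, `[[`, "", 1L)
    follower_of <- list()
    for (grp in spec$planted_groups) {
      for (m in grp[-1]) follower_of[[m]] <- grp[1]
    }
    cores <- setNames(character(length(spec$species)), spec$species)
    for (g in seq_len(spec$n_genera)) {
      backbone <- random_dna(L)
      for (s in seq_len(spec$species_per_genus)) {
        sp <- sprintf("Genus%02d species%02d", g, s)
        if (!is.null(follower_of[[sp]])) next
        block_pos <- ((s - 1L) * B + 1L):(s * B)
        cores[sp] <- mutate_positions(backbone, block_pos)
      }
      for (s in seq_len(spec$species_per_genus)) {
        sp <- sprintf("Genus%02d species%02d", g, s)
        leader <- follower_of[[sp]]
        if (is.null(leader)) next
        n_sub <- max(1L, round(spec$group_divergence * L))
        cores[sp] <- mutate_positions(cores[leader], sample.int(L, n_sub))
      }
    }
    pad5 <- random_dna(spec$pad_length)
    pad3 <- random_dna(spec$pad_length)
    rows <- list()
    for (sp in spec$species) {
      for (t in seq_len(spec$strains_per_species)) {
        n_mut <- rbinom(1L, L, spec$within_species_divergence)
        strain_core <- if (n_mut > 0) {
          mutate_positions(cores[[sp]], sample.int(L, n_mut))
        } else cores[[sp]]
        seq <- paste0(pad5, instantiate_primer(spec$primer_pair$forward),
                      strain_core,
                      revcomp(instantiate_primer(spec$primer_pair$reverse)),
                      pad3)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_t%d", gsub(" ", "_", sp), t),
          sequence = seq, species = sp, genus = sub(" .*$", "", sp),
          stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, rows), cores = cores)
  })
}

#' Simulate a community under a rank-abundance model
#'
#' `uniform`: equal abundances. `linear`: abundance proportional to
#' `S - i + 1` over a seeded random species order (so species identity
#' and abundance rank are independent across replicates). `powerlaw`:
#' abundance proportional to `i^(-p)` over the same seeded order. 16S
#' copy numbers are drawn uniformly from `copy_number_range`.
#'
#' @param species character vector of community species.
#' @param model `"uniform"`, `"linear"` or `"powerlaw"`.
#' @param p power-law exponent (> 0; ignored otherwise).
#' @param copy_number_range integer range of per-species 16S copy number.
#' @param seed integer seed.
#' @return a `community_profile` data.frame: `species`, `abundance`
#'   (sums to 1), `copy_number`.
#' @export
simulate_community <- function(species, model = c("uniform", "linear", "powerlaw"),
                               p = 1, copy_number_range = c(1L, 10L),
                               seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(species) >= 1L)
  if (model == "powerlaw" && p <= 0) stopf("power-law exponent must be positive")
  S <- length(species)
  withr::with_seed(seed, {
    ord <- sample(species)
    weights <- switch(model,
      uniform = rep(1, S),
      linear = S - seq_len(S) + 1,
      powerlaw = seq_len(S)^(-p))
    abundance <- setNames(weights / sum(weights), ord)[species]
    copy_number <- sample(seq(copy_number_range[1], copy_number_range[2]),
                          S, replace = TRUE)
  })
  out <- data.frame(species = species, abundance = unname(abundance),
                    copy_number = copy_number, stringsAsFactors = FALSE)
  class(out) <- c("community_profile", "data.frame")
  out
}

#' Simulate amplicon reads with ground truth
#'
#' Extracts the hypervariable region from every strain of every community
#' species (an extraction failure is an error naming the species, never a
#' silent drop), draws read counts proportional to
#' `abundance * copy_number` (copy-number bias can be disabled), and
#' emits each read as an extracted region with i.i.d. substitutions at
#' `error_rate` (the uniform 0.5% error model; no indels). In paired
#' mode each template yields two overlapping reads of `read_length` nt
#' (overlap must reach at least 20 nt). Qualities are constant Q40.
#'
#' @param refs a [simulate_references()] result (or any record data.frame
#'   with `id`, `sequence`, `species`).
#' @param community a [simulate_community()] profile.
#' @param error_rate per-base substitution rate (default 0.005).
#' @param coverage_fold sets the default total read count,
#'   `coverage_fold * nrow(community)`.
#' @param n_reads explicit total read count (overrides `coverage_fold`).
#' @param copy_number_bias weight species by 16S copy number.
#' @param paired emit overlapping read pairs instead of single reads.
#' @param read_length paired-mode read length.
#' @param primer_pair a [primer_pair()] for region extraction.
#' @param seed integer seed.
#' @return list with `reads` (data.frame `id`, `sequence`, `quality`; in
#'   paired mode `forward` and `reverse` data.frames instead) and `truth`
#'   (data.frame `read_id`, `species`, `strain`).
#' @export
simulate_amplicons <- function(refs, community, error_rate = 0.005,
                               coverage_fold = 1000L, n_reads = NULL,
                               copy_number_bias = TRUE, paired = FALSE,
                               read_length = 250L,
                               primer_pair = v3v4_primer_pair(), seed = 1L) {
  records <- if (is.data.frame(refs)) refs else refs$records
  stopifnot(all(c("id", "sequence", "species") %in% names(records)))
  regions <- list()
  for (sp in community$species) {
    strains <- records[records$species == sp, , drop = FALSE]
    if (nrow(strains) == 0L) stopf("no reference for community species %s", sp)
    ext <- lapply(strains$sequence, extract_region, pair = primer_pair)
    ok <- !vapply(ext, is.null, TRUE)
    if (!any(ok)) {
      stopf("region extraction failed for species %s (primer mismatch)", sp)
    }
    regions[[sp]] <- setNames(
      vapply(ext[ok], `[[`, "", "sequence"), strains$id[ok])
  }
  n_reads <- n_reads %||% (coverage_fold * nrow(community))
  weights <- community$abundance *
    (if (copy_number_bias) community$copy_number else 1)
  weights <- weights / sum(weights)

  withr::with_seed(seed, {
    counts <- as.vector(rmultinom(1L, n_reads, weights))
    ids <- character(n_reads); seqs <- character(n_reads)
    truth_sp <- character(n_reads); truth_strain <- character(n_reads)
    r <- 0L
    for (k in seq_along(community$species)) {
      sp <- community$species[k]
      pool <- regions[[sp]]
      for (dup in seq_len(counts[k])) {
        r <- r + 1L
        si <- sample.int(length(pool), 1L)
        template <- pool[[si]]
        Lr <- nchar(template)
        n_err <- rbinom(1L, Lr, error_rate)
        read <- if (n_err > 0) {
          mutate_positions(template, sample.int(Lr, n_err))
        } else template
        ids[r] <- sprintf("read%06d", r)
        seqs[r] <- read
        truth_sp[r] <- sp
        truth_strain[r] <- names(pool)[si]
      }
    }
    # seeded shuffle so samples are not blocked by species
    ord <- sample.int(n_reads)
  })
  ids <- ids[ord]; seqs <- seqs[ord]
  truth <- data.frame(read_id = ids, species = truth_sp[ord],
                      strain = truth_strain[ord], stringsAsFactors = FALSE)
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  if (!paired) {
    reads <- data.frame(id = ids, sequence = seqs, quality = qual,
                        stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth))
  }
  lens <- nchar(seqs)
  overlap <- 2L * read_length - lens
  if (any(lens > read_length & overlap < 20L)) {
    stopf("paired mode: read_length %d gives overlap < 20 for a %d nt region",
          read_length, max(lens))
  }
  fwd_seq <- substr(seqs, 1L, pmin(read_length, lens))
  rev_seq <- revcomp(substr(seqs, pmax(1L, lens - read_length + 1L), lens))
  forward <- data.frame(id = paste0(ids, "/1"), sequence = fwd_seq,
                        quality = vapply(nchar(fwd_seq), strrep, "", x = "I"),
                        stringsAsFactors = FALSE)
  reverse <- data.frame(id = paste0(ids, "/2"), sequence = rev_seq,
                        quality = vapply(nchar(rev_seq), strrep, "", x = "I"),
                        stringsAsFactors = FALSE)
  list(forward = forward, reverse = reverse, truth = truth)
}
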