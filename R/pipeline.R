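# End-to-end profiling: merge -> filter -> cluster -> classify (genus)
# -> assign (species/group) -> composition profiles.

#' Pipeline configuration
#'
#' Collects every tunable threshold with its default: OTU identity 0.99,
#' species identity gate 97 percent (strict), homologous-group threshold
#' 99 percent, genus bootstrap-confidence threshold 0.8, the FLASH-style
#' merge policy, and the region length statistics (V3-V4: mean 421,
#' sd 11) used by the merged-read filter.
#'
#' @param primer_pair a [primer_pair()].
#' @param otu_threshold OTU clustering identity (fraction).
#' @param species_min_identity species identity gate (percent, strict).
#' @param group_threshold homologous-group identity threshold (percent).
#' @param confidence_threshold genus bootstrap-confidence threshold.
#' @param merge_policy a [merge_policy()].
#' @param region_stats `c(mean = , sd = )` of the region length.
#' @param max_evalue,use_evalue e-value gate for species assignment.
#' @param n_bootstrap bootstrap trials for the genus classifier.
#' @param seed integer seed for every stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(primer_pair = v3v4_primer_pair(),
                            otu_threshold = 0.99,
                            species_min_identity = 97,
                            group_threshold = 99,
                            confidence_threshold = 0.8,
                            merge_policy = hsg16S::merge_policy(),
                            region_stats = c(mean = 421, sd = 11),
                            max_evalue = 1e-10, use_evalue = TRUE,
                            n_bootstrap = 100L, seed = 1L) {
  stopifnot(otu_threshold > 0, otu_threshold <= 1,
            species_min_identity > 0, species_min_identity <= 100,
            group_threshold > 0, group_threshold <= 100,
            confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(primer_pair = primer_pair, otu_threshold = otu_threshold,
                 species_min_identity = species_min_identity,
                 group_threshold = group_threshold,
                 confidence_threshold = confidence_threshold,
                 merge_policy = merge_policy, region_stats = region_stats,
                 max_evalue = max_evalue, use_evalue = use_evalue,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reference bundle for profiling
#'
#' @param model an [train_classifier()] model.
#' @param consensus_db a [build_species_consensus()] table.
#' @param group_table a group table (`group_name`, `member`).
#' @return an object of class `reference_bundle`.
#' @export
reference_bundle <- function(model, consensus_db, group_table) {
  if (is.null(model) || !inherits(model, "nb_classifier")) {
    stopf("bundle is missing a classifier model")
  }
  if (is.null(consensus_db) || nrow(consensus_db) == 0L) {
    stopf("bundle is missing the species consensus database")
  }
  if (is.null(group_table) || !all(c("group_name", "member") %in% names(group_table))) {
    stopf("bundle is missing the homologous-group table")
  }
  structure(list(model = model, consensus_db = consensus_db,
                 group_table = group_table), class = "reference_bundle")
}

#' Per-sample relative abundance from OTU labels
#'
#' `abundance(t)` = reads of OTUs labelled `t` / reads in the sample;
#' unlabelled OTUs are pooled into an explicit `"unclassified"` bin so
#' every read stays accounted for. Columns each sum to 1.
#'
#' @param otu_table OTU x sample count matrix ([build_otu_table()]).
#' @param labels character vector of per-OTU labels, named by `otu_id`
#'   (`NA` or `"unclassified"` pools into the unclassified bin).
#' @return matrix label x sample of relative abundances.
#' @export
relative_abundance <- function(otu_table, labels) {
  lab <- labels[rownames(otu_table)]
  lab[is.na(lab)] <- "unclassified"
  out <- rowsum(otu_table, group = lab)
  totals <- colSums(out)
  totals[totals == 0] <- 1  # an empty sample profiles as all-zero
  sweep(out, 2L, totals, `/`)
}

#' Run the full profiling pipeline
#'
#' For each sample: merge read pairs, apply the merged-read filter; then
#' pool all samples, cluster into OTUs, classify each representative at
#' the genus level (naive Bayes + bootstrap, confidence-thresholded) and
#' at the species level (nearest consensus, homologous-group labels);
#' finally derive per-sample composition profiles at the genus and
#' species/group rank. Per-stage read counts are logged and returned so
#' conservation can be audited.
#'
#' @param samples named list; each element is a list with `forward` and
#'   `reverse`, either FASTQ paths or FASTQ record data.frames.
#' @param bundle a [reference_bundle()].
#' @param config a [pipeline_config()].
#' @return list with `otu_table`, `otus`, `assignments` (per-OTU genus +
#'   species calls), `profiles` (list: `genus`, `species` abundance
#'   matrices), and `stage_counts`.
#' @export
run_profile <- function(samples, bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "reference_bundle"),
            length(samples) > 0, !is.null(names(samples)))
  merged_all <- list()
  sample_of <- character(0)
  counts <- data.frame(sample = names(samples), input = 0L, merged = 0L,
                       kept = 0L, stringsAsFactors = FALSE)
  for (s in names(samples)) {
    fwd <- samples[[s]]$forward
    rev <- samples[[s]]$reverse
    if (is.character(fwd)) fwd <- read_fastq(fwd)
    if (is.character(rev)) rev <- read_fastq(rev)
    merged <- merge_pairs(fwd, rev, config$merge_policy)
    kept <- merged_qc(merged, config$region_stats)
    if (nrow(kept) > 0L) kept$id <- paste0(s, ":", kept$id)
    i <- match(s, counts$sample)
    counts$input[i] <- nrow(fwd)
    counts$merged[i] <- nrow(merged)
    counts$kept[i] <- nrow(kept)
    message(sprintf("[%s] %d pairs -> %d merged -> %d after QC",
                    s, nrow(fwd), nrow(merged), nrow(kept)))
    merged_all[[s]] <- kept
    sample_of <- c(sample_of, setNames(rep(s, nrow(kept)), kept$id))
  }
  pool <- do.call(rbind, merged_all)
  if (is.null(pool) || nrow(pool) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, names(samples)))
    uncl <- matrix(1, nrow = 1, ncol = length(samples),
                   dimnames = list("unclassified", names(samples)))
    return(list(otu_table = empty, otus = NULL, assignments = NULL,
                profiles = list(genus = uncl, species = uncl),
                stage_counts = counts))
  }
  otus <- greedy_cluster(setNames(pool$sequence, pool$id),
                         threshold = config$otu_threshold)
  otu_table <- build_otu_table(otus, sample_of)
  message(sprintf("clustered %d reads into %d OTUs", nrow(pool), nrow(otus)))

  genus_labels <- character(nrow(otus))
  genus_conf <- numeric(nrow(otus))
  for (i in seq_len(nrow(otus))) {
    a <- classify(bundle$model, otus$representative[i],
                  n_bootstrap = config$n_bootstrap,
                  seed = config$seed + i)
    a <- apply_confidence_threshold(a, config$confidence_threshold)
    g <- a$label[a$rank == "genus"]
    genus_labels[i] <- if (is.na(g)) "unclassified" else g
    conf <- a$confidence[a$rank == "genus"]
    genus_conf[i] <- if (is.na(conf)) 0 else conf
  }
  species_calls <- assign_all(otus, bundle$consensus_db, bundle$group_table,
                              min_identity = config$species_min_identity,
                              max_evalue = config$max_evalue,
                              use_evalue = config$use_evalue)
  assignments <- data.frame(otu_id = otus$otu_id, size = otus$size,
                            genus = genus_labels,
                            genus_confidence = genus_conf,
                            species = species_calls$label,
                            best_identity = species_calls$best_identity,
                            n_tied_best = species_calls$n_tied_best,
                            evalue = species_calls$evalue,
                            stringsAsFactors = FALSE)
  profiles <- list(
    genus = relative_abundance(otu_table,
                               setNames(genus_labels, otus$otu_id)),
    species = relative_abundance(otu_table,
                                 setNames(species_calls$label, otus$otu_id)))
  list(otu_table = otu_table, otus = otus, assignments = assignments,
       profiles = profiles, stage_counts = counts)
}
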