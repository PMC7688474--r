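# Species-level assignment of OTU representatives: nearest neighbour
# (k = 1) against the species consensus database with identity and
# e-value gates, resolved to homologous-group labels.

#' Rescale an alignment to the +1/-2 score scheme
#'
#' `n_identical - 2 * n_other`, where `n_other` counts the non-identical
#' alignment columns. Feeds the e-value surrogate.
#'
#' @param n_identical identical alignment columns.
#' @param n_other non-identical alignment columns (mismatches and gaps).
#' @return rescaled score.
#' @export
rescale_score <- function(n_identical, n_other) {
  n_identical - 2 * n_other
}

#' Karlin-Altschul e-value surrogate
#'
#' `E = K * m * n * exp(-lambda * S')` with the query/database lengths
#' `m`, `n` and the +1/-2-rescaled score `S'`. The defaults
#' `(lambda, K) = (0.625, 0.41)` are the standard ungapped +1/-2 DNA
#' constants; the surrogate is monotone decreasing in the score and
#' linear in either length. It stands in for BLAST's database-size
#' statistics, which are not reproduced bit-exactly; the identity gate is
#' the primary filter.
#'
#' @param score rescaled alignment score (see [rescale_score()]).
#' @param query_len,db_len positive lengths.
#' @param lambda,K Karlin-Altschul constants.
#' @return the e-value.
#' @export
evalue_surrogate <- function(score, query_len, db_len,
                             lambda = 0.625, K = 0.41) {
  stopifnot(query_len > 0, db_len > 0)
  K * query_len * db_len * exp(-lambda * score)
}

#' Nearest-neighbour species call for one query
#'
#' The query is aligned against every consensus sequence with the
#' needle-style scorer (free end gaps; equal-length pairs use the
#' ungapped statistics, which coincide with the optimal alignment at the
#' identity regime the gates care about); candidates must exceed
#' `min_identity` percent identity (strict `>`) and fall below
#' `max_evalue`. The best candidate's species is the call; with no
#' candidate the query is `"unclassified"`. A called species belonging
#' to a multi-member homologous group is reported under the group label
#' (`"...+"`). Equal-best ties within one group resolve to the group
#' label; ties spanning groups resolve to the lexicographically smallest
#' group label, with the tie count recorded.
#'
#' @param query query sequence (an OTU representative).
#' @param consensus_db a [build_species_consensus()] table.
#' @param group_table group table (`group_name`, `member`) from
#'   [build_group_table()].
#' @param k neighbourhood size; only `k = 1` is supported.
#' @param min_identity identity gate, percent (default 97, strict).
#' @param max_evalue e-value gate (default 1e-10); `use_evalue = FALSE`
#'   disables it.
#' @param use_evalue logical.
#' @return list with `label`, `best_identity`, `n_tied_best`, `evalue`.
#' @export
knn_species <- function(query, consensus_db, group_table, k = 1L,
                        min_identity = 97, max_evalue = 1e-10,
                        use_evalue = TRUE) {
  stopifnot(nrow(consensus_db) > 0)
  if (k != 1L) stopf("only k = 1 is supported")
  db_len <- sum(nchar(consensus_db$consensus_seq))
  m <- nchar(query)
  stats <- batch_align_stats_cpp(toupper(query), consensus_db$consensus_seq,
                                 5, -4, 10, 0.5)
  identity <- 100 * stats[1, ] / stats[2, ]
  evalue <- evalue_surrogate(rescale_score(stats[1, ], stats[2, ] - stats[1, ]),
                             m, db_len)
  candidate <- identity > min_identity + 1e-9
  if (use_evalue) candidate <- candidate & evalue < max_evalue
  if (!any(candidate)) {
    return(list(label = "unclassified", best_identity = max(identity),
                n_tied_best = 0L, evalue = evalue[which.max(identity)]))
  }
  best <- max(identity[candidate])
  tied <- which(candidate & identity > best - 1e-9)
  tied_species <- consensus_db$species[tied]
  gidx <- match(tied_species, group_table$member)
  labels <- ifelse(is.na(gidx), tied_species, group_table$group_name[gidx])
  label <- sort(unique(labels))[1]  # cross-group ties: lexicographic
  list(label = label, best_identity = best,
       n_tied_best = length(tied), evalue = min(evalue[tied]))
}

#' Assign species labels to all OTU representatives
#'
#' @param otus an [greedy_cluster()] result (or any data.frame with
#'   `otu_id` and `representative`).
#' @param consensus_db,group_table,min_identity,max_evalue,use_evalue
#'   passed to [knn_species()].
#' @return data.frame of species calls (`otu_id`, `label`,
#'   `best_identity`, `n_tied_best`, `evalue`); a summary of specific /
#'   group / unclassified counts is attached and logged.
#' @export
assign_all <- function(otus, consensus_db, group_table,
                       min_identity = 97, max_evalue = 1e-10,
                       use_evalue = TRUE) {
  calls <- lapply(otus$representative, knn_species,
                  consensus_db = consensus_db, group_table = group_table,
                  min_identity = min_identity, max_evalue = max_evalue,
                  use_evalue = use_evalue)
  out <- data.frame(
    otu_id = otus$otu_id,
    label = vapply(calls, `[[`, "", "label"),
    best_identity = vapply(calls, `[[`, 0, "best_identity"),
    n_tied_best = vapply(calls, function(x) as.integer(x$n_tied_best), 0L),
    evalue = vapply(calls, `[[`, 0, "evalue"),
    stringsAsFactors = FALSE)
  summary <- c(
    specific = sum(out$label != "unclassified" & !endsWith(out$label, "+")),
    group = sum(endsWith(out$label, "+")),
    unclassified = sum(out$label == "unclassified"))
  attr(out, "summary") <- summary
  message(sprintf("assign_all: %d specific, %d group, %d unclassified",
                  summary[["specific"]], summary[["group"]],
                  summary[["unclassified"]]))
  out
}
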