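# RDP-style naive Bayesian 8-mer classifier for genus-level assignment
# with bootstrap confidence.

#' Distinct overlapping words of a sequence
#'
#' All distinct overlapping `w`-mers containing only A/C/G/T (windows with
#' ambiguous bases are skipped); presence semantics, no counts.
#'
#' @param seq nucleotide sequence, length at least `w`.
#' @param w word size (default 8).
#' @return character vector (a set) of words.
#' @export
extract_words <- function(seq, w = 8L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < w) stopf("sequence shorter than word size %d", w)
  words <- substring(seq, 1:(n - w + 1L), w:n)
  unique(words[grepl("^[ACGT]+$", words)])
}

#' Train the naive Bayesian genus classifier
#'
#' Word priors follow the RDP formulation: with `N` training sequences
#' and `n(w)` of them containing word `w`,
#' `P(w) = (n(w) + 0.5) / (N + 1)`; for a genus `G` of `M` sequences of
#' which `m(w)` contain `w`, `P(w | G) = (m(w) + P(w)) / (M + 1)`.
#'
#' @param records data.frame with columns `sequence`, `genus`, and
#'   optionally the remaining [TAX_RANKS] columns (used for rank-level
#'   bootstrap confidence; missing ranks stay unannotated).
#' @param word_size word size (default 8).
#' @return an object of class `nb_classifier`: word vocabulary, log
#'   conditionals (vocabulary x genera), per-genus counts and lineages.
#' @export
train_classifier <- function(records, word_size = 8L) {
  stopifnot(all(c("sequence", "genus") %in% names(records)))
  if (anyNA(records$genus) || any(!nzchar(records$genus))) {
    stopf("every training record needs a genus")
  }
  genera <- sort(unique(records$genus))
  word_sets <- lapply(records$sequence, extract_words, w = word_size)
  vocab <- sort(unique(unlist(word_sets)))
  N <- nrow(records)
  n_w <- integer(length(vocab))
  occ <- lapply(word_sets, match, table = vocab)
  for (o in occ) n_w[o] <- n_w[o] + 1L
  p_w <- (n_w + 0.5) / (N + 1)

  M <- vapply(genera, function(g) sum(records$genus == g), 0L)
  log_cond <- matrix(0, nrow = length(vocab), ncol = length(genera),
                     dimnames = list(NULL, genera))
  for (gi in seq_along(genera)) {
    m_w <- integer(length(vocab))
    for (o in occ[records$genus == genera[gi]]) m_w[o] <- m_w[o] + 1L
    log_cond[, gi] <- log((m_w + p_w) / (M[gi] + 1))
  }

  lineages <- matrix(NA_character_, nrow = length(genera),
                     ncol = length(TAX_RANKS),
                     dimnames = list(genera, TAX_RANKS))
  for (rank in intersect(TAX_RANKS, names(records))) {
    lineages[, rank] <- as.character(
      records[[rank]][match(genera, records$genus)])
  }
  lineages[, "genus"] <- genera
  lineages[, "species"] <- NA_character_  # species is not this classifier's job

  structure(list(word_size = as.integer(word_size), genera = genera,
                 vocab = vocab, word_prior = setNames(p_w, vocab),
                 log_cond = log_cond, n_word = setNames(n_w, vocab),
                 n_train = N, genus_counts = setNames(M, genera),
                 lineages = lineages, version = "hsg16S-nb/1"),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat(sprintf("<nb_classifier %s: %d genera, %d training seqs, %d words (w=%d)>\n",
              x$version, length(x$genera), x$n_train, length(x$vocab), x$word_size))
  invisible(x)
}

# per-word log P(w|G) matrix for a query word set; words unseen in
# training fall back to P(w) at n(w)=0, i.e. 0.5/(N+1), shared across genera
query_log_matrix <- function(model, words) {
  idx <- match(words, model$vocab)
  Q <- matrix(0, nrow = length(words), ncol = length(model$genera))
  known <- !is.na(idx)
  if (any(known)) Q[known, ] <- model$log_cond[idx[known], , drop = FALSE]
  if (any(!known)) {
    p0 <- 0.5 / (model$n_train + 1)
    Q[!known, ] <- matrix(log(p0 / (model$genus_counts + 1)),
                          nrow = sum(!known), ncol = length(model$genera),
                          byrow = TRUE)
  }
  colnames(Q) <- model$genera
  Q
}

#' Classify a sequence with bootstrap confidence
#'
#' The genus score is the sum of `log P(w | G)` over the query's word
#' set; the full-set argmax is the point assignment (ties break to the
#' lexicographically smallest genus). Each bootstrap trial draws
#' `floor(n_words * subsample_fraction)` words with replacement and
#' records its argmax; the confidence at each rank is the fraction of
#' trials whose argmax genus agrees with the point assignment's lineage
#' at that rank. Ranks above genus inherit from the genus lineage.
#'
#' @param model an [train_classifier()] model.
#' @param seq query sequence.
#' @param n_bootstrap number of bootstrap trials (default 100).
#' @param subsample_fraction fraction of words per trial (default 1/8).
#' @param seed optional integer seed for the bootstrap (deterministic
#'   classification given a seed).
#' @return an object of class `rank_assignment`: data.frame with columns
#'   `rank`, `label`, `confidence` (one row per canonical rank; species
#'   stays unannotated).
#' @export
classify <- function(model, seq, n_bootstrap = 100L,
                     subsample_fraction = 1 / 8, seed = NULL) {
  words <- tryCatch(extract_words(seq, model$word_size),
                    error = function(e) character(0))
  empty <- data.frame(rank = TAX_RANKS, label = NA_character_,
                      confidence = 0, stringsAsFactors = FALSE)
  class(empty) <- c("rank_assignment", "data.frame")
  if (length(words) == 0L) return(empty)

  Q <- query_log_matrix(model, words)
  point_scores <- colSums(Q)
  point_genus <- model$genera[which.max(point_scores)]  # genera sorted: ties lexicographic
  point_lineage <- model$lineages[point_genus, ]

  size <- max(1L, as.integer(floor(length(words) * subsample_fraction)))
  draw <- function() {
    idx <- sample.int(length(words), size, replace = TRUE)
    model$genera[which.max(colSums(Q[idx, , drop = FALSE]))]
  }
  trial_genera <- if (is.null(seed)) {
    vapply(seq_len(n_bootstrap), function(i) draw(), "")
  } else {
    withr::with_seed(seed, vapply(seq_len(n_bootstrap), function(i) draw(), ""))
  }
  trial_lineages <- model$lineages[trial_genera, , drop = FALSE]

  conf <- vapply(TAX_RANKS, function(rank) {
    ref <- point_lineage[[rank]]
    if (is.na(ref)) return(NA_real_)
    mean(!is.na(trial_lineages[, rank]) & trial_lineages[, rank] == ref)
  }, 0)
  out <- data.frame(rank = TAX_RANKS, label = unname(point_lineage),
                    confidence = unname(conf), stringsAsFactors = FALSE)
  class(out) <- c("rank_assignment", "data.frame")
  out
}

#' Truncate an assignment at a confidence threshold
#'
#' Reports the deepest prefix of ranks whose confidences all meet the
#' threshold; the first sub-threshold rank and everything below it are
#' cleared. The default 0.8 is the usual bootstrap-confidence convention
#' for short amplicons.
#'
#' @param assignment a [classify()] result.
#' @param threshold confidence threshold in `[0, 1]`.
#' @return the truncated `rank_assignment`.
#' @export
apply_confidence_threshold <- function(assignment, threshold = 0.8) {
  clear <- FALSE
  for (i in seq_len(nrow(assignment))) {
    conf <- assignment$confidence[i]
    if (!clear && !is.na(assignment$label[i]) &&
        (is.na(conf) || conf < threshold)) {
      clear <- TRUE
    }
    if (clear) assignment$label[i] <- NA_character_
  }
  assignment
}

#' Serialise / load a classifier model (plain text)
#'
#' A single portable, versioned TSV-sectioned text file: a header with
#' the scalar fields, a genus table (counts + lineages) and the word
#' table with per-genus log conditionals.
#'
#' @param model an `nb_classifier`.
#' @param path file path.
#' @rdname classifier_io
#' @export
write_classifier <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#%s", model$version),
               sprintf("#word_size\t%d", model$word_size),
               sprintf("#n_train\t%d", model$n_train),
               "#genera"), con)
  gtab <- data.frame(genus = model$genera,
                     count = unname(model$genus_counts),
                     model$lineages[, setdiff(TAX_RANKS, "species"), drop = FALSE],
                     stringsAsFactors = FALSE, row.names = NULL)
  write.table(gtab, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  writeLines("#words", con)
  wtab <- data.frame(word = model$vocab, n = unname(model$n_word),
                     stringsAsFactors = FALSE)
  wtab <- cbind(wtab, as.data.frame(model$log_cond))
  write.table(wtab, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname classifier_io
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  version <- sub("^#", "", lines[1])
  if (version != "hsg16S-nb/1") stopf("unsupported classifier format: %s", version)
  word_size <- as.integer(strsplit(lines[2], "\t")[[1]][2])
  n_train <- as.integer(strsplit(lines[3], "\t")[[1]][2])
  gstart <- which(lines == "#genera") + 1L
  wstart <- which(lines == "#words") + 1L
  gtab <- read.delim(text = lines[gstart:(wstart - 2L)],
                     stringsAsFactors = FALSE, na.strings = "")
  wtab <- read.delim(text = lines[wstart:length(lines)],
                     stringsAsFactors = FALSE, na.strings = "",
                     check.names = FALSE)
  genera <- gtab$genus
  lineages <- matrix(NA_character_, nrow = length(genera),
                     ncol = length(TAX_RANKS),
                     dimnames = list(genera, TAX_RANKS))
  for (rank in setdiff(TAX_RANKS, "species")) {
    lineages[, rank] <- as.character(gtab[[rank]])
  }
  vocab <- wtab$word
  log_cond <- as.matrix(wtab[, genera, drop = FALSE])
  rownames(log_cond) <- NULL
  n_w <- as.integer(wtab$n)
  p_w <- (n_w + 0.5) / (n_train + 1)
  structure(list(word_size = word_size, genera = genera, vocab = vocab,
                 word_prior = setNames(p_w, vocab), log_cond = log_cond,
                 n_word = setNames(n_w, vocab), n_train = n_train,
                 genus_counts = setNames(gtab$count, genera),
                 lineages = lineages, version = version),
            class = "nb_classifier")
}
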