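# Independent test oracles. These deliberately share no code with the
# package: the aligner oracle is a plain R 3-state DP, the component
# oracle is a boolean transitive closure.

# Gotoh 3-state DP with the same contract as needleman_wunsch():
# match/mismatch scoring with -2 for ambiguity codes, gap of length L
# costing gap_open + (L-1)*gap_extend, free end gaps counted in the
# alignment length, and the shared deterministic lexicographic objective
# (score, then identical columns, then shorter alignment). The objective
# tuple pins down identity, so no traceback is needed.
oracle_nw <- function(a, b, match = 5, mismatch = -4,
                      gap_open = 10, gap_extend = 0.5,
                      end_gaps_free = TRUE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  EPS <- 1e-9
  acgt <- c("A", "C", "G", "T")
  sc <- function(x, y) {
    if (!(x %in% acgt) || !(y %in% acgt)) return(-2)
    if (x == y) match else mismatch
  }
  cell <- function(s, nid, alen) list(s = s, nid = nid, alen = alen)
  INVALID <- NULL
  better <- function(x, y) {
    if (is.null(x)) return(FALSE)
    if (is.null(y)) return(TRUE)
    if (x$s > y$s + EPS) return(TRUE)
    if (x$s < y$s - EPS) return(FALSE)
    if (x$nid != y$nid) return(x$nid > y$nid)
    x$alen < y$alen
  }
  adv <- function(x, ds, dnid, dalen) {
    if (is.null(x)) return(NULL)
    cell(x$s + ds, x$nid + dnid, x$alen + dalen)
  }
  best3 <- function(x, y, z) {
    b <- x
    if (better(y, b)) b <- y
    if (better(z, b)) b <- z
    b
  }
  newmat <- function() {
    mat <- vector("list", (m + 1) * (n + 1))
    dim(mat) <- c(m + 1, n + 1)
    mat
  }
  M <- newmat(); X <- newmat(); Y <- newmat()
  M[[1, 1]] <- cell(0, 0, 0)
  for (i in seq_len(m)) {
    X[[i + 1, 1]] <- cell(if (end_gaps_free) 0 else
      -(gap_open + (i - 1) * gap_extend), 0, i)
  }
  for (j in seq_len(n)) {
    Y[[1, j + 1]] <- cell(if (end_gaps_free) 0 else
      -(gap_open + (j - 1) * gap_extend), 0, j)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- sc(A[i], B[j])
      id <- as.integer(A[i] == B[j] && A[i] %in% acgt)
      M[[i + 1, j + 1]] <- adv(best3(M[[i, j]], X[[i, j]], Y[[i, j]]), s, id, 1)
      X[[i + 1, j + 1]] <- best3(adv(M[[i, j + 1]], -gap_open, 0, 1),
                                 adv(X[[i, j + 1]], -gap_extend, 0, 1),
                                 adv(Y[[i, j + 1]], -gap_open, 0, 1))
      Y[[i + 1, j + 1]] <- best3(adv(M[[i + 1, j]], -gap_open, 0, 1),
                                 adv(Y[[i + 1, j]], -gap_extend, 0, 1),
                                 adv(X[[i + 1, j]], -gap_open, 0, 1))
    }
  }
  cellbest <- function(i, j) best3(M[[i + 1, j + 1]], X[[i + 1, j + 1]],
                                   Y[[i + 1, j + 1]])
  if (end_gaps_free) {
    btot <- INVALID
    for (i in 0:(m - 1)) {
      v <- adv(cellbest(i, n), 0, 0, m - i)
      if (better(v, btot)) btot <- v
    }
    for (j in 0:n) {
      v <- adv(cellbest(m, j), 0, 0, n - j)
      if (better(v, btot)) btot <- v
    }
  } else {
    btot <- cellbest(m, n)
  }
  list(score = btot$s, n_identical = btot$nid,
       alignment_length = btot$alen,
       identity_pct = 100 * btot$nid / btot$alen)
}

# Transitive-closure (Floyd-Warshall over booleans) component oracle:
# returns the partition of `species` induced by `edges` as a list of
# sorted member vectors, ordered by first member.
oracle_components <- function(species, edges) {
  n <- length(species)
  adj <- diag(TRUE, n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$species1[k], species)
      j <- match(edges$species2[k], species)
      adj[i, j] <- TRUE; adj[j, i] <- TRUE
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (adj[i, k]) adj[i, ] <- adj[i, ] | adj[k, ]
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(adj[i, ])
    seen[members] <- TRUE
    comps[[length(comps) + 1L]] <- sort(species[members])
  }
  comps[order(vapply(comps, `[[`, "", 1L))]
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate exactly n distinct positions to a different base
mutate_n <- function(seq, n) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}
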