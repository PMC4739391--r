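# Independent oracles used to freeze expected values.

# Brute-force optimal global alignment score: enumerates every monotone
# alignment path and scores it with explicit affine gap accounting
# (gap run of length k costs gap_open + (k - 1) * gap_extend).
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -5, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, "M",
          sc + if (ca[i] == cb[j]) match else mismatch)
    if (i <= length(ca))
      rec(i + 1, j, "X",
          sc + if (identical(prev, "X")) gap_extend else gap_open)
    if (j <= length(cb))
      rec(i, j + 1, "Y",
          sc + if (identical(prev, "Y")) gap_extend else gap_open)
  }
  rec(1, 1, "", 0)
  best
}

# Full sign-enumeration oracle for the two-sided exact signed-rank p.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Random unrooted tree with positive branch lengths and its additive
# (path-length) distance matrix.
oracle_additive_case <- function(k) {
  tr <- ape::rtree(k, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# quick dataset builder
make_dataset <- function(seqs, species, ids = NULL, locus = "test") {
  if (is.null(ids)) ids <- sprintf("ACC%03d", seq_along(seqs))
  locus_dataset(data.frame(accession_id = ids, species = species,
                           sequence = seqs, stringsAsFactors = FALSE),
                locus = locus)
}

# build a k2p_dm object directly from a distance matrix and labels
make_dm <- function(d, species, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("ACC%03d", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, species = species, d = d),
            class = "k2p_dm")
}
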