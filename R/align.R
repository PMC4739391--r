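#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment. A gap run of length k costs
#' `gap_open + (k - 1) * gap_extend`; traceback ties are broken
#' deterministically (diagonal, then up, then left).
#'
#' @param a,b nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters. The
#'   defaults (+1/-1, gap -5/-1) approximate common DNA alignment
#'   settings.
#' @return a `pairwise_alignment`: list with `gapped_a`, `gapped_b`
#'   (equal-length gapped strings), `score`, `identity` (fraction of
#'   aligned non-gap-pair columns with equal symbols), `coverage_a` and
#'   `coverage_b` (fraction of each input's residues aligned to a
#'   residue of the other).
#' @export
#' @examples
#' global_align("ACGT", "ACT")
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  stopifnot(is.character(a), is.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("global_align requires non-empty sequences")
  res <- .align_global_cpp(toupper(a), toupper(b), match, mismatch,
                           gap_open, gap_extend)
  .finish_pairwise(res, nchar(a), nchar(b))
}

#' Optimal local pairwise alignment with affine gaps
#'
#' Smith-Waterman alignment under the same scoring model as
#' [global_align()]. An empty alignment (score 0) is allowed when no
#' positively scoring block exists.
#'
#' @inheritParams global_align
#' @return a `pairwise_alignment` as for [global_align()], with
#'   additional 1-based block coordinates `start_a`, `end_a`,
#'   `start_b`, `end_b` (all 0 for an empty alignment).
#' @export
#' @examples
#' local_align("GGACGTGG", "TTACGTTT")
local_align <- function(a, b, match = 1, mismatch = -1,
                        gap_open = -5, gap_extend = -1) {
  stopifnot(is.character(a), is.character(b))
  res <- .align_local_cpp(toupper(a), toupper(b), match, mismatch,
                          gap_open, gap_extend)
  out <- .finish_pairwise(res, nchar(a), nchar(b))
  out$start_a <- res$start_a
  out$end_a <- res$end_a
  out$start_b <- res$start_b
  out$end_b <- res$end_b
  out
}

.finish_pairwise <- function(res, len_a, len_b) {
  ca <- .chars(res$gapped_a)
  cb <- .chars(res$gapped_b)
  aligned <- ca != "-" & cb != "-"
  identity <- if (any(aligned)) mean(ca[aligned] == cb[aligned]) else NA_real_
  structure(list(gapped_a = res$gapped_a, gapped_b = res$gapped_b,
                 score = res$score, identity = identity,
                 coverage_a = sum(aligned) / len_a,
                 coverage_b = sum(aligned) / len_b),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score:", x$score,
      "identity:", round(x$identity, 3), "\n")
  cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n")
  invisible(x)
}

#' Construct a multiple alignment object
#'
#' @param rows character vector of equal-length gapped sequences.
#' @param row_ids identifiers, one per row.
#' @return a `multiple_alignment`: list with `rows`, `row_ids`,
#'   `n_columns`.
#' @export
multiple_alignment <- function(rows, row_ids = names(rows)) {
  stopifnot(length(rows) >= 1L)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length")
  if (is.null(row_ids)) row_ids <- as.character(seq_along(rows))
  rows <- toupper(unname(rows))
  # drop all-gap columns
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  allgap <- apply(m == "-", 2, all)
  if (any(allgap)) {
    m <- m[, !allgap, drop = FALSE]
    rows <- apply(m, 1, paste, collapse = "")
  }
  structure(list(rows = rows, row_ids = row_ids,
                 n_columns = nchar(rows[1])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment>", length(x$rows), "rows x", x$n_columns,
      "columns\n")
  invisible(x)
}

#' Character matrix view of a multiple alignment
#' @param x a [multiple_alignment()].
#' @param ... unused.
#' @return a character matrix (rows = sequences, columns = sites).
#' @export
as.matrix.multiple_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$row_ids
  m
}

# 4 x L profile of A/C/G/T fractions; gaps and ambiguity codes
# contribute nothing
.profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  k <- nrow(m)
  p <- matrix(0, 4, ncol(m))
  for (b in names(.base_code))
    p[.base_code[[b]], ] <- colSums(m == b) / k
  p
}

# apply a merge op vector to two row sets, inserting gap columns
.apply_ops <- function(rows_a, rows_b, ops) {
  ca <- strsplit(rows_a, "", fixed = TRUE)
  cb <- strsplit(rows_b, "", fixed = TRUE)
  n_out <- length(ops)
  ia <- cumsum(ops != 2L)   # position in a consumed at each op
  ib <- cumsum(ops != 1L)
  out_a <- lapply(ca, function(ch) {
    v <- rep("-", n_out)
    take <- ops != 2L
    v[take] <- ch[ia[take]]
    paste(v, collapse = "")
  })
  out_b <- lapply(cb, function(ch) {
    v <- rep("-", n_out)
    take <- ops != 1L
    v[take] <- ch[ib[take]]
    paste(v, collapse = "")
  })
  c(unlist(out_a), unlist(out_b))
}

#' Progressive multiple sequence alignment
#'
#' A ClustalW-style progressive aligner: pairwise global alignments give
#' an identity-based distance matrix, a neighbor-joining guide tree is
#' built from it, and profiles are merged in guide-tree postorder using
#' profile-profile alignment under the same affine gap model. Output row
#' order equals input order; all-gap columns are dropped.
#'
#' @param dataset a [locus_dataset()] with at least two records, or a
#'   named character vector of sequences.
#' @inheritParams global_align
#' @return a [multiple_alignment()] with `row_ids` equal to the
#'   accession ids.
#' @export
progressive_msa <- function(dataset, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  if (inherits(dataset, "locus_dataset")) {
    seqs <- gsub("-", "", dataset$records$sequence, fixed = TRUE)
    ids <- dataset$records$accession_id
  } else {
    seqs <- gsub("-", "", toupper(dataset), fixed = TRUE)
    ids <- names(dataset)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
  }
  n <- length(seqs)
  if (n < 2L) stop("progressive_msa requires at least 2 records")
  if (n == 2L) {
    aln <- global_align(seqs[1], seqs[2], match, mismatch,
                        gap_open, gap_extend)
    return(multiple_alignment(c(aln$gapped_a, aln$gapped_b), ids))
  }
  stats <- .global_stats_cpp(seqs, match, mismatch, gap_open, gap_extend)
  d <- 1 - stats$identity
  merge_order <- .guide_tree_merges(d)
  # clusters carry gapped rows plus original indices
  clusters <- lapply(seq_len(n), function(i)
    list(rows = seqs[i], idx = i))
  for (m in merge_order) {
    a <- clusters[[m[1]]]
    b <- clusters[[m[2]]]
    ops <- .align_profiles_cpp(.profile_of(a$rows), .profile_of(b$rows),
                               match, mismatch, gap_open, gap_extend)
    rows <- .apply_ops(a$rows, b$rows, ops)
    clusters[[m[1]]] <- list(rows = rows, idx = c(a$idx, b$idx))
    clusters[[m[2]]] <- NULL_cluster
  }
  final <- clusters[[merge_order[[length(merge_order)]][1]]]
  ord <- order(final$idx)
  multiple_alignment(final$rows[ord], ids[final$idx[ord]])
}

NULL_cluster <- list(rows = character(0), idx = integer(0))

# postorder merge schedule from a neighbor-joining guide tree.
# Returns a list of index pairs; each merge folds cluster j into i.
.guide_tree_merges <- function(d) {
  n <- nrow(d)
  if (n == 2L) return(list(c(1L, 2L)))
  if (n == 3L) return(list(c(1L, 2L), c(1L, 3L)))
  rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  tr <- ape::nj(stats::as.dist(d))
  tr <- stats::reorder(tr, "postorder")
  # map tree tips back to input indices
  tip_idx <- as.integer(sub("t", "", tr$tip.label))
  merges <- list()
  cluster_rep <- integer(ape::Nnode(tr) + ape::Ntip(tr))
  cluster_rep[seq_len(ape::Ntip(tr))] <- tip_idx
  # postorder: children are merged before their parent is reached
  for (node in unique(tr$edge[, 1])) {
    children <- tr$edge[tr$edge[, 1] == node, 2]
    reps <- cluster_rep[children]
    for (k in seq_along(reps)[-1])
      merges[[length(merges) + 1L]] <- c(reps[1], reps[k])
    cluster_rep[node] <- reps[1]
  }
  merges
}

#' Count variable sites in an alignment
#'
#' A column is variable when it contains at least two distinct
#' unambiguous bases (A, C, G, T); gaps and ambiguity codes do not make
#' a column variable.
#'
#' @param msa a [multiple_alignment()].
#' @return integer count of variable columns.
#' @export
count_variable_sites <- function(msa) {
  m <- as.matrix(msa)
  sum(apply(m, 2, function(col) {
    b <- unique(col[col %in% c("A", "C", "G", "T")])
    length(b) >= 2L
  }))
}

#' Count indel sites in an alignment
#'
#' With `count = "events"` (the default), indels are counted as distinct
#' maximal gap runs, identified by their (start, end) column interval:
#' the same deletion shared by several rows counts once. With
#' `count = "columns"`, the number of columns containing at least one
#' gap is returned.
#'
#' @param msa a [multiple_alignment()].
#' @param count `"events"` or `"columns"`.
#' @return integer count.
#' @export
count_indel_sites <- function(msa, count = c("events", "columns")) {
  count <- match.arg(count)
  m <- as.matrix(msa)
  gaps <- m == "-"
  if (count == "columns") return(sum(apply(gaps, 2, any)))
  events <- character(0)
  for (i in seq_len(nrow(m))) {
    r <- rle(gaps[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values)
    if (length(run))
      events <- c(events, paste(starts[run], ends[run], sep = "-"))
  }
  length(unique(events))
}

#' Write a multiple alignment as aligned FASTA
#' @param msa a [multiple_alignment()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_msa <- function(msa, path) {
  lines <- as.vector(rbind(paste0(">", msa$row_ids), msa$rows))
  writeLines(lines, path)
  invisible(path)
}

#' Read an aligned FASTA file as a multiple alignment
#' @param path path to an aligned FASTA file.
#' @return a [multiple_alignment()].
#' @export
read_msa <- function(path) {
  seqs <- ape::read.FASTA(path)
  rows <- toupper(vapply(as.character(seqs), paste, "", collapse = ""))
  multiple_alignment(rows, names(seqs))
}
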