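#' Find homopolymer runs
#'
#' Maximal single-base runs of at least `min_len` bases, reported with
#' 1-based inclusive coordinates on the ungapped sequence.
#'
#' @param seq a nucleotide string (gaps are removed before scanning).
#' @param min_len minimum run length in bp.
#' @param sequence_id optional id recorded in the result.
#' @return a `feature_hits` data frame with columns `kind`,
#'   `sequence_id`, `start`, `end`, `length`, `motif`, `copies`,
#'   `identity`.
#' @export
#' @examples
#' find_homopolymers("CCAAAAAAACC")
find_homopolymers <- function(seq, min_len = 6, sequence_id = NA_character_) {
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  ch <- .chars(s)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$lengths >= min_len & r$values %in% c("A", "C", "G", "T"))
  .feature_hits(kind = rep("homopolymer", length(sel)),
                sequence_id = rep(sequence_id, length(sel)),
                start = starts[sel], end = ends[sel],
                motif = r$values[sel], copies = r$lengths[sel],
                identity = rep(1, length(sel)))
}

.feature_hits <- function(kind, sequence_id, start, end, motif, copies,
                          identity) {
  structure(data.frame(kind = kind, sequence_id = sequence_id,
                       start = as.integer(start), end = as.integer(end),
                       length = as.integer(end - start + 1L),
                       motif = motif, copies = as.integer(copies),
                       identity = identity, stringsAsFactors = FALSE),
            class = c("feature_hits", "data.frame"))
}

# smallest period p of string ch (character vector) such that
# ch[i] == ch[i + p] for all valid i; returns p (may equal length)
.primitive_period <- function(ch) {
  n <- length(ch)
  for (p in seq_len(n - 1)) {
    if (all(ch[seq_len(n - p)] == ch[(p + 1):n])) return(p)
  }
  n
}

#' Find perfect tandem repeats
#'
#' Maximal perfect tandem arrays of a repeat unit between `unit_min` and
#' `unit_max` bp with at least `min_copies` full copies and a total
#' (full-copy) length of at least `min_total` bp. The smallest
#' rotational unit is reported; homopolymer arrays are left to
#' [find_homopolymers()]. Coordinates are 1-based inclusive on the
#' ungapped sequence and span the full copies only.
#'
#' @param seq a nucleotide string.
#' @param unit_min,unit_max repeat unit length bounds in bp.
#' @param min_copies minimum number of full copies.
#' @param min_total minimum total array length in bp.
#' @param sequence_id optional id recorded in the result.
#' @return a `feature_hits` data frame (see [find_homopolymers()]).
#' @export
#' @examples
#' find_tandem_repeats("GGATTAAAATTAAAGG")
find_tandem_repeats <- function(seq, unit_min = 3, unit_max = 10,
                                min_copies = 2, min_total = 12,
                                sequence_id = NA_character_) {
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  ch <- .chars(s)
  n <- length(ch)
  found <- list()
  for (u in unit_min:unit_max) {
    if (2 * u > n) break
    m <- ch[seq_len(n - u)] == ch[(u + 1):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u)) {
      region_start <- starts[k]
      region_end <- ends[k] + u      # inclusive, includes partial copy
      seg <- ch[region_start:region_end]
      p <- .primitive_period(seg)
      if (p < 2L || p > u) next      # homopolymer, or found at its own u
      # extend region with period p in both directions
      while (region_start > 1L &&
             ch[region_start - 1L] == ch[region_start - 1L + p])
        region_start <- region_start - 1L
      while (region_end < n && ch[region_end + 1L] == ch[region_end + 1L - p])
        region_end <- region_end + 1L
      copies <- (region_end - region_start + 1L) %/% p
      if (copies < min_copies || copies * p < min_total) next
      found[[length(found) + 1L]] <- c(region_start,
                                       region_start + copies * p - 1L, p)
    }
  }
  if (length(found) == 0L)
    return(.feature_hits(character(0), character(0), integer(0),
                         integer(0), character(0), integer(0), numeric(0)))
  mat <- unique(do.call(rbind, found))
  motif <- vapply(seq_len(nrow(mat)), function(i)
    paste(ch[mat[i, 1]:(mat[i, 1] + mat[i, 3] - 1L)], collapse = ""), "")
  .feature_hits(kind = rep("tandem_repeat", nrow(mat)),
                sequence_id = rep(sequence_id, nrow(mat)),
                start = mat[, 1], end = mat[, 2], motif = motif,
                copies = (mat[, 2] - mat[, 1] + 1L) %/% mat[, 3],
                identity = rep(1, nrow(mat)))
}

#' Detect inverted segments against a reference
#'
#' Finds segments of the query that align to the reference in
#' reverse-complement orientation: the reverse complement of the query
#' is locally aligned to the reference, and a hit is reported when the
#' aligned block spans at least `min_len` query bases at identity at
#' least `min_identity`, and scores strictly better than the
#' forward-strand local alignment of the same query segment. After a
#' hit the segment is masked and the scan repeats, so multiple
#' inversions can be reported. Coordinates are 1-based inclusive on the
#' ungapped query.
#'
#' @param query,reference nucleotide strings.
#' @param min_len minimum inverted block length in bp.
#' @param min_identity minimum block identity (fraction).
#' @param max_hits scan stops after this many hits.
#' @inheritParams global_align
#' @return a `feature_hits` data frame (see [find_homopolymers()]);
#'   empty when no inversion is found.
#' @export
detect_inversion <- function(query, reference, min_len = 50,
                             min_identity = 0.98, max_hits = 5,
                             match = 1, mismatch = -1,
                             gap_open = -5, gap_extend = -1) {
  q0 <- gsub("-", "", toupper(query), fixed = TRUE)
  ref <- gsub("-", "", toupper(reference), fixed = TRUE)
  hits <- list()
  q <- q0
  lq <- nchar(q0)
  repeat {
    if (length(hits) >= max_hits) break
    rc <- revcomp(q)
    aln <- local_align(rc, ref, match, mismatch, gap_open, gap_extend)
    if (aln$score <= 0) break
    # map the rc block back to query coordinates
    q_start <- lq - aln$end_a + 1L
    q_end <- lq - aln$start_a + 1L
    block_len <- q_end - q_start + 1L
    if (block_len < min_len || is.na(aln$identity) ||
        aln$identity < min_identity) break
    segment <- substr(q0, q_start, q_end)
    fwd <- local_align(segment, ref, match, mismatch, gap_open,
                       gap_extend)
    if (fwd$score >= aln$score) break
    hits[[length(hits) + 1L]] <- c(q_start, q_end, aln$identity)
    # mask the hit and rescan for further inversions
    q <- paste0(substr(q, 1, q_start - 1),
                strrep("N", block_len),
                substr(q, q_end + 1, lq))
  }
  if (length(hits) == 0L)
    return(.feature_hits(character(0), character(0), integer(0),
                         integer(0), character(0), integer(0), numeric(0)))
  mat <- do.call(rbind, hits)
  .feature_hits(kind = rep("inversion", nrow(mat)),
                sequence_id = rep(NA_character_, nrow(mat)),
                start = mat[, 1], end = mat[, 2],
                motif = rep("", nrow(mat)),
                copies = rep(1L, nrow(mat)), identity = mat[, 3])
}

#' Species-diagnostic alignment columns
#'
#' Columns of a multiple alignment at which every member of the target
#' species carries a state (base or gap) carried by no non-target
#' member.
#'
#' @param msa a [multiple_alignment()].
#' @param species species labels aligned with the alignment rows.
#' @param target the target species binomial.
#' @return integer vector of 1-based diagnostic column indices.
#' @export
diagnostic_positions <- function(msa, species, target) {
  stopifnot(length(species) == length(msa$rows))
  m <- as.matrix(msa)
  in_target <- species == target
  if (!any(in_target)) stop("target species not present: ", target)
  if (all(in_target)) stop("no non-target rows to compare against")
  which(vapply(seq_len(ncol(m)), function(j) {
    tstates <- unique(m[in_target, j])
    ostates <- unique(m[!in_target, j])
    length(intersect(tstates, ostates)) == 0L
  }, logical(1)))
}

#' Write feature hits as TSV
#' @param hits a `feature_hits` data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_features <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write feature hits as BED
#'
#' Converts the 1-based inclusive feature coordinates to BED's 0-based
#' half-open convention.
#'
#' @param hits a `feature_hits` data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_features_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$sequence_id,
                    chromStart = hits$start - 1L,
                    chromEnd = hits$end,
                    name = paste0(hits$kind,
                                  ifelse(nchar(hits$motif) > 0,
                                         paste0(":", hits$motif), "")))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
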