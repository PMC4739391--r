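#' Transition/transversion comparison of two aligned sequences
#'
#' Pairwise deletion: columns with a gap or an ambiguity code in either
#' row are skipped. Transitions are A/G and C/T differences;
#' transversions are all other base differences.
#'
#' @param row_a,row_b equal-length gapped sequence strings.
#' @return a list with `P` (transition difference proportion), `Q`
#'   (transversion proportion), `L` (effective compared sites) and
#'   `defined` (FALSE when `L` is 0, in which case `P` and `Q` are NA).
#' @export
#' @examples
#' compare_pair("ACGT", "GCGT")
compare_pair <- function(row_a, row_b) {
  a <- .chars(toupper(row_a))
  b <- .chars(toupper(row_b))
  if (length(a) != length(b))
    stop("compare_pair requires equal-length rows")
  ok <- a %in% names(.base_code) & b %in% names(.base_code)
  L <- sum(ok)
  if (L == 0L)
    return(list(P = NA_real_, Q = NA_real_, L = 0L, defined = FALSE))
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                (a == "C" & b == "T") | (a == "T" & b == "C"))
  list(P = sum(ts) / L, Q = sum(diff & !ts) / L, L = L, defined = TRUE)
}

#' Kimura 2-parameter distance
#'
#' Evaluates d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q), the expected
#' substitutions per site under a model with separate transition and
#' transversion rates. Outside the model's domain (1 - 2P - Q <= 0 or
#' 1 - 2Q <= 0, i.e. saturation) the distance is undefined and NA is
#' returned, never 0.
#'
#' @param P transition difference proportion (vectorized), or the list
#'   returned by [compare_pair()].
#' @param Q transversion difference proportion; ignored when `P` is a
#'   comparison list.
#' @return numeric distance(s) in substitutions/site; NA when undefined.
#' @export
#' @examples
#' k2p_distance(0.1, 0.05)
k2p_distance <- function(P, Q = NULL) {
  if (is.list(P)) {
    Q <- P$Q
    P <- P$P
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(is.na(w1) | is.na(w2) | w1 <= 0 | w2 <= 0,
              NA_real_,
              -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                0.25 * log(pmax(w2, .Machine$double.xmin)))
  unname(d)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' Applies [compare_pair()] and [k2p_distance()] to every row pair of a
#' multiple alignment. Saturated pairs and pairs with no shared
#' unambiguous sites are NA in the distance matrix (flagged, never
#' silently 0).
#'
#' @param msa a [multiple_alignment()].
#' @param species species labels aligned with the alignment rows.
#' @param deletion `"pairwise"` (default: skip a column only for the
#'   pair missing it) or `"complete"` (drop any column containing a gap
#'   or ambiguity in any row before comparing).
#' @return a `k2p_dm`: list with `ids`, `species`, `d` (symmetric
#'   distance matrix with NA for undefined entries), `P`, `Q`, `L`.
#' @export
distance_matrix <- function(msa, species,
                            deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(species) == length(msa$rows))
  m <- as.matrix(msa)
  code <- matrix(0L, nrow(m), ncol(m))
  for (b in names(.base_code)) code[m == b] <- .base_code[[b]]
  if (deletion == "complete") {
    keep <- apply(code > 0L, 2, all)
    code <- code[, keep, drop = FALSE]
  }
  cnt <- .pair_counts_cpp(code)
  d <- k2p_distance(cnt$P, cnt$Q)
  d <- matrix(d, nrow(m), nrow(m))
  diag(d) <- 0
  dimnames(d) <- list(msa$row_ids, msa$row_ids)
  structure(list(ids = msa$row_ids, species = species, d = d,
                 P = cnt$P, Q = cnt$Q, L = cnt$L),
            class = "k2p_dm")
}

#' @export
print.k2p_dm <- function(x, ...) {
  cat("<k2p_dm>", length(x$ids), "accessions,",
      length(unique(x$species)), "species;",
      sum(is.na(x$d[upper.tri(x$d)])), "undefined pair(s)\n")
  invisible(x)
}

#' Overall mean distance
#'
#' Mean of the defined off-diagonal entries, each unordered pair counted
#' once — the per-locus average evolutionary divergence over all
#' sequence pairs.
#'
#' @param dm a `k2p_dm` from [distance_matrix()].
#' @return numeric mean distance.
#' @export
overall_mean_distance <- function(dm) {
  v <- dm$d[upper.tri(dm$d)]
  mean(v, na.rm = TRUE)
}

#' Write a distance matrix as square TSV
#' @param dm a `k2p_dm`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  out <- data.frame(accession_id = dm$ids, dm$d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# long view of the defined pairwise distances with pair classification
.pair_table <- function(dm) {
  n <- length(dm$ids)
  idx <- which(upper.tri(dm$d), arr.ind = TRUE)
  data.frame(
    id_a = dm$ids[idx[, 1]],
    id_b = dm$ids[idx[, 2]],
    species_a = dm$species[idx[, 1]],
    species_b = dm$species[idx[, 2]],
    distance = dm$d[idx],
    conspecific = dm$species[idx[, 1]] == dm$species[idx[, 2]],
    stringsAsFactors = FALSE)
}
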