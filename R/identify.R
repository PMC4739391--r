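#' Leave-one-out identification by the nearest-distance method
#'
#' Removes the query from the reference set and assigns it the species
#' of the minimum-distance reference. When the minimum distance is
#' shared by references of more than one species the query is a tie and
#' counts as a success only if all tied references are conspecific with
#' it.
#'
#' @param dm a `k2p_dm` from [distance_matrix()].
#' @param query_id accession id of the query.
#' @param tol tolerance when comparing distances for ties.
#' @return an `identification_result`: one-row data frame with columns
#'   `query_id`, `method`, `best_hit_id`, `assigned_species`,
#'   `correct_species`, `correct_genus`, `tie`.
#' @export
nearest_distance_id <- function(dm, query_id, tol = 1e-12) {
  qi <- match(query_id, dm$ids)
  if (is.na(qi)) stop("query id not in distance matrix: ", query_id)
  if (length(dm$ids) < 2L) stop("need at least one other record")
  d <- dm$d[qi, -qi]
  ref_species <- dm$species[-qi]
  ref_ids <- dm$ids[-qi]
  .assign_from_scores(query_id, "nearest_distance",
                      score = -d, ref_ids = ref_ids,
                      ref_species = ref_species,
                      query_species = dm$species[qi], tol = tol)
}

#' Leave-one-out identification by the local-alignment top-hit method
#'
#' An in-package stand-in for BLAST-style top-hit assignment: the query
#' is locally aligned against every other record and assigned the
#' species of the top-scoring hit. Score ties are handled as in
#' [nearest_distance_id()].
#'
#' @param dataset a [locus_dataset()].
#' @param query_id accession id of the query.
#' @inheritParams global_align
#' @return an `identification_result` (see [nearest_distance_id()]).
#' @export
top_hit_id <- function(dataset, query_id, match = 1, mismatch = -1,
                       gap_open = -5, gap_extend = -1) {
  rec <- dataset$records
  qi <- base::match(query_id, rec$accession_id)  # `match` is a score here
  if (is.na(qi)) stop("query id not in dataset: ", query_id)
  if (nrow(rec) < 2L) stop("need at least one other record")
  q <- gsub("-", "", rec$sequence[qi], fixed = TRUE)
  refs <- rec[-qi, , drop = FALSE]
  scores <- vapply(seq_len(nrow(refs)), function(i) {
    local_align(q, gsub("-", "", refs$sequence[i], fixed = TRUE),
                match, mismatch, gap_open, gap_extend)$score
  }, numeric(1))
  scores[scores == 0] <- NA_real_  # no local similarity at all
  .assign_from_scores(query_id, "top_hit", score = scores,
                      ref_ids = refs$accession_id,
                      ref_species = refs$species,
                      query_species = rec$species[qi], tol = 1e-9)
}

# shared assignment logic: higher score = better hit
.assign_from_scores <- function(query_id, method, score, ref_ids,
                                ref_species, query_species, tol) {
  genus_of <- function(sp) vapply(strsplit(sp, "\\s+"), `[`, "", 1L)
  if (all(is.na(score))) {
    return(structure(data.frame(
      query_id = query_id, method = method, best_hit_id = NA_character_,
      assigned_species = NA_character_, correct_species = FALSE,
      correct_genus = FALSE, tie = FALSE, stringsAsFactors = FALSE),
      class = c("identification_result", "data.frame")))
  }
  best <- max(score, na.rm = TRUE)
  hits <- which(!is.na(score) & score >= best - tol)
  hit_species <- unique(ref_species[hits])
  tie <- length(hits) > 1L && length(hit_species) > 1L
  assigned <- if (length(hit_species) == 1L) hit_species else "ambiguous"
  correct_species <- length(hit_species) >= 1L &&
    all(hit_species == query_species)
  hit_genera <- unique(genus_of(ref_species[hits]))
  correct_genus <- all(hit_genera == genus_of(query_species))
  structure(data.frame(
    query_id = query_id, method = method,
    best_hit_id = ref_ids[hits[1]], assigned_species = assigned,
    correct_species = correct_species, correct_genus = correct_genus,
    tie = tie, stringsAsFactors = FALSE),
    class = c("identification_result", "data.frame"))
}

#' Identify every accession by leave-one-out
#'
#' Runs [nearest_distance_id()] or [top_hit_id()] with each accession in
#' turn as the query.
#'
#' @param x a `k2p_dm` (for `method = "nearest_distance"`) or a
#'   [locus_dataset()] (for `method = "top_hit"`).
#' @param method identification method.
#' @param ... passed to the per-query function.
#' @return a data frame of `identification_result` rows, plus columns
#'   `query_species` and `singleton` (TRUE when the query's species has
#'   no other representative).
#' @export
identify_all <- function(x, method = c("nearest_distance", "top_hit"),
                         ...) {
  method <- match.arg(method)
  if (method == "nearest_distance") {
    stopifnot(inherits(x, "k2p_dm"))
    ids <- x$ids
    species <- x$species
    res <- lapply(ids, function(id) nearest_distance_id(x, id, ...))
  } else {
    stopifnot(inherits(x, "locus_dataset"))
    ids <- x$records$accession_id
    species <- x$records$species
    # all-pairs local scores in one pass, then per-query assignment
    seqs <- gsub("-", "", x$records$sequence, fixed = TRUE)
    params <- utils::modifyList(list(match = 1, mismatch = -1,
                                     gap_open = -5, gap_extend = -1),
                                list(...))
    sc <- .local_scores_cpp(seqs, params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
    res <- lapply(seq_along(ids), function(qi) {
      s <- sc[qi, -qi]
      s[s == 0] <- NA_real_
      .assign_from_scores(ids[qi], "top_hit", score = s,
                          ref_ids = ids[-qi],
                          ref_species = species[-qi],
                          query_species = species[qi], tol = 1e-9)
    })
  }
  out <- do.call(rbind, res)
  out$query_species <- species
  counts <- table(species)
  out$singleton <- counts[species] == 1L
  rownames(out) <- NULL
  out
}

#' Identification efficiency
#'
#' The percentage of successful leave-one-out queries. At species level,
#' queries whose species has no other representative are excluded from
#' the denominator (they cannot possibly be matched correctly); at
#' genus level all queries count.
#'
#' @param results a data frame from [identify_all()], or a `k2p_dm` /
#'   [locus_dataset()] (in which case `method` selects the
#'   identification method and [identify_all()] is run first).
#' @param level `"species"` or `"genus"`.
#' @param method identification method, used only when `results` is not
#'   already a results data frame.
#' @param ... passed to [identify_all()].
#' @return efficiency as a percentage (0-100); NA when no query
#'   qualifies.
#' @export
efficiency <- function(results, level = c("species", "genus"),
                       method = c("nearest_distance", "top_hit"), ...) {
  level <- match.arg(level)
  if (!is.data.frame(results))
    results <- identify_all(results, method = match.arg(method), ...)
  if (level == "species") {
    use <- results[!results$singleton, , drop = FALSE]
    if (nrow(use) == 0L) return(NA_real_)
    100 * mean(use$correct_species)
  } else {
    100 * mean(results$correct_genus)
  }
}

#' Write per-query identification results as TSV
#' @param results a data frame from [identify_all()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_identification <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
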