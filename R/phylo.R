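#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on the defined entries of
#' a distance matrix. Undefined (saturated) entries are imputed as 1.1
#' times the largest defined distance, keeping saturated pairs
#' peripheral; the run aborts instead when more than `max_undefined` of
#' the off-diagonal entries are undefined. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch; the
#' raw lengths are retained in `attr(tree, "raw_edge_length")`.
#'
#' @param dm a `k2p_dm` from [distance_matrix()], or a plain symmetric
#'   numeric matrix with dimnames.
#' @param species optional species labels (taken from `dm` when it is a
#'   `k2p_dm`); stored in `attr(tree, "species")` named by tip label.
#' @param max_undefined largest tolerated fraction of undefined entries.
#' @return an \pkg{ape} `phylo` tree with attributes `species`,
#'   `raw_edge_length` and `imputed_pairs`.
#' @export
nj_tree <- function(dm, species = NULL, max_undefined = 0.05) {
  if (inherits(dm, "k2p_dm")) {
    d <- dm$d
    if (is.null(species)) species <- stats::setNames(dm$species, dm$ids)
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 3L) stop("nj_tree requires at least 3 taxa")
  off <- d[upper.tri(d)]
  n_undef <- sum(is.na(off))
  if (n_undef > max_undefined * length(off))
    stop("too many undefined distances: ", n_undef, " of ", length(off))
  imputed <- NULL
  if (n_undef > 0L) {
    fill <- 1.1 * max(off, na.rm = TRUE)
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    imputed <- data.frame(id_a = rownames(d)[idx[, 1]],
                          id_b = colnames(d)[idx[, 2]],
                          value = fill, stringsAsFactors = FALSE)
    d[is.na(d)] <- fill
  }
  tr <- ape::nj(stats::as.dist(d))
  raw <- tr$edge.length
  tr$edge.length <- .clamp_negative_edges(tr)
  attr(tr, "raw_edge_length") <- raw
  attr(tr, "imputed_pairs") <- imputed
  if (!is.null(species)) attr(tr, "species") <- species
  tr
}

# zero out negative edges, transferring the deficit to the sibling
# branch so root-to-tip path lengths are preserved where possible
.clamp_negative_edges <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      el[sibs[1]] <- el[sibs[1]] + el[e]
    }
    el[e] <- 0
  }
  pmax(el, 0)
}

#' Per-species monophyly report for a tree
#'
#' For each species with at least two accessions, finds the largest
#' clade (bipartition side of the unrooted tree) containing only that
#' species' accessions; members outside that clade are counted as
#' misplaced. The total misplaced count summarizes how well the tree
#' sorts accessions into recognized species.
#'
#' @param tree an ape `phylo` tree.
#' @param species named character vector mapping tip labels to species;
#'   defaults to `attr(tree, "species")`.
#' @return a list with `per_species` (data frame: `species`,
#'   `n_accessions`, `largest_clade`, `misplaced`) and `n_misplaced`
#'   (total), `n_accessions_total`.
#' @export
monophyly_report <- function(tree, species = attr(tree, "species")) {
  if (is.null(species)) stop("species labels are required")
  species <- species[tree$tip.label]
  if (anyNA(species)) stop("species labels missing for some tips")
  ntip <- length(tree$tip.label)
  # candidate clades: each internal edge bipartition, both sides
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, identity)
  sides <- c(sides, lapply(parts, function(p) setdiff(seq_len(ntip), p)))
  sides <- sides[vapply(sides, length, integer(1)) > 0L]
  per <- lapply(unique(species), function(sp) {
    members <- which(species == sp)
    if (length(members) < 2L) return(NULL)
    pure <- vapply(sides, function(s) all(species[s] == sp), logical(1))
    largest <- if (any(pure))
      max(vapply(sides[pure], length, integer(1))) else 1L
    largest <- min(largest, length(members))
    data.frame(species = sp, n_accessions = length(members),
               largest_clade = largest,
               misplaced = length(members) - largest,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_species = per,
       n_misplaced = if (is.null(per)) 0L else sum(per$misplaced),
       n_accessions_total = ntip)
}

#' Serialize a tree to newick text
#'
#' Writes branch lengths at full precision; labels containing
#' whitespace, quotes or newick metacharacters are single-quoted. The
#' output round-trips through [read_newick()].
#'
#' @param tree an ape `phylo` tree.
#' @param path optional file path; when given the text is also written
#'   there.
#' @param digits significant digits for branch lengths.
#' @return the newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 17) {
  quote_label <- function(lab) {
    if (grepl("[^A-Za-z0-9_.|/-]", lab))   # anything newick-unsafe
      paste0("'", gsub("'", "''", lab), "'")
    else lab
  }
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      child <- tree$edge[e, 2]
      paste0(rec(child),
             if (!is.null(tree$edge.length))
               paste0(":", fmt_len(tree$edge.length[e])) else "")
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n_tip + 1L
  txt <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse newick text into a tree
#'
#' Single-quoted labels (the newick convention for labels containing
#' spaces or metacharacters, with `''` as an escaped quote) are
#' supported by substituting placeholders before parsing and restoring
#' the original labels afterwards.
#'
#' @param text a newick string, or NULL to read from `path`.
#' @param path optional file to read from.
#' @return an ape `phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  m <- gregexpr("'(?:[^']|'')*'", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(ape::read.tree(text = text))
  quoted <- regmatches(text, list(m))[[1]]
  labels <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1))
  placeholders <- sprintf("QLBL%03dX", seq_along(quoted))
  regmatches(text, list(m)) <- list(placeholders)
  tr <- ape::read.tree(text = text)
  restore <- function(x) {
    idx <- base::match(x, placeholders)
    ifelse(is.na(idx), x, labels[idx])
  }
  tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  tr
}

#' Write a monophyly report as TSV
#' @param report a list from [monophyly_report()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_monophyly <- function(report, path) {
  write.table(report$per_species, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
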