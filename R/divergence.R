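#' Inter- and intraspecific divergence parameters
#'
#' Computes the six divergence parameters commonly reported when ranking
#' candidate barcode loci, each as mean and SD in substitutions/site:
#' \describe{
#'   \item{theta}{per-species mean conspecific distance, averaged across
#'     species with at least two accessions.}
#'   \item{coalescent_depth}{per-species maximum conspecific distance,
#'     averaged the same way.}
#'   \item{all_intra}{all conspecific pairwise distances pooled.}
#'   \item{theta_prime}{per-species mean distance from its members to
#'     all congeners, averaged across species.}
#'   \item{min_inter}{per-species minimum distance from its members to
#'     any heterospecific member, averaged across species.}
#'   \item{all_inter}{all heterospecific pairwise distances pooled.}
#' }
#' Species with a single accession contribute only to the interspecific
#' parameters. Undefined (saturated) pairs are excluded throughout.
#'
#' @param dm a `k2p_dm` from [distance_matrix()].
#' @return a `divergence_summary` data frame with columns `parameter`,
#'   `mean`, `sd`, `n` (number of pairs or species contributing).
#'   Intraspecific rows are NA when no species has two accessions.
#' @export
divergence_parameters <- function(dm) {
  pt <- .pair_table(dm)
  pt <- pt[!is.na(pt$distance), , drop = FALSE]
  if (length(unique(dm$species)) < 2L)
    stop("divergence_parameters requires at least 2 species")
  intra <- pt[pt$conspecific, , drop = FALSE]
  inter <- pt[!pt$conspecific, , drop = FALSE]

  per_species_intra <- split(intra$distance, intra$species_a)
  theta_vals <- vapply(per_species_intra, mean, numeric(1))
  depth_vals <- vapply(per_species_intra, max, numeric(1))

  sp_all <- unique(dm$species)
  inter_by_sp <- lapply(sp_all, function(s)
    inter$distance[inter$species_a == s | inter$species_b == s])
  has_inter <- vapply(inter_by_sp, length, integer(1)) > 0L
  tp_vals <- vapply(inter_by_sp[has_inter], mean, numeric(1))
  mi_vals <- vapply(inter_by_sp[has_inter], min, numeric(1))

  msd <- function(v) {
    if (length(v) == 0L) return(c(NA_real_, NA_real_, 0))
    c(mean(v), if (length(v) > 1L) sd(v) else 0, length(v))
  }
  rows <- rbind(
    theta = msd(theta_vals),
    coalescent_depth = msd(depth_vals),
    all_intra = msd(intra$distance),
    theta_prime = msd(tp_vals),
    min_inter = msd(mi_vals),
    all_inter = msd(inter$distance))
  structure(data.frame(parameter = rownames(rows),
                       mean = rows[, 1], sd = rows[, 2], n = rows[, 3],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("divergence_summary", "data.frame"))
}

#' Barcoding-gap profile
#'
#' Separates the conspecific and heterospecific distance distributions
#' into histograms on a common binning, and computes an overlap
#' statistic: the fraction of intraspecific distances at or above the
#' 5th percentile of the interspecific distances. A clear barcoding gap
#' gives overlap near 0; identical distributions give overlap near 1.
#'
#' @param dm a `k2p_dm` from [distance_matrix()].
#' @param bin_width histogram bin width in substitutions/site.
#' @return a `gap_profile`: list with `breaks`, `intra_counts`,
#'   `inter_counts`, `bin_width`, `overlap`, `n_intra`, `n_inter`.
#' @export
barcoding_gap <- function(dm, bin_width = 0.005) {
  pt <- .pair_table(dm)
  pt <- pt[!is.na(pt$distance), , drop = FALSE]
  intra <- pt$distance[pt$conspecific]
  inter <- pt$distance[!pt$conspecific]
  top <- max(c(intra, inter, bin_width))
  breaks <- seq(0, top + bin_width, by = bin_width)
  cut_counts <- function(v) {
    if (length(v) == 0L) return(integer(length(breaks) - 1L))
    tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)
  }
  overlap <- if (length(intra) && length(inter))
    mean(intra >= quantile(inter, 0.05)) else NA_real_
  structure(list(breaks = breaks,
                 intra_counts = cut_counts(intra),
                 inter_counts = cut_counts(inter),
                 bin_width = bin_width, overlap = overlap,
                 n_intra = length(intra), n_inter = length(inter)),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("<gap_profile>", x$n_intra, "intra /", x$n_inter, "inter pairs;",
      "overlap:", round(x$overlap, 3), "\n")
  invisible(x)
}

#' Write a gap profile's histogram data as TSV
#' @param profile a `gap_profile` from [barcoding_gap()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gap_profile <- function(profile, path) {
  out <- data.frame(bin_start = profile$breaks[-length(profile$breaks)],
                    intra_count = profile$intra_counts,
                    inter_count = profile$inter_counts)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties are mid-ranked. For n non-zero
#' differences up to `exact_max_n` the two-sided p-value is exact,
#' computed from the full null distribution of the positive rank sum
#' over all sign assignments (mid-ranks included); beyond that a normal
#' approximation with continuity and tie correction is used. The
#' reported direction (is `x` greater or less than `y`) follows the
#' sign of the median difference.
#'
#' @param x,y equal-length paired numeric samples.
#' @param exact_max_n largest n for which the exact null distribution is
#'   enumerated.
#' @return a `wilcoxon_result`: list with `w_plus`, `w_minus`, `n`,
#'   `p_value`, `direction` ("greater", "less" or "equal"), `exact`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
wilcoxon_signed_rank <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(w_plus = 0, w_minus = 0, n = 0L, p_value = 1,
                          direction = "equal", exact = TRUE),
                     class = "wilcoxon_result"))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_max_n) {
    p <- .wilcoxon_exact_p(r, w_plus)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    mu <- n * (n + 1) / 4
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  med <- median(x - y)
  direction <- if (med > 0) "greater" else if (med < 0) "less"
  else if (w_plus > w_minus) "greater" else if (w_plus < w_minus) "less"
  else "equal"
  structure(list(w_plus = w_plus, w_minus = w_minus, n = n, p_value = p,
                 direction = direction, exact = exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> W+ =", x$w_plus, "W- =", x$w_minus,
      "n =", x$n, "p =", signif(x$p_value, 4),
      "direction:", x$direction, "\n")
  invisible(x)
}

# Exact two-sided p for the signed-rank statistic with mid-ranks.
# Doubling the ranks makes them integers; the null distribution of
# 2*W+ is built by the usual generating-function convolution over
# independent sign flips.
.wilcoxon_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # index k+1 = P(2W+ = k) (unnormalized)
  dist[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), dist[seq_len(total + 1L - rk)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w_plus))
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Compare loci by paired signed-rank tests
#'
#' For every pair of loci, pairs the distances that belong to the same
#' unordered accession pair present in both loci (joined on the two
#' accession ids) and runs [wilcoxon_signed_rank()] on them, separately
#' for interspecific or intraspecific pairs. Locus pairs with fewer
#' than `min_pairs` common distance pairs are flagged as underpowered
#' and not tested.
#'
#' @param dms named list of `k2p_dm` objects, one per locus.
#' @param mode `"inter"` or `"intra"`.
#' @param min_pairs minimum number of common pairs to run a test.
#' @return a data frame with one row per locus pair: `locus_a`,
#'   `locus_b`, `n`, `w_plus`, `w_minus`, `p_value`, `direction`
#'   (e.g. `"ITS2 < psbA-trnH"`), `note`.
#' @export
compare_loci <- function(dms, mode = c("inter", "intra"), min_pairs = 4) {
  mode <- match.arg(mode)
  if (length(dms) < 2L) stop("compare_loci requires at least 2 loci")
  if (is.null(names(dms))) stop("dms must be a named list")
  want_consp <- mode == "intra"
  tabs <- lapply(dms, function(dm) {
    pt <- .pair_table(dm)
    pt <- pt[!is.na(pt$distance) & pt$conspecific == want_consp, ,
             drop = FALSE]
    key <- apply(cbind(pt$id_a, pt$id_b), 1,
                 function(p) paste(sort(p), collapse = "|"))
    stats::setNames(pt$distance, key)
  })
  combos <- combn(names(dms), 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    a <- tabs[[pr[1]]]
    b <- tabs[[pr[2]]]
    common <- intersect(names(a), names(b))
    if (length(common) < min_pairs)
      return(data.frame(locus_a = pr[1], locus_b = pr[2],
                        n = length(common), w_plus = NA_real_,
                        w_minus = NA_real_, p_value = NA_real_,
                        direction = NA_character_, note = "underpowered",
                        stringsAsFactors = FALSE))
    wt <- wilcoxon_signed_rank(a[common], b[common])
    dir_str <- switch(wt$direction,
                      greater = paste(pr[1], ">", pr[2]),
                      less = paste(pr[1], "<", pr[2]),
                      equal = paste(pr[1], "=", pr[2]))
    data.frame(locus_a = pr[1], locus_b = pr[2], n = wt$n,
               w_plus = wt$w_plus, w_minus = wt$w_minus,
               p_value = wt$p_value, direction = dir_str, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
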