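#' Configuration for a multi-locus evaluation run
#'
#' @param loci named list: one entry per locus, each a list with `fasta`
#'   (path) or `dataset` (a [locus_dataset()] supplied directly).
#' @param metadata path to a metadata TSV, or a metadata data frame;
#'   required when any locus is given as a FASTA path.
#' @param out_dir output directory; created if absent.
#' @param min_len,max_ambiguous,similarity_min,coverage_min QC
#'   parameters, see [qc_filter()].
#' @param bin_width barcoding-gap histogram bin width.
#' @param seed seed recorded in the outputs (the evaluation itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(loci, metadata = NULL, out_dir = tempfile("run"),
                       min_len = 100, max_ambiguous = 1,
                       similarity_min = 0.90, coverage_min = 0.90,
                       bin_width = 0.005, seed = 1) {
  stopifnot(is.list(loci), length(loci) >= 1L, !is.null(names(loci)))
  structure(list(loci = loci, metadata = metadata, out_dir = out_dir,
                 min_len = min_len, max_ambiguous = max_ambiguous,
                 similarity_min = similarity_min,
                 coverage_min = coverage_min, bin_width = bin_width,
                 seed = seed),
            class = "run_config")
}

#' Run the full barcode-evaluation pipeline
#'
#' For each locus: QC filtering, progressive alignment, K2P distance
#' matrix, locus summary, divergence parameters, barcoding-gap profile,
#' leave-one-out identification efficiencies (both methods, species and
#' genus level), neighbor-joining tree with monophyly report. Across
#' loci: paired signed-rank comparisons of the inter- and intraspecific
#' distance distributions. All tables are written as TSV into
#' `config$out_dir`, trees as newick, and a provenance file records the
#' producing operation for every output.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with per-locus results (`summary`,
#'   `divergence`, `gap`, `efficiency`, `monophyly`, `qc`) and the
#'   cross-locus comparison tables (`inter_comparison`,
#'   `intra_comparison`), plus `out_dir`.
#' @export
run_evaluation <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- config$metadata
  if (is.character(md)) md <- read_metadata(md)
  per_locus <- list()
  dms <- list()
  provenance <- list()
  note <- function(file, op) provenance[[file]] <<- op

  for (locus in names(config$loci)) {
    entry <- config$loci[[locus]]
    dataset <- if (!is.null(entry$dataset)) entry$dataset
      else read_fasta(entry$fasta, locus, md)
    step <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", what, "' failed for locus ", locus, ": ",
             conditionMessage(e), call. = FALSE))
    }
    qc <- step("qc_filter", qc_filter(dataset, config$min_len,
                                      config$max_ambiguous,
                                      config$similarity_min,
                                      config$coverage_min))
    dataset <- qc$dataset
    if (n_records(dataset) < 2L)
      stop("stage 'qc_filter' left fewer than 2 records for locus ",
           locus)
    msa <- step("progressive_msa", progressive_msa(dataset))
    summ <- step("summarize_locus", summarize_locus(dataset, msa))
    dm <- step("distance_matrix",
               distance_matrix(msa, dataset$records$species))
    dms[[locus]] <- dm
    multi_species <- length(unique(dataset$records$species)) >= 2L
    div <- if (multi_species)
      step("divergence_parameters", divergence_parameters(dm)) else NULL
    gap <- if (multi_species)
      step("barcoding_gap", barcoding_gap(dm, config$bin_width)) else NULL
    near <- step("identify_all",
                 identify_all(dm, method = "nearest_distance"))
    top <- step("identify_all", identify_all(dataset, method = "top_hit"))
    eff <- data.frame(
      method = rep(c("nearest_distance", "top_hit"), each = 2),
      level = rep(c("species", "genus"), 2),
      efficiency = c(efficiency(near, "species"),
                     efficiency(near, "genus"),
                     efficiency(top, "species"),
                     efficiency(top, "genus")))
    mono <- NULL
    if (n_records(dataset) >= 3L) {
      tree <- step("nj_tree", nj_tree(dm))
      mono <- step("monophyly_report", monophyly_report(tree))
      tree_file <- file.path(config$out_dir,
                             paste0(locus, "_nj.nwk"))
      write_newick(tree, tree_file)
      note(basename(tree_file), "nj_tree")
      mono_file <- file.path(config$out_dir,
                             paste0(locus, "_monophyly.tsv"))
      write_monophyly(mono, mono_file)
      note(basename(mono_file), "monophyly_report")
    }
    wr <- function(obj, suffix, op, writer = write.table) {
      f <- file.path(config$out_dir, paste0(locus, "_", suffix))
      if (identical(writer, write.table))
        write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
      else writer(obj, f)
      note(basename(f), op)
    }
    wr(summ, "summary.tsv", "summarize_locus")
    if (!is.null(div)) wr(div, "divergence.tsv", "divergence_parameters")
    if (!is.null(gap)) wr(gap, "gap_histogram.tsv", "barcoding_gap",
                          write_gap_profile)
    wr(eff, "efficiency.tsv", "efficiency")
    wr(rbind(near, top), "identification.tsv", "identify_all")
    wr(qc$report, "qc.tsv", "qc_filter", write_qc_report)
    per_locus[[locus]] <- list(summary = summ, divergence = div,
                               gap = gap, efficiency = eff,
                               monophyly = mono, qc = qc$report)
  }

  inter_cmp <- intra_cmp <- NULL
  if (length(dms) >= 2L) {
    inter_cmp <- compare_loci(dms, "inter")
    intra_cmp <- compare_loci(dms, "intra")
    f1 <- file.path(config$out_dir, "interspecific_comparison.tsv")
    write.table(inter_cmp, f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note(basename(f1), "compare_loci")
    f2 <- file.path(config$out_dir, "intraspecific_comparison.tsv")
    write.table(intra_cmp, f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note(basename(f2), "compare_loci")
  }
  prov <- data.frame(file = names(provenance),
                     operation = unlist(provenance),
                     seed = config$seed, stringsAsFactors = FALSE)
  write.table(prov, file.path(config$out_dir, "provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(per_locus = per_locus, inter_comparison = inter_cmp,
                 intra_comparison = intra_cmp, out_dir = config$out_dir))
}
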