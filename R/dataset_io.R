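#' Construct a locus dataset
#'
#' A locus dataset bundles the sequence records of one barcode locus with
#' their taxonomy. Records are kept as a data frame with one row per
#' accession; the genus is derived from the first whitespace-delimited
#' token of the species binomial.
#'
#' @param records data frame with columns `accession_id`, `species`,
#'   `sequence` and optionally `voucher`, `origin`.
#' @param locus locus name (e.g. "ITS2", "rbcL", "psbA-trnH").
#' @param provenance free-text note on where the data came from.
#' @return an object of class `locus_dataset`.
#' @export
locus_dataset <- function(records, locus, provenance = "") {
  stopifnot(is.data.frame(records),
            all(c("accession_id", "species", "sequence") %in% names(records)))
  records$sequence <- toupper(records$sequence)
  if (any(nchar(records$sequence) == 0L))
    stop("empty sequence in records: ",
         paste(records$accession_id[nchar(records$sequence) == 0L],
               collapse = ", "))
  bad <- vapply(records$sequence,
                function(s) any(!.chars(s) %in% .iupac), logical(1))
  if (any(bad))
    stop("non-IUPAC symbols in sequence(s): ",
         paste(records$accession_id[bad], collapse = ", "))
  dup <- duplicated(records$accession_id)
  if (any(dup))
    stop("duplicated accession ids: ",
         paste(unique(records$accession_id[dup]), collapse = ", "))
  if (is.null(records$voucher)) records$voucher <- NA_character_
  if (is.null(records$origin)) records$origin <- NA_character_
  records$genus <- vapply(strsplit(records$species, "\\s+"), `[`, "", 1L)
  rownames(records) <- NULL
  structure(list(locus = locus,
                 records = records[, c("accession_id", "species", "genus",
                                       "voucher", "origin", "sequence")],
                 provenance = provenance),
            class = "locus_dataset")
}

#' @export
print.locus_dataset <- function(x, ...) {
  cat("<locus_dataset> locus:", x$locus, "-", nrow(x$records), "records,",
      length(unique(x$records$species)), "species\n")
  invisible(x)
}

#' Number of records in a locus dataset
#' @param x a `locus_dataset`.
#' @return integer count of records.
#' @export
n_records <- function(x) nrow(x$records)

#' Read sequence metadata
#'
#' Reads a tab-separated metadata table with the fixed columns
#' `accession_id`, `species`, `locus`, `voucher`, `origin`.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("accession_id", "species", "locus")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  md
}

#' Accession metadata of the Uncaria barcoding study
#'
#' The packaged accession table of the five candidate barcode loci
#' (ITS2, rbcL, psbA-trnH, ITS and matK) sampled across the genus
#' Uncaria: 257 accession-by-locus entries from 89 vouchered samples of
#' 15 species, with GenBank accession numbers, voucher identifiers and
#' collection origins.
#'
#' @return a data frame with columns `accession_id`, `species`, `locus`,
#'   `voucher`, `origin`.
#' @export
#' @examples
#' md <- uncaria_metadata()
#' table(md$locus)
uncaria_metadata <- function() {
  read_metadata(system.file("extdata", "table1_metadata.tsv",
                            package = "barcodeGauge", mustWork = TRUE))
}

#' Read a FASTA file into a locus dataset
#'
#' Every FASTA identifier must resolve to a metadata row for the given
#' locus; species, voucher and origin are joined from the metadata.
#' Record order follows the FASTA file.
#'
#' @param path path to a FASTA file.
#' @param locus locus name; used to subset the metadata.
#' @param metadata data frame as returned by [read_metadata()].
#' @return a [locus_dataset()].
#' @export
read_fasta <- function(path, locus, metadata) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- names(seqs)
  md <- metadata[metadata$locus == locus, , drop = FALSE]
  missing <- setdiff(ids, md$accession_id)
  if (length(missing))
    stop("FASTA id(s) absent from metadata for locus ", locus, ": ",
         paste(missing, collapse = ", "))
  idx <- match(ids, md$accession_id)
  records <- data.frame(
    accession_id = ids,
    species = md$species[idx],
    voucher = if ("voucher" %in% names(md)) md$voucher[idx] else NA_character_,
    origin = if ("origin" %in% names(md)) md$origin[idx] else NA_character_,
    sequence = toupper(vapply(as.character(seqs),
                              paste, "", collapse = "")),
    stringsAsFactors = FALSE)
  locus_dataset(records, locus, provenance = paste("read from", path))
}

#' Write a locus dataset to FASTA
#'
#' @param dataset a [locus_dataset()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  lines <- character(0)
  for (i in seq_len(nrow(dataset$records))) {
    lines <- c(lines, paste0(">", dataset$records$accession_id[i]),
               dataset$records$sequence[i])
  }
  writeLines(lines, path)
  invisible(path)
}

# count of ambiguous symbols: anything that is not A/C/G/T and not a gap
.n_ambiguous <- function(seq) {
  ch <- .chars(seq)
  sum(!ch %in% c("A", "C", "G", "T", "-"))
}

# species-name markers indicating an undetermined taxon
.indeterminate_species <- function(species) {
  tokens <- strsplit(tolower(species), "\\s+")
  vapply(tokens, function(tk) any(tk %in% c("sp.", "spp.", "aff.", "cf.")),
         logical(1))
}

#' Quality-filter a locus dataset
#'
#' Applies the inclusion rules used when assembling congeneric barcode
#' datasets from public sequence repositories: minimum ungapped length,
#' a cap on ambiguous bases, exclusion of undetermined taxa ("sp.",
#' "spp.", "aff.", "cf." in the binomial), and a congener screen that
#' requires each record to reach both a minimum identity and a minimum
#' query-coverage against at least one conspecific record (records that
#' are the sole representative of their species pass the screen
#' vacuously).
#'
#' @param dataset a [locus_dataset()].
#' @param min_len minimum ungapped sequence length in bp.
#' @param max_ambiguous maximum number of ambiguous (non-ACGT, non-gap)
#'   symbols tolerated.
#' @param similarity_min minimum pairwise identity against the best
#'   conspecific match (fraction).
#' @param coverage_min minimum query coverage against the best
#'   conspecific match (fraction).
#' @return a list with elements `dataset` (the filtered
#'   [locus_dataset()]) and `report` (a `qc_report`: data frame of kept
#'   ids and a data frame of rejected ids with reason codes
#'   `"short"`, `"ambiguous"`, `"indeterminate_taxon"`,
#'   `"congener_screen"`).
#' @export
qc_filter <- function(dataset, min_len = 100, max_ambiguous = 1,
                      similarity_min = 0.90, coverage_min = 0.90) {
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("dataset is empty")
  ungapped <- gsub("-", "", rec$sequence, fixed = TRUE)
  len <- nchar(ungapped)
  n_amb <- vapply(ungapped, .n_ambiguous, integer(1))
  reason <- rep(NA_character_, nrow(rec))
  reason[.indeterminate_species(rec$species)] <- "indeterminate_taxon"
  reason[is.na(reason) & n_amb > max_ambiguous] <- "ambiguous"
  reason[is.na(reason) & len < min_len] <- "short"

  # congener screen among records passing the basic checks
  pass <- which(is.na(reason))
  sp <- rec$species[pass]
  for (s in unique(sp)) {
    members <- pass[sp == s]
    if (length(members) < 2L) next  # sole representative: vacuous pass
    stats <- .global_stats_cpp(ungapped[members], 1, -1, -5, -1)
    len <- nchar(ungapped[members])
    coverage <- stats$aligned / len  # per-row query coverage
    good <- stats$identity >= similarity_min & coverage >= coverage_min
    diag(good) <- FALSE
    ok <- apply(good, 1, any)
    reason[members[!ok]] <- "congener_screen"
  }

  keep <- is.na(reason)
  report <- structure(
    list(kept = rec$accession_id[keep],
         rejected = data.frame(accession_id = rec$accession_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)),
    class = "qc_report")
  filtered <- dataset
  filtered$records <- rec[keep, , drop = FALSE]
  rownames(filtered$records) <- NULL
  list(dataset = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", length(x$kept), "kept,", nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [qc_filter()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- rbind(
    data.frame(accession_id = report$kept, status = "kept",
               reason = NA_character_, stringsAsFactors = FALSE),
    if (nrow(report$rejected))
      data.frame(accession_id = report$rejected$accession_id,
                 status = "rejected", reason = report$rejected$reason,
                 stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-record GC fraction; ambiguous bases excluded from numerator and
# denominator, gaps ignored
.gc_fraction <- function(seq) {
  ch <- .chars(gsub("-", "", seq, fixed = TRUE))
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0L) return(NA_real_)
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Summarize a locus dataset
#'
#' Computes the per-locus description used to compare candidate barcodes:
#' species and accession counts, ungapped length range and mean, mean GC
#' content, and (when an alignment is supplied) the number of variable
#' sites and indel events.
#'
#' @param dataset a [locus_dataset()].
#' @param msa optional [multiple_alignment()] whose rows correspond 1:1
#'   to the dataset records; required for the site counts.
#' @return a one-row data frame (`locus_summary`).
#' @export
summarize_locus <- function(dataset, msa = NULL) {
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("dataset is empty")
  ungapped <- gsub("-", "", rec$sequence, fixed = TRUE)
  len <- nchar(ungapped)
  gc <- vapply(ungapped, .gc_fraction, numeric(1))
  n_var <- NA_integer_
  n_indel <- NA_integer_
  if (!is.null(msa)) {
    if (length(msa$rows) != nrow(rec))
      stop("msa rows do not correspond 1:1 to dataset records")
    n_var <- count_variable_sites(msa)
    n_indel <- count_indel_sites(msa)
  }
  structure(data.frame(
    locus = dataset$locus,
    n_species = length(unique(rec$species)),
    n_accessions = nrow(rec),
    length_min = min(len),
    length_max = max(len),
    length_mean = mean(len),
    gc_mean = 100 * mean(gc, na.rm = TRUE),
    n_variable_sites = n_var,
    n_indel_sites = n_indel,
    stringsAsFactors = FALSE), class = c("locus_summary", "data.frame"))
}
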