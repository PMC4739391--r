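test_that("FASTA reading round-trips records and joins metadata", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">X1", "ACGTACGTACGT", ">X2", "acgtTTTTacgt"), fa)
  md <- data.frame(accession_id = c("X1", "X2"),
                   species = c("Genus alpha", "Genus beta"),
                   locus = "ITS2", voucher = c("v1", NA),
                   origin = c("here", "there"),
                   stringsAsFactors = FALSE)
  ds <- read_fasta(fa, "ITS2", md)
  expect_s3_class(ds, "locus_dataset")
  expect_equal(n_records(ds), 2L)
  expect_equal(ds$records$accession_id, c("X1", "X2"))
  expect_equal(ds$records$sequence[2], "ACGTTTTTACGT")  # upper-cased
  expect_equal(ds$records$genus, c("Genus", "Genus"))

  out <- tempfile(fileext = ".fasta")
  write_fasta(ds, out)
  back <- read_fasta(out, "ITS2", md)
  expect_equal(back$records$sequence, ds$records$sequence)
})

test_that("FASTA ids absent from the metadata are a named hard error", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">KM999999", "ACGT"), fa)
  md <- data.frame(accession_id = "OTHER", species = "Genus alpha",
                   locus = "ITS2", stringsAsFactors = FALSE)
  expect_error(read_fasta(fa, "ITS2", md), "KM999999")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(suppressWarnings(read_fasta(empty, "ITS2", md)))
})

test_that("sequence validation rejects bad alphabets and duplicates", {
  expect_error(make_dataset(c("ACGT", "ACZT"), c("G a", "G a")),
               "non-IUPAC")
  expect_error(
    locus_dataset(data.frame(accession_id = c("A1", "A1"),
                             species = "G a",
                             sequence = "ACGT"), "x"),
    "duplicated")
})

test_that("qc_filter applies the published inclusion rules", {
  seqs <- c(
    strrep("ACGT", 50),                 # fine
    strrep("ACGT", 50),                 # identical conspecific: both kept
    strrep("A", 99),                    # 99 bp: short
    paste0(strrep("ACGT", 40), "NN"),   # two Ns: ambiguous
    strrep("ACGT", 50))
  ds <- make_dataset(seqs,
                     c("Uncaria alpha", "Uncaria alpha", "Uncaria alpha",
                       "Uncaria alpha", "Uncaria sp."))
  res <- qc_filter(ds)
  rej <- res$report$rejected
  expect_setequal(res$report$kept, c("ACC001", "ACC002"))
  expect_equal(rej$reason[rej$accession_id == "ACC003"], "short")
  expect_equal(rej$reason[rej$accession_id == "ACC004"], "ambiguous")
  expect_equal(rej$reason[rej$accession_id == "ACC005"],
               "indeterminate_taxon")
  # kept and rejected partition the input ids
  expect_setequal(c(res$report$kept, rej$accession_id),
                  ds$records$accession_id)
})

test_that("qc congener screen drops records unlike all conspecifics", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  ds <- make_dataset(c(base, base, other),
                     rep("Uncaria alpha", 3))
  res <- qc_filter(ds)
  expect_setequal(res$report$kept, c("ACC001", "ACC002"))
  expect_equal(res$report$rejected$reason, "congener_screen")
  # sole representatives pass the screen vacuously
  ds2 <- make_dataset(c(base, other),
                      c("Uncaria alpha", "Uncaria beta"))
  expect_equal(length(qc_filter(ds2)$report$kept), 2L)
})

test_that("qc filtering is idempotent", {
  set.seed(12)
  pool <- replicate(6, paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                             collapse = ""))
  pool[2] <- strrep("T", 80)
  pool[4] <- paste0(substr(pool[4], 1, 140), "NNNNNNNNNN")
  ds <- make_dataset(pool, rep(c("Uncaria alpha", "Uncaria beta"), 3))
  once <- qc_filter(ds)
  twice <- qc_filter(once$dataset)
  expect_equal(twice$dataset$records, once$dataset$records)
  expect_equal(nrow(twice$report$rejected), 0L)
})

test_that("locus summary reports lengths, GC and site counts", {
  s <- summarize_locus(make_dataset("ACGT", "G a"))
  expect_equal(c(s$length_min, s$length_mean, s$length_max), c(4, 4, 4))
  expect_equal(s$gc_mean, 50)

  s2 <- summarize_locus(make_dataset(c("GGGG", "CCCC"), c("G a", "G b")))
  expect_equal(s2$gc_mean, 100)

  # invariance to record order and case
  ds_a <- make_dataset(c("ACGTAC", "GGCCAA"), c("G a", "G b"))
  ds_b <- make_dataset(c("ggccaa", "acgtac"), c("G b", "G a"))
  expect_equal(summarize_locus(ds_a)$gc_mean,
               summarize_locus(ds_b)$gc_mean)

  # k copies of one sequence: degenerate length range
  ds_k <- make_dataset(rep("ACGTACGT", 4), rep("G a", 4))
  sk <- summarize_locus(ds_k)
  expect_equal(sk$length_min, sk$length_max)

  # ambiguous bases excluded from the GC computation entirely
  expect_equal(summarize_locus(make_dataset("GCNN", "G a"))$gc_mean, 100)

  msa <- multiple_alignment(c("ACGT", "ACGA"), c("r1", "r2"))
  ds2r <- make_dataset(c("ACGT", "ACGA"), c("G a", "G b"))
  sm <- summarize_locus(ds2r, msa)
  expect_equal(sm$n_variable_sites, 1L)
  expect_error(summarize_locus(ds_k, msa), "1:1")
})

test_that("the packaged accession table matches its published margins", {
  md <- uncaria_metadata()
  expect_equal(nrow(md), 257L)
  expect_equal(sum(md$locus == "ITS2"), 77L)
  expect_equal(length(unique(md$species[md$locus == "ITS2"])), 14L)
  expect_equal(length(unique(md$species)), 15L)
  # per-locus accession and species counts
  expect_equal(as.vector(table(md$locus)[c("ITS2", "rbcL", "psbA-trnH",
                                           "ITS", "matK")]),
               c(77L, 63L, 49L, 58L, 10L))
  spn <- vapply(split(md$species, md$locus),
                function(s) length(unique(s)), integer(1))
  expect_equal(as.vector(spn[c("ITS2", "rbcL", "psbA-trnH", "ITS",
                               "matK")]),
               c(14L, 15L, 10L, 14L, 7L))
  # accession ids unique within each locus
  expect_false(any(vapply(split(md$accession_id, md$locus),
                          anyDuplicated, integer(1)) > 0))
})
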