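test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- simulation_config(n_species = 4, accessions_per_species = 3,
                           root_length = 250, seed = 81,
                           planted_features = list(
                             list(species = 1, kind = "tandem_repeat")))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth_features, b$truth_features)
  fa <- tempfile(); fb <- tempfile()
  write_fasta(a$dataset, fa)
  write_fasta(b$dataset, fb)
  expect_identical(readLines(fa), readLines(fb))
  # and a different seed does not
  c2 <- simulate_dataset(simulation_config(
    n_species = 4, accessions_per_species = 3, root_length = 250,
    seed = 82, planted_features = list(
      list(species = 1, kind = "tandem_repeat"))))
  expect_false(identical(a$dataset$records$sequence,
                         c2$dataset$records$sequence))
})

test_that("species tree geometry tracks the divergence targets", {
  cfg <- simulation_config(n_species = 10, accessions_per_species = 3,
                           target_intra = 0.006, target_inter = 0.05,
                           seed = 83)
  paths <- c()
  depths <- c()
  for (s in 1:5) {
    cfg$seed <- 83 + s
    tr <- simulate_species_tree(cfg)
    cop <- ape::cophenetic.phylo(tr)
    sp <- attr(tr, "species")[rownames(cop)]
    same <- outer(sp, sp, "==")
    ut <- upper.tri(cop)
    paths <- c(paths, cop[ut & !same])
    depths <- c(depths, cop[ut & same])
  }
  expect_lt(abs(mean(paths) - 0.05) / 0.05, 0.10)
  expect_lt(abs(mean(depths) - 0.006) / 0.006, 0.10)
})

test_that("degenerate configurations behave as documented", {
  # two species with one accession each: a two-tip tree, path = inter
  cfg <- simulation_config(n_species = 2, accessions_per_species = 1,
                           target_intra = 0, target_inter = 0.04,
                           seed = 84)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sum(tr$edge.length), 0.04, tolerance = 0.25)

  # zero intraspecific depth: conspecific tips are identical
  cfg0 <- simulation_config(n_species = 3, accessions_per_species = 3,
                            target_intra = 0, target_inter = 0.05,
                            indel_rate = 0, seed = 85)
  sim0 <- simulate_dataset(cfg0)
  sp <- sim0$dataset$records$species
  for (s in unique(sp)) {
    seqs <- sim0$dataset$records$sequence[sp == s]
    expect_equal(length(unique(seqs)), 1L)
  }

  # zero-length branches: all sequences equal the root
  flat <- ape::read.tree(text = "((x:0,y:0):0,z:0);")
  dsf <- evolve_sequences(flat, simulation_config(
    n_species = 2, accessions_per_species = 1, root_length = 200,
    target_intra = 0.001, target_inter = 0.01, seed = 86))
  expect_equal(length(unique(dsf$records$sequence)), 1L)
})

test_that("root composition honors the GC target", {
  cfg <- simulation_config(n_species = 5, accessions_per_species = 2,
                           root_length = 500, gc_target = 0.66,
                           target_intra = 0.001, target_inter = 0.01,
                           indel_rate = 0, seed = 87)
  sim <- simulate_dataset(cfg)
  gc <- vapply(sim$dataset$records$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  expect_lt(abs(100 * mean(gc) - 66), 2)
})

test_that("realized divergences land near the configured targets", {
  cfg <- sim_preset("psbA-trnH", n_species = 8,
                    accessions_per_species = 3, seed = 88)
  sim <- simulate_dataset(cfg)
  msa <- progressive_msa(sim$dataset)
  dm <- distance_matrix(msa, sim$dataset$records$species)
  dv <- divergence_parameters(dm)
  intra <- dv$mean[dv$parameter == "all_intra"]
  inter <- dv$mean[dv$parameter == "all_inter"]
  expect_lt(abs(intra - 0.048) / 0.048, 0.25)
  expect_lt(abs(inter - 0.107) / 0.107, 0.25)
})

test_that("truth report states expectations and the efficiency rule", {
  cfg <- simulation_config(target_intra = 0.005, target_inter = 0.035,
                           seed = 1)
  tr <- truth_report(cfg)
  expect_equal(tr$expected_all_intra, 0.005)
  expect_equal(tr$expected_all_inter, 0.035)
  expect_equal(tr$expected_efficiency, 100)  # ratio 7 >= 5

  low <- truth_report(simulation_config(target_intra = 0.02,
                                        target_inter = 0.021, seed = 1))
  expect_true(is.na(low$expected_efficiency))
  expect_false(low$efficiency_predicted)
})

test_that("presets encode the two locus regimes", {
  its2 <- sim_preset("ITS2")
  expect_equal(c(its2$target_intra, its2$target_inter), c(0.006, 0.035))
  expect_equal(c(its2$gc_target, its2$root_length), c(0.66, 220))
  psba <- sim_preset("psbA-trnH", seed = 9)
  expect_equal(c(psba$target_intra, psba$target_inter), c(0.048, 0.107))
  expect_equal(psba$seed, 9)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(target_intra = 0.05,
                                 target_inter = 0.02))
  expect_error(simulation_config(gc_target = 0))
  expect_error(simulation_config(kappa = -1))
})
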