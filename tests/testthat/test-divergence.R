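test_that("divergence parameters match a hand-enumerated two-species case", {
  # 2 species x 2 accessions: intra = 0.01 in both species, inter = 0.10
  d <- matrix(0.10, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0.01
  dm <- make_dm(d, c("G a", "G a", "G b", "G b"))
  dv <- divergence_parameters(dm)
  get <- function(p, col = "mean") dv[dv$parameter == p, col]
  expect_equal(get("theta"), 0.01)
  expect_equal(get("all_intra"), 0.01)
  expect_equal(get("coalescent_depth"), 0.01)
  expect_equal(get("theta_prime"), 0.10)
  expect_equal(get("min_inter"), 0.10)
  expect_equal(get("all_inter"), 0.10)
  expect_equal(sum(dv$sd), 0)
  expect_equal(get("all_intra", "n"), 2)
  expect_equal(get("all_inter", "n"), 4)
})

test_that("an all-zero matrix gives all-zero parameters", {
  dm <- make_dm(matrix(0, 4, 4), c("G a", "G a", "G b", "G b"))
  dv <- divergence_parameters(dm)
  expect_equal(dv$mean, rep(0, 6))
})

test_that("singleton species only contribute interspecific parameters", {
  d <- matrix(0.2, 3, 3)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.02
  dm <- make_dm(d, c("G a", "G a", "G b"))
  dv <- divergence_parameters(dm)
  expect_equal(dv[dv$parameter == "theta", "n"], 1)        # only species a
  expect_equal(dv[dv$parameter == "theta_prime", "n"], 2)  # both species
  # no multi-accession species at all: intraspecific fields flagged NA
  dm2 <- make_dm(matrix(c(0, .1, .1, 0), 2), c("G a", "G b"))
  dv2 <- divergence_parameters(dm2)
  expect_true(is.na(dv2[dv2$parameter == "theta", "mean"]))
  expect_false(is.na(dv2[dv2$parameter == "all_inter", "mean"]))
})

test_that("coalescent depth dominates mean intraspecific distance", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 9
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.2)
    d <- d + t(d)
    dm <- make_dm(d, rep(c("G a", "G b", "G c"), each = 3))
    dv <- divergence_parameters(dm)
    expect_gte(dv[dv$parameter == "coalescent_depth", "mean"],
               dv[dv$parameter == "theta", "mean"])
  }
})

test_that("barcoding gap overlap separates gapped from gapless loci", {
  d <- matrix(0.1, 6, 6)
  diag(d) <- 0
  sp <- rep(c("G a", "G b", "G c"), each = 2)
  for (i in c(1, 3, 5)) d[i, i + 1] <- d[i + 1, i] <- 0
  gp <- barcoding_gap(make_dm(d, sp))
  expect_equal(gp$overlap, 0)
  expect_equal(sum(gp$intra_counts), gp$n_intra)
  expect_equal(sum(gp$inter_counts), gp$n_inter)

  # identical intra and inter distributions: overlap near 1
  set.seed(42)
  n <- 12
  d2 <- matrix(0, n, n)
  d2[upper.tri(d2)] <- runif(n * (n - 1) / 2, 0.01, 0.05)
  d2 <- d2 + t(d2)
  gp2 <- barcoding_gap(make_dm(d2, rep(c("G a", "G b", "G c"), 4)))
  expect_gt(gp2$overlap, 0.8)
})

test_that("signed-rank test handles zeros, ties and the textbook case", {
  same <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "equal")

  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w$w_plus, 15)
  expect_equal(w$w_minus, 0)
  expect_equal(w$p_value, 2 / 32)        # 2^5 sign patterns, one extreme
  expect_equal(w$direction, "greater")

  # mid-ranks: w+ + w- is always n(n+1)/2
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- sample(0:4, n, TRUE)
    y <- sample(0:4, n, TRUE)
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$w_plus + r$w_minus, r$n * (r$n + 1) / 2)
  }
})

test_that("exact signed-rank p matches the sign-enumeration oracle", {
  set.seed(44)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    x <- sample(0:5, n, TRUE)
    y <- sample(0:5, n, TRUE)
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_value, oracle_signed_rank_p(x, y),
                 tolerance = 1e-12, info = paste(rep))
  }
})

test_that("large samples switch to the corrected normal approximation", {
  set.seed(45)
  x <- runif(60)
  y <- x + rnorm(60, 0.15, 0.1)
  r <- wilcoxon_signed_rank(x, y)
  expect_false(r$exact)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$direction, "less")
})

test_that("locus comparison pairs shared accession pairs and ranks loci", {
  set.seed(46)
  n <- 10
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 0.1)
  d <- d + t(d)
  sp <- rep(c("G a", "G b"), each = 5)
  dm_a <- make_dm(d, sp)
  dm_b <- make_dm(2 * d, sp)

  equal_cmp <- compare_loci(list(L1 = dm_a, L2 = dm_a), "inter")
  expect_match(equal_cmp$direction, "=")

  cmp <- compare_loci(list(A = dm_a, B = dm_b), "inter")
  expect_match(cmp$direction, "A < B", fixed = TRUE)
  expect_lt(cmp$p_value, 0.05)
  expect_gte(cmp$n, 20)

  # antisymmetry: swapping the loci flips direction, keeps p
  rev_cmp <- compare_loci(list(B = dm_b, A = dm_a), "inter")
  expect_match(rev_cmp$direction, "B > A", fixed = TRUE)
  expect_equal(rev_cmp$p_value, cmp$p_value)

  # too few common pairs: flagged, not computed
  dm_small <- make_dm(d[1:3, 1:3], sp[1:3],
                      ids = c("ACC001", "ACC002", "ACC999"))
  under <- compare_loci(list(A = dm_a, S = dm_small), "intra")
  expect_equal(under$note, "underpowered")
  expect_true(is.na(under$p_value))
})

test_that("simulated loci with ordered divergences are ranked correctly", {
  cfgs <- list(
    lo = simulation_config(n_species = 5, accessions_per_species = 3,
                           root_length = 250, target_intra = 0.004,
                           target_inter = 0.02, indel_rate = 0, seed = 5),
    hi = simulation_config(n_species = 5, accessions_per_species = 3,
                           root_length = 250, target_intra = 0.004,
                           target_inter = 0.09, indel_rate = 0, seed = 5))
  dms <- lapply(cfgs, function(cf) {
    sim <- simulate_dataset(cf)
    msa <- multiple_alignment(sim$dataset$records$sequence,
                              sim$dataset$records$accession_id)
    distance_matrix(msa, sim$dataset$records$species)
  })
  cmp <- compare_loci(dms, "inter")
  expect_match(cmp$direction, "lo < hi", fixed = TRUE)
  expect_lt(cmp$p_value, 0.01)
})
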