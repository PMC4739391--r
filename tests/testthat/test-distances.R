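test_that("pairwise comparison classifies differences under pairwise deletion", {
  c1 <- compare_pair("ACGT", "ACGT")
  expect_equal(c(c1$P, c1$Q, c1$L), c(0, 0, 4))

  c2 <- compare_pair("ACGT", "GCGT")
  expect_equal(c(c2$P, c2$Q), c(0.25, 0))  # A<->G is a transition

  c3 <- compare_pair("AC-T", "ACGT")
  expect_equal(c(c3$P, c3$Q, c3$L), c(0, 0, 3))

  c4 <- compare_pair("ACNT", "ACGA")      # N column skipped; T/A transversion
  expect_equal(c(c4$Q, c4$L), c(1 / 3, 3))

  c5 <- compare_pair("----", "ACGT")
  expect_false(c5$defined)
  expect_equal(c5$L, 0L)
  expect_error(compare_pair("ACG", "ACGT"), "equal-length")
})

test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-15)
  expect_true(is.na(k2p_distance(0.5, 0)))   # 1 - 2P - Q = 0
  expect_true(is.na(k2p_distance(0.1, 0.5))) # 1 - 2Q = 0
  # comparison-list form
  expect_equal(k2p_distance(compare_pair("ACGT", "GCGT")),
               -0.5 * log(1 - 0.5) - 0.25 * log(1))
})

test_that("K2P dominates the p-distance and is monotone in P and Q", {
  grid <- expand.grid(P = seq(0.01, 0.25, length.out = 8),
                      Q = seq(0.01, 0.2, length.out = 8))
  grid <- grid[1 - 2 * grid$P - grid$Q > 0.05, ]
  d <- k2p_distance(grid$P, grid$Q)
  expect_true(all(d >= grid$P + grid$Q))
  expect_true(all(k2p_distance(grid$P + 0.01, grid$Q) > d))
  expect_true(all(k2p_distance(grid$P, grid$Q + 0.01) > d))
  expect_equal(k2p_distance(0, 0), 0)
})

test_that("distance matrix agrees entry-wise with the scalar pipeline", {
  set.seed(31)
  for (rep in 1:5) {
    rows <- replicate(4, paste(sample(c("A", "C", "G", "T", "-", "N"), 30,
                                      TRUE, prob = c(rep(0.23, 4), .04, .04)),
                               collapse = ""))
    msa <- multiple_alignment(rows, paste0("r", 1:4))
    dm <- distance_matrix(msa, rep(c("G a", "G b"), 2))
    m <- as.matrix(msa)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        expected <- k2p_distance(compare_pair(
          paste(m[i, ], collapse = ""), paste(m[j, ], collapse = "")))
        expect_equal(dm$d[i, j], expected, info = paste(rep, i, j))
        expect_equal(dm$d[j, i], dm$d[i, j])
      }
    }
    expect_equal(unname(diag(dm$d)), rep(0, 4))
  }
})

test_that("identical rows give an all-zero matrix", {
  msa <- multiple_alignment(rep("ACGTACGT", 3), paste0("r", 1:3))
  dm <- distance_matrix(msa, rep("G a", 3))
  expect_true(all(dm$d == 0))
  expect_equal(overall_mean_distance(dm), 0)
})

test_that("overall mean distance averages each unordered pair once", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.1
  d[1, 3] <- d[3, 1] <- 0.2
  d[2, 3] <- d[3, 2] <- 0.3
  dm <- make_dm(d, c("a", "b", "c"))
  expect_equal(overall_mean_distance(dm), 0.2)
})

test_that("complete deletion drops every gapped or ambiguous column", {
  msa <- multiple_alignment(c("ACGTA", "AC-TA", "GCGTA"), paste0("r", 1:3))
  dmp <- distance_matrix(msa, letters[1:3])
  dmc <- distance_matrix(msa, letters[1:3], deletion = "complete")
  # pairwise: rows 1 and 3 still compare at the (matching) gapped
  # column, diluting the single difference relative to complete deletion
  expect_lt(dmp$d[1, 3], dmc$d[1, 3])
  expect_equal(dmc$d[1, 2], dmp$d[1, 2])
})

test_that("estimated distances recover the simulated divergence", {
  # two tips at path length 0.1, kappa = 2: the K2P estimator should be
  # unbiased; check the Monte Carlo mean against 3 standard errors
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  est <- vapply(1:150, function(i) {
    cfg <- simulation_config(n_species = 2, accessions_per_species = 1,
                             root_length = 500, kappa = 2,
                             target_intra = 0.01, target_inter = 0.1,
                             indel_rate = 0, seed = 4000 + i)
    ds <- evolve_sequences(tr, cfg)
    k2p_distance(compare_pair(ds$records$sequence[1],
                              ds$records$sequence[2]))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.1), 3 * se)
})

test_that("distance matrices survive a TSV round trip", {
  msa <- multiple_alignment(c("ACGTACGT", "ACGAACGT", "TCGAACGA"),
                            paste0("r", 1:3))
  dm <- distance_matrix(msa, letters[1:3])
  f <- tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               unname(dm$d), ignore_attr = TRUE, tolerance = 1e-9)
})
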