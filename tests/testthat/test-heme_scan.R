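test_that("scanner resolves planted and nested motifs with the greedy rule", {
  h <- scan_protein("MCAACHK")
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif_class, "CXXCH")
  expect_equal(h$start, 1L)
  # leftmost rule: CX3CH at 0 suppresses the CXXCH nested at 1
  h <- scan_protein("CCACCH")
  expect_equal(h$motif_class, "CX3CH")
  expect_equal(h$start, 0L)
  h <- scan_protein("CAACHCAAACH")
  expect_equal(h$motif_class, c("CXXCH", "CX3CH"))
  expect_equal(h$start, c(0L, 5L))
  expect_equal(nrow(scan_protein("")), 0L)
  # '*' blocks motifs; ambiguity codes match wildcards but never anchors
  expect_equal(nrow(scan_protein("CA*CH")), 0L)
  expect_equal(nrow(scan_protein("CXXCH")), 1L)
  expect_equal(nrow(scan_protein("CXXXH")), 0L)  # X is not an anchor C
})

test_that("greedy scanner equals the brute-force oracle on random sequences", {
  set.seed(402)
  for (i in 1:2000) {
    s <- random_protein(sample(0:120, 1L))
    expect_identical(scan_protein(s), oracle_scan(s), label = s)
  }
})

test_that("hits never overlap and counts are append-monotone", {
  set.seed(403)
  for (i in 1:300) {
    s <- random_protein(sample(10:200, 1L))
    h <- scan_protein(s)
    if (nrow(h) > 1L)
      expect_true(all(h$start[-1L] >= (h$start + h$span)[-nrow(h)]))
    s2 <- paste0(s, random_protein(sample(1:30, 1L)))
    expect_gte(nrow(scan_protein(s2)), nrow(h))
  }
})

test_that("planted motifs separated by non-motif residues are recovered exactly", {
  set.seed(404)
  sim <- simulate_cohort(simulation_config(seed = 51L, n_per_group = 1L))
  truth <- sim$truth$proteins
  for (g in sim$genomes) {
    pr <- profile_genome(g)$profiles
    tp <- truth[truth$genome_id == g$genome_id, ]
    got <- setNames(rep(0L, nrow(tp)), tp$protein_id)
    got[pr$protein_id] <- pr$total_hemes
    expect_identical(unname(got), tp$total_hemes)
  }
})

test_that("profiles bin by total hemes and summaries are consistent", {
  ten_hemes <- paste(rep("CAACH", 10L), collapse = "AAA")
  g <- toy_genome("G", c(mono = "MCAACHK", deca = ten_hemes,
                         none = "MKLVVV"))
  pg <- profile_genome(g)
  expect_equal(nrow(pg$profiles), 2L)
  expect_equal(pg$profiles$category[pg$profiles$protein_id == "mono"], "1")
  expect_equal(pg$profiles$category[pg$profiles$protein_id == "deca"], "10+")
  expect_true(pg$profiles$is_mhc[pg$profiles$protein_id == "deca"])
  expect_equal(sum(pg$summary$histogram), pg$summary$n_motif_proteins)
  expect_error(profile_genome(g, bin_edges = c(3, 1)), "increasing")
  # zero motif-bearing proteins: empty profiles, all-zero histogram
  pg0 <- profile_genome(toy_genome("G0", c(a = "MKLVVV")))
  expect_equal(nrow(pg0$profiles), 0L)
  expect_true(all(pg0$summary$histogram == 0L))
})

test_that("heme ratio is the ratio of group means with guarded errors", {
  two <- function(id, n_motif) {
    seqs <- c(rep("MCAACHK", n_motif), "MKLVVV")
    names(seqs) <- c(sprintf("m%d", seq_len(n_motif)), "bg")
    toy_genome(id, seqs)
  }
  a <- list(two("a1", 3L), two("a2", 3L))
  b <- list(two("b1", 2L), two("b2", 2L))
  r <- cohort_heme_ratio(a, b)
  expect_equal(r$ratio, 1.5)
  expect_equal(cohort_heme_ratio(a, a)$ratio, 1)
  none <- list(toy_genome("z", c(a = "MKLVVV")))
  expect_error(cohort_heme_ratio(a, none), "denominator")
  expect_error(cohort_heme_ratio(list(), b), "non-empty")
})
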