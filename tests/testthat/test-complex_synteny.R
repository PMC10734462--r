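catalog <- reference_catalog()
defs <- complex_definitions()

test_that("fixture loci yield the expected verdicts", {
  cases <- list(c("minimal-pcc3", "PCC3", "complete"),
                c("pcc3-two-periplasmic", "PCC3", "complete-variant"),
                c("mto-with-mtrc", "Mto", "complete"),
                c("uet-no-porin", "Uet", "complete"))
  for (cs in cases) {
    fx <- make_fixture(cs[1])
    g <- fx$genomes[[1]]
    call <- call_complex(g, defs[[cs[2]]], catalog = catalog)
    expect_equal(call$verdict, cs[3], label = cs[1])
  }
  # MtrC rides along as an optional subunit of the Mto call
  fx <- make_fixture("mto-with-mtrc")
  call <- call_complex(fx$genomes[[1]], defs$Mto, catalog = catalog)
  expect_true("mtrC" %in% names(call$subunit_map))
  expect_error(make_fixture("nope"), "registry")
})

test_that("role candidates respect heme-count constraints", {
  fx <- make_fixture("uet-no-porin")
  g <- fx$genomes[[1]]
  hits <- find_role_candidates(g, "uetJ", catalog)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$total_hemes, 11L)
  # same homolog rejected when an impossible heme window is demanded
  none <- find_role_candidates(g, "uetJ", catalog, min_hemes = 20L)
  expect_equal(nrow(none), 0L)
  empty <- find_role_candidates(g, "mtoA", catalog)
  expect_equal(nrow(empty), 0L)
  expect_error(find_role_candidates(g, "not_a_role", catalog), "role")
})

test_that("deleting subunits downgrades verdicts monotonically", {
  fx <- make_fixture("minimal-pcc3")
  g <- fx$genomes[[1]]
  rank_of <- c(absent = 0L, partial = 1L, complete = 2L,
               "complete-variant" = 2L)
  base <- rank_of[call_complex(g, defs$PCC3, catalog = catalog)$verdict]
  porin <- fx$truth$proteins$protein_id[
    fx$truth$proteins$family == "pcc3_porin"]
  g1 <- drop_protein(g, porin)
  v1 <- call_complex(g1, defs$PCC3, catalog = catalog)$verdict
  expect_equal(v1, "partial")
  expect_lte(rank_of[v1], base)
  cyt <- fx$truth$proteins$protein_id[
    fx$truth$proteins$family != "filler"]
  g0 <- Reduce(drop_protein, cyt, g)
  v0 <- call_complex(g0, defs$PCC3, catalog = catalog)$verdict
  expect_equal(v0, "absent")
})

test_that("widening the window never downgrades a verdict", {
  fx <- make_fixture("minimal-pcc3")
  g <- fx$genomes[[1]]
  # spread the operon: move the porin far from the anchor
  p <- g$proteins
  porin <- fx$truth$proteins$protein_id[
    fx$truth$proteins$family == "pcc3_porin"]
  p$rank[p$protein_id == porin] <- 40L
  p$start[p$protein_id == porin] <- 80001L
  g$proteins <- p[order(p$contig_id, p$start), ]
  rank_of <- c(absent = 0L, partial = 1L, complete = 2L,
               "complete-variant" = 2L)
  verdicts <- vapply(c(5L, 15L, 60L), function(w) {
    d <- complex_definitions(window = w)$PCC3
    call_complex(g, d, catalog = catalog)$verdict
  }, character(1))
  expect_equal(verdicts, c("partial", "partial", "complete"))
  expect_true(all(diff(rank_of[verdicts]) >= 0))
})

test_that("synteny is required: subunits on different contigs stay partial", {
  fx <- make_fixture("minimal-pcc3")
  g <- fx$genomes[[1]]
  p <- g$proteins
  porin <- fx$truth$proteins$protein_id[
    fx$truth$proteins$family == "pcc3_porin"]
  p$contig_id[p$protein_id == porin] <- "contig_2"
  p$rank <- as.integer(stats::ave(seq_len(nrow(p)), p$contig_id,
                                  FUN = seq_along)) - 1L
  g$proteins <- p
  expect_equal(call_complex(g, defs$PCC3, catalog = catalog)$verdict,
               "partial")
})

test_that("cohort verdict matrix matches planted truth", {
  sim <- simulate_cohort(simulation_config(seed = 71L, n_per_group = 2L))
  cx <- cohort_complex_matrix(sim$genomes, catalog = catalog)
  truth <- sim$truth$complexes
  for (cn in names(defs)) {
    expect_equal(cx$matrix[[cn]],
                 truth[[cn]][match(cx$matrix$genome_id, truth$genome_id)],
                 label = cn)
  }
  vsum <- cx$summary
  expect_equal(sum(vsum[vsum$complex == "Cyc2", -1]), length(sim$genomes))
  empty <- cohort_complex_matrix(list(), catalog = catalog)
  expect_equal(nrow(empty$matrix), 0L)
})
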