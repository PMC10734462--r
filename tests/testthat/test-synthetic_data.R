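test_that("simulation is byte-identical for a fixed seed", {
  cfg <- simulation_config(seed = 121L, n_per_group = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("config validation and the motif-budget accounting hold", {
  expect_error(simulation_config(), "seed")
  cfg <- simulation_config(seed = 1L)
  expect_s3_class(cfg, "simulation_config")
  bad <- simulation_config(seed = 1L)
  bad$complex_prevalence[1, 1] <- 2
  expect_error(with(bad, stopifnot(all(complex_prevalence <= 1))))
  # planted motif-protein means track the configured FeOB:NOB ratio
  sim <- simulate_cohort(simulation_config(seed = 131L, n_per_group = 12L))
  tp <- sim$truth$proteins
  gr <- sim$truth$groups
  cnt <- tapply(tp$total_hemes > 0, tp$genome_id, sum)
  mean_f <- mean(cnt[gr$genome_id[gr$is_feob]])
  mean_n <- mean(cnt[gr$genome_id[!gr$is_feob]])
  expect_gt(mean_f / mean_n, 1.15)   # well above parity at ratio 1.5
})

test_that("zero divergence collapses groups to identical planted genes and perfect clustering", {
  cfg <- simulation_config(seed = 141L, n_per_group = 2L,
                           gene_divergence = 0)
  sim <- simulate_cohort(cfg)
  genomes <- sim$genomes
  hemes <- profile_cohort(genomes)
  seqs <- do.call(rbind, lapply(genomes, function(g)
    data.frame(protein_id = g$proteins$protein_id, genome_id = g$genome_id,
               sequence = g$proteins$sequence, stringsAsFactors = FALSE)))
  motif <- seqs[seqs$protein_id %in% hemes$profiles$protein_id, ]
  cl <- greedy_cluster(motif, similarity_edges(motif))
  truth <- sim$truth$proteins
  fam <- truth$family[match(cl$protein_id, truth$protein_id)]
  expect_equal(ari(cl$cluster_id, fam), 1)
})

test_that("truth tables are internally consistent", {
  sim <- simulate_cohort(simulation_config(seed = 151L, n_per_group = 2L))
  truth <- sim$truth
  # a genome with a planted complete PCC3 has all four subunits and their
  # heme counts in the proteome
  complete <- truth$complexes$genome_id[truth$complexes$PCC3 %in%
                                          c("complete", "complete-variant")]
  for (gid in complete) {
    fams <- truth$proteins$family[truth$proteins$genome_id == gid]
    expect_true(all(c("pcc3_periplasmic", "pcc3_extracellular", "pcc3_porin",
                      "pcc3_imp") %in% fams), label = gid)
    ph <- truth$proteins[truth$proteins$genome_id == gid &
                           truth$proteins$family == "pcc3_periplasmic", ]
    expect_true(all(ph$total_hemes >= 20L))
  }
  # marker truth rows agree with planted subunit roles
  mdefs <- marker_definitions()
  for (gid in truth$markers$genome_id[1:3]) {
    fams <- truth$proteins$family[truth$proteins$genome_id == gid]
    for (i in seq_len(nrow(mdefs))) {
      subs <- strsplit(mdefs$subunits[i], ";")[[1]]
      want <- as.integer(mean(subs %in% fams) >= mdefs$rule[i])
      expect_identical(truth$markers[truth$markers$genome_id == gid,
                                     mdefs$marker_name[i]], want)
    }
  }
  # generating tree parses and its tips are the cohort
  tr <- ape::read.tree(text = truth$tree_newick)
  expect_setequal(tr$tip.label, truth$groups$genome_id)
})

test_that("divergence ladder genomes carry the configured labels and sizes", {
  lad <- simulate_divergence_ladder(seed = 161L, divergences = c(0, 0.1),
                                    n_genes = 5L, gene_len_aa = 50L)
  expect_named(lad, c("d0", "d10"))
  expect_equal(nrow(lad$d0$proteins), 5L)
  expect_equal(nchar(lad$d0$proteins$sequence[1]), 50L)
  expect_equal(nchar(lad$d0$cds_nt$sequence[1]), 150L)
})
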