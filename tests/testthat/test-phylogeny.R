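test_that("marker extraction finds planted markers and applies the presence threshold", {
  sim <- simulate_cohort(simulation_config(seed = 101L, n_per_group = 1L))
  mks <- extract_markers(sim$genomes)
  expect_length(mks$sequences, 13L)
  expect_true(all(vapply(mks$sequences, length, integer(1)) ==
                  length(sim$genomes)))
  # remove one marker from half the cohort: prevalence 0.5 < 0.895 -> dropped
  genomes <- sim$genomes
  truth <- sim$truth$proteins
  for (gid in names(genomes)[1:2]) {
    pid <- truth$protein_id[truth$genome_id == gid &
                              truth$family == "ribo_S9"]
    genomes[[gid]] <- drop_protein(genomes[[gid]], pid)
  }
  mks2 <- suppressMessages(extract_markers(genomes))
  expect_false("S9" %in% names(mks2$sequences))
  expect_true("S9" %in% mks2$dropped$marker)
})

test_that("progressive alignment is gap-free for identical sequences and order-invariant", {
  set.seed(33)
  s <- random_protein(80, alphabet = LETTERS[c(1, 4:9, 11:13)])
  al <- align_marker(c(a = s, b = s, c = s))
  expect_false(any(al == "-"))
  expect_equal(ncol(al), 80L)
  mut <- strsplit(s, "")[[1]]; mut[c(5, 40)] <- "W"
  seqs <- c(x = s, y = paste(mut, collapse = ""), z = s)
  al1 <- align_marker(seqs)
  al2 <- align_marker(seqs[c(3, 1, 2)])
  expect_identical(al1[sort(rownames(al1)), ], al2[sort(rownames(al2)), ])
})

test_that("a single internal deletion produces exactly one gap column, matching an independent pairwise aligner", {
  set.seed(34)
  s <- random_protein(60, alphabet = LETTERS[c(1, 4:9, 11:13)])
  del <- paste0(substr(s, 1, 29), substr(s, 31, 60))
  al <- align_marker(c(full = s, short = del))
  expect_equal(ncol(al), 60L)
  expect_equal(sum(al["short", ] == "-"), 1L)
  expect_equal(sum(al["full", ] == "-"), 0L)
  # independent check: Biostrings global alignment agrees on the gap count
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s), Biostrings::AAString(del), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  expect_equal(Biostrings::nchar(pa), ncol(al))
  bs_short <- as.character(Biostrings::alignedSubject(pa))
  # same gap count; sequences identical after degapping (gap placement may
  # differ at score ties)
  expect_equal(sum(strsplit(bs_short, "")[[1]] == "-"),
               sum(al["short", ] == "-"))
  expect_equal(paste(al["short", al["short", ] != "-"], collapse = ""), del)
  expect_equal(paste(al["full", ], collapse = ""), s)
})

test_that("masking removes exactly the strictly-gappier-than-threshold columns", {
  block <- matrix("A", 10, 3)
  block[1:7, 1] <- "-"   # 0.7  -> retained (strict >)
  block[1:8, 2] <- "-"   # 0.8  -> removed
  rownames(block) <- sprintf("g%02d", 1:10)
  res <- mask_and_concat(list(m = block), rownames(block), end_trim = NA)
  expect_equal(ncol(res$alignment), 2L)
  expect_equal(res$column_map$marker_column, c(1L, 3L))
  # masking is idempotent
  res2 <- mask_and_concat(list(m = res$alignment), rownames(block),
                          end_trim = NA)
  expect_identical(res2$alignment, res$alignment)
  # concatenated length conserves retained per-marker columns
  b2 <- matrix("C", 10, 5, dimnames = list(rownames(block), NULL))
  res3 <- mask_and_concat(list(m1 = block, m2 = b2), rownames(block),
                          end_trim = NA)
  expect_equal(ncol(res3$alignment), 2L + 5L)
  expect_equal(nrow(res3$column_map), ncol(res3$alignment))
  allgap <- matrix("-", 10, 2, dimnames = list(rownames(block), NULL))
  expect_warning(mask_and_concat(list(m1 = block, bad = allgap),
                                 rownames(block), end_trim = NA), "dropped")
})

test_that("NJ reproduces an additive four-taxon matrix exactly", {
  fx <- make_fixture("nj-additive")
  tree <- ape::nj(as.dist(fx$dist))
  expect_true(ape::all.equal.phylo(ape::unroot(ape::read.tree(
    text = fx$newick)), ape::unroot(tree), use.edge.length = FALSE))
  # branch lengths: tree distances reproduce the input matrix to 1e-9
  cop <- ape::cophenetic.phylo(tree)[rownames(fx$dist), colnames(fx$dist)]
  expect_true(max(abs(cop - fx$dist)) < 1e-9)
})

test_that("bootstrap supports are seed-deterministic and duplicates collapse", {
  set.seed(35)
  base <- strsplit(random_protein(120, alphabet = LETTERS[c(1, 4:9)]),
                   "")[[1]]
  taxa <- list(a = base, b = base)
  taxa$c <- replace(base, 1:18, "W")
  taxa$d <- replace(base, 100:118, "Y")
  aln <- do.call(rbind, taxa)
  t1 <- nj_tree(aln, bootstraps = 50L, seed = 9L)
  t2 <- nj_tree(aln, bootstraps = 50L, seed = 9L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # identical rows a,b form a zero-length pendant pair
  d <- ape::cophenetic.phylo(t1)
  expect_lt(d["a", "b"], 1e-12)
  expect_error(nj_tree(aln[1:3, ]), ">= 4")
})

test_that("the planted four-clade structure is recovered with strong support", {
  sim <- simulate_cohort(simulation_config(seed = 111L, n_per_group = 3L))
  mks <- extract_markers(sim$genomes)
  blocks <- lapply(mks$sequences, align_marker)
  concat <- mask_and_concat(blocks, genome_ids = names(sim$genomes),
                            marker_order = names(mks$sequences))
  tree <- nj_tree(concat$alignment, bootstraps = 100L, seed = 4L)
  for (gp in unique(sim$truth$groups$group)) {
    taxa <- sim$truth$groups$genome_id[sim$truth$groups$group == gp]
    cs <- clade_support(tree, taxa)
    expect_true(cs$monophyletic, label = gp)
    expect_gte(cs$support, 90)
  }
})
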