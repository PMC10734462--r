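test_that("pairwise alignment: self-identity, symmetry, coverage of a subsequence", {
  r <- pairwise_align("ACDEFGH", "ACDEFGH")
  expect_equal(r$identity, 100)
  expect_equal(r$query_cov, 1.0)
  expect_equal(r$target_cov, 1.0)
  set.seed(21)
  a <- random_protein(80, alphabet = LETTERS[1:20])
  a <- gsub("[^ARNDCQEGHILKMFPSTWYV]", "K", a)
  b <- paste0(substr(a, 11, 70), "")
  rab <- pairwise_align(a, b)
  rba <- pairwise_align(b, a)
  expect_equal(rab$score, rba$score)
  expect_equal(rab$query_cov, rba$target_cov)
  expect_equal(rab$target_cov, rba$query_cov)
  # 100-residue query vs its exact 80-residue core
  x <- paste(rep("ARNDEQGILK", 10), collapse = "")
  y <- substr(x, 11, 90)
  r <- pairwise_align(x, y)
  expect_equal(r$target_cov, 1.0)
  expect_equal(r$query_cov, 0.8)
  expect_error(pairwise_align("", "AAA"), "empty")
})

test_that("similarity edges obey the bidirectional-coverage contract", {
  set.seed(77)
  core <- random_protein(50, alphabet = LETTERS[c(1,3:9)])
  prot <- data.frame(
    protein_id = c("short", "long", "twin1", "twin2"),
    sequence = c(core, paste0(core, random_protein(150)),
                 random_protein(120), NA),
    stringsAsFactors = FALSE)
  prot$sequence[4] <- prot$sequence[3]
  edges <- similarity_edges(prot, prefilter = 0)
  key <- paste(edges$a, edges$b)
  expect_true("twin1 twin2" %in% key)           # identical pair
  expect_false(any(grepl("short", key)))        # long-side coverage 0.25
})

test_that("random unrelated sequences yield no edges at default thresholds", {
  set.seed(88)
  for (rep in 1:10) {
    prot <- data.frame(protein_id = sprintf("r%02d", 1:10),
                       sequence = replicate(10, random_protein(100,
                         alphabet = LETTERS[LETTERS %in% strsplit(
                           "ARNDCQEGHILKMFPSTWYV", "")[[1]]])),
                       stringsAsFactors = FALSE)
    expect_equal(nrow(similarity_edges(prot, prefilter = 0)), 0L)
  }
})

test_that("greedy set-cover clustering follows degree and tie-break rules", {
  prot <- data.frame(protein_id = c("a", "b", "c"),
                     sequence = rep(strrep("AK", 30), 3),
                     stringsAsFactors = FALSE)
  tri <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                    identity = 100, cov_a = 1, cov_b = 1)
  cl <- greedy_cluster(prot, tri)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # path a-b-c: b has highest degree -> single cluster with centroid b
  path <- tri[1:2, ]; path$a <- c("a", "b"); path$b <- c("b", "c")
  cl <- greedy_cluster(prot, path)
  expect_equal(unique(cl$centroid_id), "b")
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # no edges: all singletons
  cl <- greedy_cluster(prot, tri[0, ])
  expect_equal(nrow(cl), 3L)
  expect_equal(length(unique(cl$cluster_id)), 3L)
})

test_that("clustering is a deterministic partition", {
  set.seed(99)
  fams <- replicate(4, random_protein(150, alphabet = LETTERS[c(1, 4:18)]))
  prot <- do.call(rbind, lapply(1:4, function(f) data.frame(
    protein_id = sprintf("f%d_m%d", f, 1:5),
    sequence = vapply(1:5, function(i) {
      ch <- strsplit(fams[f], "")[[1]]
      idx <- sample(seq_along(ch), 10)
      ch[idx] <- sample(c("A", "D", "E", "G"), 10, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1)), stringsAsFactors = FALSE)))
  edges <- similarity_edges(prot)
  cl1 <- greedy_cluster(prot, edges)
  cl2 <- greedy_cluster(prot[sample(nrow(prot)), ], edges)
  expect_setequal(prot$protein_id, cl1$protein_id)
  expect_equal(anyDuplicated(cl1$protein_id), 0L)
  m1 <- setNames(cl1$centroid_id, cl1$protein_id)
  m2 <- setNames(cl2$centroid_id, cl2$protein_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("raising thresholds never merges clusters", {
  set.seed(123)
  sim <- simulate_cohort(simulation_config(seed = 61L, n_per_group = 1L,
                                           gene_divergence = 0.12))
  genomes <- sim$genomes
  hemes <- profile_cohort(genomes)
  seqs <- do.call(rbind, lapply(genomes, function(g)
    data.frame(protein_id = g$proteins$protein_id, genome_id = g$genome_id,
               sequence = g$proteins$sequence, stringsAsFactors = FALSE)))
  motif <- seqs[seqs$protein_id %in% hemes$profiles$protein_id, ]
  loose <- greedy_cluster(motif, similarity_edges(motif, min_id = 30))
  tight <- greedy_cluster(motif, similarity_edges(motif, min_id = 60,
                                                  min_cov = 0.9))
  # every tight cluster is contained in one loose cluster
  loose_of <- setNames(loose$cluster_id, loose$protein_id)
  for (cid in unique(tight$cluster_id)) {
    members <- tight$protein_id[tight$cluster_id == cid]
    expect_equal(length(unique(loose_of[members])), 1L)
  }
})

test_that("cluster classification uses isolate, consensus and none routes", {
  catalog <- reference_catalog()
  cyc2 <- catalog$entries$sequence[catalog$entries$role_label == "cyc2"]
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(!ch %in% c("C", "H"))[seq_len(k) * 7L]
    ch[idx] <- "A"
    paste(ch, collapse = "")
  }
  set.seed(31)
  prot <- data.frame(
    protein_id = c("iso", "near1", "near2", "junk"),
    sequence = c(cyc2, mut(cyc2, 8), mut(cyc2, 12), random_protein(150)),
    stringsAsFactors = FALSE)
  cl <- data.frame(cluster_id = c(1L, 1L, 1L, 2L), centroid_id = c("iso",
    "iso", "iso", "junk"), protein_id = prot$protein_id,
    is_centroid = c(TRUE, FALSE, FALSE, TRUE))
  lab <- classify_clusters(cl, prot, catalog)
  expect_equal(lab$label[lab$cluster_id == 1L], "cyc2")
  expect_equal(lab$label_source[lab$cluster_id == 1L],
               "isolate-representative")
  expect_equal(lab$label[lab$cluster_id == 2L], "unclassified")
  # consensus: majority of qualifying best hits wins
  cl2 <- cl; cl2$centroid_id[1:3] <- "near1"
  prot2 <- prot; prot2$sequence[1] <- mut(cyc2, 4)
  lab2 <- classify_clusters(cl2, prot2, catalog)
  expect_equal(lab2$label[1], "cyc2")
  expect_equal(lab2$label_source[1], "consensus")
  expect_error(classify_clusters(cl, prot,
                                 list(entries = data.frame())), "empty")
})

test_that("pangenome bins follow prevalence and strain-specific rules", {
  prot <- data.frame(protein_id = sprintf("p%02d", 1:15),
                     genome_id = c(sprintf("g%02d", 1:9), "g01",
                                   sprintf("g%02d", 1:5)),
                     sequence = "M", stringsAsFactors = FALSE)
  cl <- data.frame(cluster_id = c(rep(1L, 9), 2L, rep(3L, 5)),
                   centroid_id = "x", protein_id = prot$protein_id,
                   is_centroid = FALSE)
  bins <- pangenome_bins(cl, prot, n_genomes = 10L)
  expect_equal(bins$bin, c("near-core", "strain-specific", "accessory"))
  expect_equal(bins$prevalence, c(0.9, 0.1, 0.5))
  expect_error(pangenome_bins(cl, prot, n_genomes = 1L), ">= 2")
})
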