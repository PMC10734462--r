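test_that("AAI identity case is exact and undefined cases are graceful", {
  set.seed(7)
  g <- toy_genome("a", setNames(replicate(12, random_protein(120,
    alphabet = LETTERS[c(1, 4:9, 11:14)])), sprintf("p%02d", 1:12)))
  r <- aai(g, g)
  expect_identical(r$aai, 100)
  expect_equal(r$n_pairs, 12L)
  other <- toy_genome("b", setNames(replicate(12, random_protein(120,
    alphabet = LETTERS[c(16:20, 22:25)])), sprintf("q%02d", 1:12)))
  r0 <- aai(g, other)
  expect_true(is.na(r0$aai))
  expect_equal(r0$n_pairs, 0L)
  expect_true(r0$low_support)
})

test_that("three-protein toy AAI equals hand-computed mean identity", {
  # orthologs with mismatches planted away from the ends, so the local
  # alignment spans the full length and identity is exact arithmetic
  base <- strrep("ARNDEQGILKMFPSTWVARNDEQGILKMFPSTWV", 3)  # 102 aa
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]; ch[pos] <- "Y"; paste(ch, collapse = "")
  }
  L <- nchar(base)
  a <- c(p1 = base, p2 = strrep("GILKARNDEQ", 10), p3 = strrep("MFPSTW", 17))
  b <- c(q1 = mutate_at(base, seq(10, 30, 10)),           # 3 mismatches
         q2 = a[["p2"]],                                  # identical
         q3 = mutate_at(a[["p3"]], seq(20, 60, 20)))      # 3 mismatches
  expected <- mean(c(100 * (L - 3) / L, 100,
                     100 * (nchar(a[["p3"]]) - 3) / nchar(a[["p3"]])))
  r <- aai(toy_genome("A", a), toy_genome("B", b))
  expect_equal(r$n_pairs, 3L)
  expect_equal(r$aai, expected, tolerance = 1e-12)
})

test_that("similarity matrices are symmetric with a 100 diagonal", {
  lad <- simulate_divergence_ladder(seed = 13L, divergences = c(0, 0.05, 0.1),
                                    n_genes = 15L, gene_len_aa = 150L)
  sm <- similarity_matrix(lad, "AAI")
  expect_true(all(abs(sm$values - t(sm$values)) <= 1e-9, na.rm = TRUE))
  expect_true(all(diag(sm$values) == 100))
})

test_that("AAI and ANI decay monotonically along a divergence ladder", {
  lad <- simulate_divergence_ladder(seed = 17L, n_genes = 30L,
                                    gene_len_aa = 200L)
  aai_vals <- vapply(names(lad)[-1],
                     function(n) aai(lad[["d0"]], lad[[n]])$aai, numeric(1))
  expect_true(all(diff(aai_vals) < 0))
  ani_vals <- vapply(names(lad)[-1],
                     function(n) ani(lad[["d0"]], lad[[n]])$ani, numeric(1))
  expect_true(all(diff(ani_vals) < 0))
  # 5% nucleotide divergence lands near 95% identity (frozen expectation
  # from repeat simulation: local-alignment end-trimming adds < 0.5)
  expect_lt(abs(ani_vals[["d5"]] - 95), 0.5)
})

test_that("structural-RNA exclusion prevents ANI inflation", {
  lad <- simulate_divergence_ladder(seed = 23L, divergences = c(0, 0.2),
                                    n_genes = 12L, gene_len_aa = 150L)
  a <- lad$d0; b <- lad$d20
  set.seed(24)
  rrna <- paste(sample(c("A", "C", "G", "T"), 1600, TRUE), collapse = "")
  a$cds_nt <- rbind(a$cds_nt, data.frame(id = "a_rrna", type = "rRNA",
                                         sequence = rrna))
  b$cds_nt <- rbind(b$cds_nt, data.frame(id = "b_rrna", type = "rRNA",
                                         sequence = rrna))
  with_rrna <- ani(a, b, exclude_structural_rna = FALSE)$ani
  without <- ani(a, b, exclude_structural_rna = TRUE)$ani
  expect_gt(with_rrna, without)
})

test_that("16S identity: arithmetic, boundary, and input validation", {
  set.seed(29)
  s <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  expect_equal(rrna_identity(s, s)$identity, 100)
  ch <- strsplit(s, "")[[1]]
  idx <- seq(50, by = 100, length.out = 15)
  ch[idx] <- vapply(idx, function(i) setdiff(c("A", "C", "G", "T"),
                                             ch[i])[1], character(1))
  r <- rrna_identity(s, paste(ch, collapse = ""))
  expect_equal(r$identity, 100 * (1500 - 15) / 1500)
  short <- substr(s, 1, 1400)
  expect_false(rrna_identity(short, s)$evaluated)
  expect_error(rrna_identity(gsub("A", "J", s), s), "IUPAC")
})
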