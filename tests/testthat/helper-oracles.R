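# Independent oracles and small builders used across the suite.

# Brute-force heme-motif oracle: enumerate every candidate match of the three
# motif classes by direct character tests (no regex), then apply the same
# leftmost-start / shortest-span greedy selection. Independent of the
# package's regex-based scanner.
oracle_scan <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_letter <- grepl("[A-Za-z]", chars)
  cand <- list()
  for (span in c(5L, 6L, 7L)) {
    cls <- c("CXXCH", "CX3CH", "CX4CH")[span - 4L]
    if (n < span) next
    for (s in seq_len(n - span + 1L)) {
      seg <- s:(s + span - 1L)
      if (chars[s] == "C" && chars[s + span - 2L] == "C" &&
          chars[s + span - 1L] == "H" &&
          all(is_letter[seg[c(-1L, -(span - 1L), -span)] + 0L]) &&
          all(is_letter[seg])) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = s - 1L, motif_class = cls, span = span,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(start = integer(0), motif_class = character(0),
                      span = integer(0), stringsAsFactors = FALSE)
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$span), , drop = FALSE]
  sel <- list(); next_free <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= next_free) {
      sel[[length(sel) + 1L]] <- cand[i, ]
      next_free <- cand$start[i] + cand$span[i]
    }
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  out
}

random_protein <- function(len, alphabet = c(LETTERS[LETTERS %in%
  c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T",
    "V","W","Y")], "*")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Minimal genome builder for unit tests
toy_genome <- function(genome_id, sequences, group = "test",
                       completeness = 95, contamination = 1,
                       contig = "contig_1") {
  n <- length(sequences)
  ids <- if (is.null(names(sequences)))
    sprintf("%s_p%02d", genome_id, seq_len(n)) else names(sequences)
  p <- data.frame(protein_id = ids, locus_tag = ids,
                  contig_id = rep(contig, length.out = n),
                  rank = NA_integer_, strand = "+",
                  start = seq_len(n) * 1000L,
                  end = seq_len(n) * 1000L + nchar(sequences) * 3L,
                  sequence = unname(sequences), stringsAsFactors = FALSE)
  p$rank <- as.integer(stats::ave(seq_len(n), p$contig_id,
                                  FUN = seq_along)) - 1L
  g <- list(genome_id = genome_id, group = group,
            completeness = completeness, contamination = contamination,
            proteins = p, rrna_16s = NULL, cds_nt = NULL)
  class(g) <- "genome_annotation"
  g
}

# drop one protein from a genome (for verdict-monotonicity checks)
drop_protein <- function(genome, protein_id) {
  p <- genome$proteins
  p <- p[p$protein_id != protein_id, , drop = FALSE]
  p$rank <- as.integer(stats::ave(seq_len(nrow(p)), p$contig_id,
                                  FUN = seq_along)) - 1L
  genome$proteins <- p
  genome
}

# Adjusted Rand index between two labelings (direct contingency formula)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
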