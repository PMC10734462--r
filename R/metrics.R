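# Pairwise genome similarity: AAI as mean identity over reciprocal best
# protein hits, gene-based ANI over nucleotide bidirectional best hits (with
# structural-RNA exclusion), and 16S rRNA percent identity.

# Best hit of each query in a subject gene set. Candidates are ranked by
# shared 4-mers (top `max_cand` attempted); returns index + stats per query.
best_hits <- function(q_seqs, s_seqs, type = "protein", max_cand = 3L,
                      prefilter = 0.01) {
  # amino-acid 4-mers are informative; DNA needs longer words (4-mers are
  # saturated in any gene-length sequence)
  k <- if (type == "dna") 10L else 4L
  s_kmers <- lapply(s_seqs, kmer_set, k = k)
  s_lens <- nchar(s_seqs)
  res <- data.frame(target = rep(NA_integer_, length(q_seqs)),
                    identity = NA_real_, query_cov = NA_real_,
                    target_cov = NA_real_, score = NA_real_)
  for (i in seq_along(q_seqs)) {
    qk <- kmer_set(q_seqs[i], k = k)
    ov <- vapply(s_kmers, kmer_overlap, numeric(1), ka = qk)
    cand <- order(-ov, s_lens)[seq_len(min(max_cand, length(s_seqs)))]
    cand <- cand[ov[cand] >= prefilter]
    if (length(cand) == 0L) next
    best <- NULL
    for (j in cand) {
      r <- align_many(q_seqs[i], s_seqs[j], type = type)
      if (is.null(best) || r$score > best$score) {
        best <- r; best$j <- j
      }
    }
    res$target[i] <- best$j
    res$identity[i] <- best$identity
    res$query_cov[i] <- best$query_cov
    res$target_cov[i] <- best$target_cov
    res$score[i] <- best$score
  }
  res
}

rbh_mean_identity <- function(a_seqs, b_seqs, type, min_id, min_cov) {
  ab <- best_hits(a_seqs, b_seqs, type = type)
  ba <- best_hits(b_seqs, a_seqs, type = type)
  ids <- numeric(0)
  for (i in seq_along(a_seqs)) {
    j <- ab$target[i]
    if (is.na(j)) next
    if (is.na(ba$target[j]) || ba$target[j] != i) next
    if (ab$identity[i] < min_id) next
    if (min(ab$query_cov[i], ab$target_cov[i]) < min_cov) next
    ids <- c(ids, ab$identity[i])
  }
  list(value = if (length(ids) == 0L) NA_real_ else mean(ids),
       n_pairs = length(ids))
}

#' Average amino-acid identity between two genomes
#'
#' Reciprocal-best-hit AAI: the best hit of each protein of A in B and vice
#' versa; reciprocal pairs passing the thresholds are retained and AAI is the
#' mean percent identity over those pairs. Symmetric by construction. Zero
#' qualifying pairs gives `NA` with `n_pairs = 0` (not an error); fewer than
#' 10 pairs carries a low-support flag.
#'
#' @param genome_a,genome_b `genome_annotation` objects.
#' @param min_id,min_cov thresholds for a retained pair (defaults 30, 0.7).
#' @return list: `aai` (percent or NA), `n_pairs`, `low_support`.
#' @export
aai <- function(genome_a, genome_b, min_id = 30, min_cov = 0.7) {
  a <- genome_a$proteins$sequence
  b <- genome_b$proteins$sequence
  if (length(a) == 0L || length(b) == 0L) stop_input("empty proteome")
  r <- rbh_mean_identity(a, b, "protein", min_id, min_cov)
  list(aai = r$value, n_pairs = r$n_pairs, low_support = r$n_pairs < 10L)
}

#' Gene-based average nucleotide identity between two genomes
#'
#' Bidirectional best hits on nucleotide identity over the genomes' CDS gene
#' sets; ANI is the mean identity of reciprocal pairs passing the thresholds.
#' Records tagged as structural RNA (rRNA/tRNA) are excluded by default,
#' since their strong conservation inflates the estimate.
#'
#' @param genome_a,genome_b `genome_annotation` objects with a `cds_nt` gene
#'   table (columns `id`, `type`, `sequence`).
#' @param min_id,min_cov thresholds (defaults 70, 0.7).
#' @param exclude_structural_rna drop rRNA/tRNA-tagged records, default TRUE.
#' @return list: `ani` (percent or NA), `n_pairs`, `low_support`.
#' @export
ani <- function(genome_a, genome_b, min_id = 70, min_cov = 0.7,
                exclude_structural_rna = TRUE) {
  get_nt <- function(g) {
    if (is.null(g$cds_nt)) stop_input("genome lacks nucleotide gene set: ",
                                      g$genome_id)
    nt <- g$cds_nt
    if (exclude_structural_rna)
      nt <- nt[!(nt$type %in% c("rRNA", "tRNA")), , drop = FALSE]
    nt$sequence
  }
  a <- get_nt(genome_a); b <- get_nt(genome_b)
  if (length(a) == 0L || length(b) == 0L) stop_input("empty gene set")
  r <- rbh_mean_identity(a, b, "dna", min_id, min_cov)
  list(ani = r$value, n_pairs = r$n_pairs, low_support = r$n_pairs < 10L)
}

#' 16S rRNA percent identity
#'
#' Global alignment of two 16S sequences; identity is matches over aligned
#' columns excluding terminal gaps. Sequences shorter than `min_len` are not
#' evaluated (returns `NA` with `evaluated = FALSE`).
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @param min_len minimum length in nt, default 1450.
#' @return list: `identity` (percent or NA), `evaluated`, `aligned_columns`.
#' @export
rrna_identity <- function(seq_a, seq_b, min_len = 1450L) {
  up <- function(s) toupper(s)
  bad <- grepl("[^ACGTURYSWKMBDHVN-]", up(c(seq_a, seq_b)))
  if (any(bad)) stop_input("non-IUPAC nucleotide characters")
  if (nchar(seq_a) < min_len || nchar(seq_b) < min_len)
    return(list(identity = NA_real_, evaluated = FALSE, aligned_columns = 0L))
  a <- gsub("U", "T", up(seq_a)); b <- gsub("U", "T", up(seq_b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = dna_matrix(), gapOpening = 5, gapExtension = 2)
  alen <- Biostrings::nchar(pa)
  nmat <- Biostrings::nmatch(pa)
  list(identity = 100 * nmat / alen, evaluated = TRUE,
       aligned_columns = alen)
}

#' Pairwise similarity matrix for a cohort
#'
#' @param genomes list of `genome_annotation` objects.
#' @param metric `"AAI"`, `"ANI"` or `"16S"`.
#' @param ... passed to [aai()], [ani()] or [rrna_identity()].
#' @return list with `values` (symmetric percent matrix, diagonal 100 where
#'   defined) and `support` (RBH pair counts, or aligned columns for 16S).
#' @export
similarity_matrix <- function(genomes, metric = c("AAI", "ANI", "16S"), ...) {
  metric <- match.arg(metric)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  n <- length(genomes)
  vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  supp <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    vals[i, i] <- 100
    supp[i, i] <- NA_integer_
    if (i == n) break
    for (j in (i + 1L):n) {
      if (metric == "AAI") {
        r <- aai(genomes[[i]], genomes[[j]], ...)
        v <- r$aai; s <- r$n_pairs
      } else if (metric == "ANI") {
        r <- ani(genomes[[i]], genomes[[j]], ...)
        v <- r$ani; s <- r$n_pairs
      } else {
        sa <- genomes[[i]]$rrna_16s; sb <- genomes[[j]]$rrna_16s
        if (is.null(sa) || is.null(sb)) { v <- NA_real_; s <- 0L }
        else {
          r <- rrna_identity(sa, sb, ...)
          v <- r$identity; s <- r$aligned_columns
        }
      }
      vals[i, j] <- vals[j, i] <- v
      supp[i, j] <- supp[j, i] <- s
    }
  }
  list(metric = metric, values = vals, support = supp)
}
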