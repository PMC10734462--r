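# Heme-binding motif census. c-type cytochromes attach heme covalently at
# CXXCH-family motifs (CXXCH, CX3CH, CX4CH): a cysteine pair plus a histidine
# that ligates the heme iron. Counting motif occurrences per protein yields a
# census of putative c-type cytochromes and flags multiheme cytochromes (MHCs).

MOTIF_CLASSES <- data.frame(
  motif_class = c("CXXCH", "CX3CH", "CX4CH"),
  span = c(5L, 6L, 7L),
  stringsAsFactors = FALSE)

#' Scan one protein for heme-binding motifs
#'
#' Finds non-overlapping CXXCH / CX3CH (CXXXCH) / CX4CH (CXXXXCH) motifs.
#' Anchor positions must be literal `C`/`H`; wildcard positions accept any
#' alphabetic residue (including ambiguity codes); `*` never matches and no
#' motif may span it. Because two heme attachments cannot share a cysteine,
#' hits are selected greedily left to right, taking the shortest motif at
#' equal start and resuming after the selected span.
#'
#' @param sequence uppercase amino-acid string.
#' @param overlap `"greedy"` (default, non-overlapping selection) or
#'   `"allow"` (report every match of every class).
#' @return `data.frame` with columns `start` (0-based), `motif_class`, `span`.
#' @examples
#' scan_protein("MCAACHK")   # one CXXCH at offset 1
#' scan_protein("CCACCH")    # CX3CH at 0 suppresses the nested CXXCH
#' @export
scan_protein <- function(sequence, overlap = c("greedy", "allow")) {
  overlap <- match.arg(overlap)
  empty <- data.frame(start = integer(0), motif_class = character(0),
                      span = integer(0), stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) < 5L) return(empty)
  # lookahead regexes so overlapping candidate matches are all enumerated
  pats <- c(CXXCH = "(?=C[A-Za-z]{2}CH)",
            CX3CH = "(?=C[A-Za-z]{3}CH)",
            CX4CH = "(?=C[A-Za-z]{4}CH)")
  cand <- list()
  for (cls in names(pats)) {
    m <- gregexpr(pats[[cls]], sequence, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      cand[[cls]] <- data.frame(
        start = as.integer(m) - 1L, motif_class = cls,
        span = MOTIF_CLASSES$span[MOTIF_CLASSES$motif_class == cls],
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$span), , drop = FALSE]
  rownames(cand) <- NULL
  if (overlap == "allow") return(cand)
  sel <- logical(nrow(cand))
  next_free <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= next_free) {
      sel[i] <- TRUE
      next_free <- cand$start[i] + cand$span[i]
    }
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

heme_category <- function(total, bin_edges) {
  k <- findInterval(total, bin_edges)
  labs <- bin_labels(bin_edges)
  ifelse(total < bin_edges[1], NA_character_, labs[k])
}

bin_labels <- function(bin_edges) {
  n <- length(bin_edges)
  labs <- character(n)
  for (i in seq_len(n - 1L)) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L] - 1L
    labs[i] <- if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }
  labs[n] <- paste0(bin_edges[n], "+")
  labs
}

#' Heme-motif profiles for one genome
#'
#' Scans every protein and returns one profile row per motif-bearing protein,
#' plus a genome-level summary (counts and a category histogram matching the
#' cohort bar-graph layout).
#'
#' @param genome a `genome_annotation`.
#' @param bin_edges ascending integers defining category bins; the default
#'   `c(1, 2, 3, 4, 10)` gives bins 1, 2, 3, 4-9 and 10+.
#' @param min_mhc minimum total hemes for the multiheme (MHC) flag, default 3.
#' @param overlap motif overlap policy, see [scan_protein()].
#' @return list with `profiles` (data.frame: protein_id, locus_tag, n_cxxch,
#'   n_cx3ch, n_cx4ch, total_hemes, category, is_mhc) and `summary` (list:
#'   n_proteins, n_motif_proteins, n_mhc, histogram named by category).
#' @export
profile_genome <- function(genome, bin_edges = c(1L, 2L, 3L, 4L, 10L),
                           min_mhc = 3L, overlap = "greedy") {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_input("bin_edges must be strictly increasing")
  p <- genome$proteins
  hits <- lapply(p$sequence, scan_protein, overlap = overlap)
  counts <- t(vapply(hits, function(h) {
    c(sum(h$motif_class == "CXXCH"), sum(h$motif_class == "CX3CH"),
      sum(h$motif_class == "CX4CH"))
  }, integer(3)))
  total <- rowSums(counts)
  keep <- total >= 1L
  profiles <- data.frame(
    protein_id = p$protein_id[keep], locus_tag = p$locus_tag[keep],
    n_cxxch = counts[keep, 1L], n_cx3ch = counts[keep, 2L],
    n_cx4ch = counts[keep, 3L], total_hemes = as.integer(total[keep]),
    stringsAsFactors = FALSE)
  profiles$category <- heme_category(profiles$total_hemes, bin_edges)
  profiles$is_mhc <- profiles$total_hemes >= min_mhc
  labs <- bin_labels(bin_edges)
  histogram <- setNames(integer(length(labs)), labs)
  tab <- table(profiles$category)
  histogram[names(tab)] <- as.integer(tab)
  list(profiles = profiles,
       summary = list(genome_id = genome$genome_id,
                      n_proteins = nrow(p),
                      n_motif_proteins = nrow(profiles),
                      n_mhc = sum(profiles$is_mhc),
                      histogram = histogram))
}

#' Heme profiles for a whole cohort
#' @param genomes list of `genome_annotation` objects.
#' @inheritParams profile_genome
#' @return list with `profiles` (one data.frame with genome_id column) and
#'   `per_genome` (data.frame of per-genome summary counts and histogram).
#' @export
profile_cohort <- function(genomes, bin_edges = c(1L, 2L, 3L, 4L, 10L),
                           min_mhc = 3L, overlap = "greedy") {
  per <- lapply(genomes, profile_genome, bin_edges = bin_edges,
                min_mhc = min_mhc, overlap = overlap)
  profs <- do.call(rbind, lapply(per, function(x) {
    if (nrow(x$profiles) == 0L) return(NULL)
    cbind(genome_id = x$summary$genome_id, x$profiles,
          stringsAsFactors = FALSE)
  }))
  if (is.null(profs))
    profs <- data.frame(genome_id = character(0), protein_id = character(0),
                        locus_tag = character(0), n_cxxch = integer(0),
                        n_cx3ch = integer(0), n_cx4ch = integer(0),
                        total_hemes = integer(0), category = character(0),
                        is_mhc = logical(0))
  rownames(profs) <- NULL
  hist_mat <- t(vapply(per, function(x) x$summary$histogram,
                       numeric(length(bin_labels(bin_edges)))))
  summary_df <- data.frame(
    genome_id = vapply(per, function(x) x$summary$genome_id, character(1)),
    n_proteins = vapply(per, function(x) x$summary$n_proteins, numeric(1)),
    n_motif_proteins = vapply(per, function(x) x$summary$n_motif_proteins,
                              numeric(1)),
    n_mhc = vapply(per, function(x) x$summary$n_mhc, numeric(1)),
    stringsAsFactors = FALSE)
  summary_df <- cbind(summary_df, as.data.frame(hist_mat))
  rownames(summary_df) <- NULL
  list(profiles = profs, per_genome = summary_df)
}

#' Ratio of mean motif-bearing protein counts between two genome sets
#'
#' The cohort-level contrast between metabolic groups: mean per-genome count
#' of proteins carrying at least one heme-binding motif in set A divided by
#' the same mean in set B (e.g., iron oxidizers over nitrite oxidizers).
#'
#' @param genomes_a,genomes_b lists of `genome_annotation` objects.
#' @param overlap motif overlap policy.
#' @return list with `ratio`, `mean_a`, `mean_b`, `counts_a`, `counts_b`.
#' @export
cohort_heme_ratio <- function(genomes_a, genomes_b, overlap = "greedy") {
  if (length(genomes_a) == 0L || length(genomes_b) == 0L)
    stop_input("both groups must be non-empty")
  count1 <- function(g) profile_genome(g, overlap = overlap)$summary$n_motif_proteins
  ca <- vapply(genomes_a, count1, numeric(1))
  cb <- vapply(genomes_b, count1, numeric(1))
  if (mean(cb) == 0) stop_input("degenerate denominator: group B mean is 0")
  list(ratio = mean(ca) / mean(cb), mean_a = mean(ca), mean_b = mean(cb),
       counts_a = ca, counts_b = cb)
}
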