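# Homolog clustering of motif-bearing proteins. Edges require bidirectional
# coverage (aligned region covering >= min_cov of BOTH sequences) plus an
# identity floor; clusters are built by greedy set-cover over the resulting
# graph and classified against a labelled reference catalog.

#' Similarity edges under a bidirectional-coverage criterion
#'
#' All-vs-all local alignment of a protein set. An (undirected) edge `a--b`
#' is emitted iff the aligned region covers at least `min_cov` of both
#' sequences and percent identity over aligned columns is at least `min_id`.
#' Two exact prefilters cut the quadratic alignment cost: a length-ratio gate
#' (coverage of the longer sequence cannot exceed `len_short/len_long`) and a
#' conservative shared-4-mer screen (`prefilter`, set 0 to disable).
#'
#' @param proteins data.frame with columns `protein_id`, `sequence` (and
#'   optionally `genome_id`).
#' @param min_cov bidirectional coverage threshold, default 0.8.
#' @param min_id percent-identity floor, default 30 (0 gives pure-coverage
#'   clustering).
#' @param prefilter minimum shared-distinct-4-mer fraction (relative to the
#'   smaller k-mer set) to attempt an alignment; default 0.02.
#' @return data.frame of edges: `a`, `b`, `identity`, `cov_a`, `cov_b`.
#' @export
similarity_edges <- function(proteins, min_cov = 0.8, min_id = 30,
                             prefilter = 0.02) {
  n <- nrow(proteins)
  empty <- data.frame(a = character(0), b = character(0),
                      identity = numeric(0), cov_a = numeric(0),
                      cov_b = numeric(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  lens <- nchar(seqs)
  kmers <- lapply(seqs, kmer_set)
  out <- vector("list", 256L); nout <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < min_cov) next
      if (prefilter > 0 && kmer_overlap(kmers[[i]], kmers[[j]]) < prefilter) next
      r <- align_pair_canonical(ids[i], seqs[i], ids[j], seqs[j])
      cov_i <- unname(r$cov[ids[i]]); cov_j <- unname(r$cov[ids[j]])
      if (cov_i >= min_cov && cov_j >= min_cov && r$identity >= min_id) {
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- data.frame(a = ids[i], b = ids[j],
                                  identity = r$identity, cov_a = cov_i,
                                  cov_b = cov_j, stringsAsFactors = FALSE)
      }
    }
  }
  if (nout == 0L) return(empty)
  do.call(rbind, out[seq_len(nout)])
}

#' Greedy set-cover clustering
#'
#' Iteratively selects the unassigned protein with the most unassigned
#' neighbours (ties broken by longer sequence, then lexicographically smaller
#' id) as a cluster centroid, assigns it together with its unassigned
#' neighbours, and repeats. Proteins without edges become singletons. The
#' result is always a partition of the input set.
#'
#' @param proteins data.frame with `protein_id`, `sequence`.
#' @param edges data.frame from [similarity_edges()].
#' @return data.frame with one row per protein: `cluster_id` (integer),
#'   `centroid_id`, `protein_id`, `is_centroid`.
#' @export
greedy_cluster <- function(proteins, edges) {
  ids <- proteins$protein_id
  lens <- setNames(nchar(proteins$sequence), ids)
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      adj[[edges$a[k]]] <- c(adj[[edges$a[k]]], edges$b[k])
      adj[[edges$b[k]]] <- c(adj[[edges$b[k]]], edges$a[k])
    }
  }
  unassigned <- setNames(rep(TRUE, length(ids)), ids)
  assignments <- list()
  cid <- 0L
  while (any(unassigned)) {
    pool <- names(unassigned)[unassigned]
    deg <- vapply(pool, function(p) sum(unassigned[adj[[p]]]), numeric(1))
    ord <- order(-deg, -lens[pool], pool)
    centroid <- pool[ord[1L]]
    members <- c(centroid, adj[[centroid]][unassigned[adj[[centroid]]]])
    members <- unique(members)
    unassigned[members] <- FALSE
    cid <- cid + 1L
    assignments[[cid]] <- data.frame(
      cluster_id = cid, centroid_id = centroid, protein_id = members,
      is_centroid = members == centroid, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, assignments)
  rownames(out) <- NULL
  out
}

#' Classify clusters against a labelled reference catalog
#'
#' A cluster containing a catalog sequence itself (matched by identical
#' sequence or shared id, the isolate-representative route) takes that
#' entry's label. Otherwise each member is searched against the catalog and
#' the majority label among members with a qualifying hit is used (consensus
#' route; ties give `"ambiguous"`). Clusters without qualifying hits are
#' `"unclassified"`.
#'
#' @param clusters data.frame from [greedy_cluster()].
#' @param proteins data.frame with `protein_id`, `sequence`.
#' @param catalog a `reference_catalog`, see [reference_catalog()].
#' @param min_id,min_cov qualifying-hit thresholds (defaults 35, 0.7).
#' @param prefilter shared-4-mer screen, see [similarity_edges()].
#' @return data.frame: `cluster_id`, `centroid_id`, `n_members`, `label`,
#'   `label_source` (`isolate-representative`/`consensus`/`none`).
#' @export
classify_clusters <- function(clusters, proteins, catalog, min_id = 35,
                              min_cov = 0.7, prefilter = 0.02) {
  if (nrow(catalog$entries) == 0L) stop_input("empty reference catalog")
  seq_of <- setNames(proteins$sequence, proteins$protein_id)
  cat_entries <- catalog$entries
  cat_kmers <- lapply(cat_entries$sequence, kmer_set)
  best_label <- function(s) {
    ks <- kmer_set(s)
    lens_ok <- rep(TRUE, nrow(cat_entries))
    cand <- which(lens_ok & vapply(cat_kmers, kmer_overlap, numeric(1), kb = ks) >=
                    prefilter)
    if (prefilter <= 0) cand <- seq_len(nrow(cat_entries))
    best <- NULL
    for (i in cand) {
      r <- align_many(s, cat_entries$sequence[i])
      if (r$identity >= min_id && r$query_cov >= min_cov &&
          r$target_cov >= min_cov) {
        if (is.null(best) || r$score > best$score)
          best <- list(score = r$score, label = cat_entries$role_label[i])
      }
    }
    if (is.null(best)) NA_character_ else best$label
  }
  res <- lapply(split(clusters, clusters$cluster_id), function(cl) {
    members <- cl$protein_id
    mseqs <- seq_of[members]
    iso <- which(mseqs %in% cat_entries$sequence | members %in% cat_entries$ref_id)
    if (length(iso) > 0L) {
      hit <- iso[1L]
      idx <- match(TRUE, cat_entries$sequence == mseqs[hit] |
                     cat_entries$ref_id == members[hit])
      label <- cat_entries$role_label[idx]
      source <- "isolate-representative"
    } else {
      labels <- vapply(mseqs, best_label, character(1))
      labels <- labels[!is.na(labels)]
      if (length(labels) == 0L) {
        label <- "unclassified"; source <- "none"
      } else {
        tab <- sort(table(labels), decreasing = TRUE)
        if (length(tab) > 1L && tab[1L] == tab[2L]) {
          label <- "ambiguous"; source <- "consensus"
        } else {
          label <- names(tab)[1L]; source <- "consensus"
        }
      }
    }
    data.frame(cluster_id = cl$cluster_id[1L], centroid_id = cl$centroid_id[1L],
               n_members = length(members), label = label,
               label_source = source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pangenome prevalence bins for clusters
#'
#' Bins each cluster by genome prevalence: strain-specific (members from a
#' single genome), near-core (present in more than 85% of genomes), else
#' accessory.
#'
#' @param clusters data.frame from [greedy_cluster()].
#' @param proteins data.frame with `protein_id`, `genome_id`.
#' @param n_genomes total genomes in the cohort (>= 2).
#' @param core_threshold prevalence above which a cluster is near-core
#'   (strict), default 0.85.
#' @return data.frame: `cluster_id`, `n_genomes_present`, `prevalence`, `bin`.
#' @export
pangenome_bins <- function(clusters, proteins, n_genomes, core_threshold = 0.85) {
  if (n_genomes < 2L) stop_input("n_genomes must be >= 2")
  gid <- setNames(proteins$genome_id, proteins$protein_id)
  res <- lapply(split(clusters$protein_id, clusters$cluster_id), function(m) {
    g <- unique(gid[m])
    prev <- length(g) / n_genomes
    bin <- if (length(g) == 1L) "strain-specific"
           else if (prev > core_threshold) "near-core" else "accessory"
    data.frame(n_genomes_present = length(g), prevalence = prev, bin = bin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(cluster_id = as.integer(names(res)), out)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
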