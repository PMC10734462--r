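# Concatenated ribosomal-protein phylogeny: extract the 13 marker proteins
# per genome by homology, align each marker, mask and concatenate, then build
# a neighbor-joining tree on Poisson-corrected distances with bootstrap
# support by column resampling.

#' Extract ribosomal phylogeny markers from a cohort
#'
#' Best qualifying hit per (genome, marker) against the shipped ribosomal
#' references; markers present in fewer than `presence_threshold` of the
#' genomes are dropped with a logged reason.
#'
#' @param genomes list of `genome_annotation` objects.
#' @param catalog a `reference_catalog` (ribosomal refs have roles
#'   `ribo_L19` ... `ribo_S9`).
#' @param markers marker names, default the 13 ribosomal proteins.
#' @param min_id,min_cov hit thresholds (defaults 40, 0.7).
#' @param presence_threshold minimum fraction of genomes with the marker for
#'   inclusion, default 0.895.
#' @param prefilter shared-4-mer screen.
#' @return list: `sequences` (marker -> named character vector genome->seq),
#'   `dropped` (data.frame marker, prevalence), `presence` (marker x genome
#'   logical matrix).
#' @export
extract_markers <- function(genomes, catalog = reference_catalog(),
                            markers = RIBO_MARKERS, min_id = 40,
                            min_cov = 0.7, presence_threshold = 0.895,
                            prefilter = 0.02) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  seqs <- list()
  presence <- matrix(FALSE, length(markers), length(ids),
                     dimnames = list(markers, ids))
  for (mk in markers) {
    role <- paste0("ribo_", mk)
    ref <- catalog$entries[catalog$entries$role_label == role, , drop = FALSE]
    if (nrow(ref) == 0L) stop_input("no reference for marker ", mk)
    found <- character(0)
    for (g in genomes) {
      p <- g$proteins
      rk <- kmer_set(ref$sequence[1])
      rlen <- nchar(ref$sequence[1])
      lens <- nchar(p$sequence)
      cand <- which(pmin(lens, rlen) / pmax(lens, rlen) >= min_cov)
      if (prefilter > 0 && length(cand) > 0L) {
        ov <- vapply(p$sequence[cand],
                     function(s) kmer_overlap(kmer_set(s), rk), numeric(1))
        cand <- cand[ov >= prefilter]
      }
      if (length(cand) == 0L) next
      al <- align_many(p$sequence[cand], ref$sequence[1])
      ok <- al$identity >= min_id & al$query_cov >= min_cov &
        al$target_cov >= min_cov
      if (!any(ok)) next
      w <- which(ok)
      if (sum(al$score[w] == max(al$score[w])) > 1L)
        message("marker ", mk, " in ", g$genome_id,
                ": multiple equal-scoring hits, keeping first")
      bi <- w[order(-al$score[w], p$protein_id[cand[w]])][1L]
      found[g$genome_id] <- p$sequence[cand[bi]]
      presence[mk, g$genome_id] <- TRUE
    }
    seqs[[mk]] <- found
  }
  prevalence <- rowMeans(presence)
  keep <- prevalence >= presence_threshold
  dropped <- data.frame(marker = markers[!keep],
                        prevalence = unname(prevalence[!keep]),
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0L)
    message("dropped marker(s) below presence threshold: ",
            paste(dropped$marker, collapse = ", "))
  list(sequences = seqs[markers[keep]], dropped = dropped,
       presence = presence)
}

# pairwise distances on a character matrix, ignoring columns with a gap in
# either row; Poisson correction d = -ln(1 - p), capped with a warning
alignment_distances <- function(alignment,
                                distance_model = c("Poisson", "p-distance"),
                                cap = 10) {
  distance_model <- match.arg(distance_model)
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  capped <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- alignment[i, ] != "-" & alignment[j, ] != "-"
      if (!any(ok)) { d[i, j] <- d[j, i] <- cap; capped <- TRUE; next }
      p <- mean(alignment[i, ok] != alignment[j, ok])
      if (distance_model == "p-distance") dd <- p
      else if (p < 1 - exp(-cap)) dd <- -log(1 - p)
      else { dd <- cap; capped <- TRUE }
      d[i, j] <- d[j, i] <- dd
    }
  }
  if (capped) warning("saturated distance(s) capped at ", cap)
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Distances ignore columns where either row has a gap; the Poisson
#' correction `d = -ln(1 - p)` is applied by default. Bootstrapping resamples
#' alignment columns with replacement (seeded) and maps supports onto the
#' full-data tree by bipartition matching.
#'
#' @param alignment genome x column character matrix (from
#'   [mask_and_concat()]).
#' @param distance_model `"Poisson"` (default) or `"p-distance"`.
#' @param bootstraps number of replicates, default 1000; 0 disables.
#' @param seed RNG seed for resampling.
#' @param outgroup optional character vector of leaf names to root on.
#' @return an `ape::phylo` tree (unrooted unless `outgroup` given) with
#'   integer percent supports in `node.label` and attribute `"supports"`.
#' @export
nj_tree <- function(alignment, distance_model = "Poisson", bootstraps = 1000L,
                    seed = 1L, outgroup = NULL) {
  if (nrow(alignment) < 4L) stop_input("need >= 4 genomes for a tree")
  dist_fun <- function(x) alignment_distances(x, distance_model)
  tree <- ape::nj(as.dist(dist_fun(alignment)))
  supports <- NULL
  if (bootstraps > 0L) {
    counts <- with_seed(seed, suppressWarnings(
      ape::boot.phylo(tree, alignment,
                      FUN = function(x) ape::nj(as.dist(dist_fun(x))),
                      B = bootstraps, rooted = FALSE, quiet = TRUE)))
    supports <- round(100 * counts / bootstraps)
    tree$node.label <- as.character(supports)
  }
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  attr(tree, "supports") <- supports
  tree
}

#' Is a set of leaves a clade of the (unrooted) tree, and with what support?
#'
#' A leaf set is monophyletic in an unrooted tree when some internal edge
#' bipartitions the leaves into the set and its complement.
#'
#' @param tree `phylo` object from [nj_tree()] (node labels carry supports).
#' @param taxa character vector of leaf names.
#' @return list: `monophyletic` (logical), `support` (percent or NA).
#' @export
clade_support <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!all(taxa %in% tips)) stop_input("unknown taxa")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(taxa, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  for (k in seq_along(parts)) {
    pp <- sort(parts[[k]])
    if (identical(pp, target) || identical(pp, comp)) {
      sup <- NA_real_
      if (!is.null(tree$node.label) && k <= length(tree$node.label)) {
        sup <- suppressWarnings(as.numeric(tree$node.label[k]))
      }
      return(list(monophyletic = TRUE, support = sup))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}
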