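# Porin-cytochrome complex calling. Subunit roles are located by homology to
# catalog references (with heme-count checks for cytochrome roles), then
# verdicts are assigned from gene colocalization: a complex is complete when
# every required role has a hit on one contig within a gene-rank window of
# the anchor cytochrome.

#' Find candidate proteins for a subunit role in one genome
#'
#' Aligns genome proteins against all catalog references of `role`; a hit is
#' retained when identity and bidirectional coverage pass the thresholds and,
#' if heme constraints are given, the protein's total heme-motif count lies
#' within `[min_hemes, max_hemes]`. Porin and other non-cytochrome roles are
#' matched by sequence similarity alone.
#'
#' @param genome a `genome_annotation`.
#' @param role catalog role label.
#' @param catalog a `reference_catalog`.
#' @param profiles optional precomputed profile data.frame from
#'   [profile_genome()] (recomputed if missing).
#' @param min_id percent identity threshold, default 30.
#' @param min_cov coverage threshold (both directions), default 0.7.
#' @param min_hemes,max_hemes optional heme-count constraints.
#' @param prefilter shared-4-mer screen, see [similarity_edges()].
#' @return data.frame of hits: protein_id, locus_tag, contig_id, rank,
#'   total_hemes, identity.
#' @export
find_role_candidates <- function(genome, role, catalog, profiles = NULL,
                                 min_id = 30, min_cov = 0.7,
                                 min_hemes = NA, max_hemes = NA,
                                 prefilter = 0.02) {
  refs <- catalog$entries[catalog$entries$role_label == role, , drop = FALSE]
  if (nrow(refs) == 0L) stop_input("role not in catalog: ", role)
  if (is.null(profiles)) profiles <- profile_genome(genome)$profiles
  p <- genome$proteins
  hemes <- setNames(rep(0L, nrow(p)), p$protein_id)
  if (nrow(profiles) > 0L)
    hemes[profiles$protein_id] <- profiles$total_hemes
  empty <- data.frame(protein_id = character(0), locus_tag = character(0),
                      contig_id = character(0), rank = integer(0),
                      total_hemes = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  best <- setNames(rep(NA_real_, nrow(p)), p$protein_id)
  for (r in seq_len(nrow(refs))) {
    rseq <- refs$sequence[r]
    rk <- kmer_set(rseq)
    rlen <- nchar(rseq)
    lens <- nchar(p$sequence)
    cand <- which(pmin(lens, rlen) / pmax(lens, rlen) >= min_cov)
    if (prefilter > 0 && length(cand) > 0L) {
      ov <- vapply(p$sequence[cand],
                   function(s) kmer_overlap(kmer_set(s), rk), numeric(1))
      cand <- cand[ov >= prefilter]
    }
    if (length(cand) == 0L) next
    al <- align_many(p$sequence[cand], rseq)
    ok <- al$identity >= min_id & al$query_cov >= min_cov &
      al$target_cov >= min_cov
    for (i in which(ok)) {
      pid <- p$protein_id[cand[i]]
      if (is.na(best[pid]) || al$identity[i] > best[pid])
        best[pid] <- al$identity[i]
    }
  }
  hit_ids <- names(best)[!is.na(best)]
  if (length(hit_ids) == 0L) return(empty)
  idx <- match(hit_ids, p$protein_id)
  out <- data.frame(protein_id = hit_ids, locus_tag = p$locus_tag[idx],
                    contig_id = p$contig_id[idx], rank = p$rank[idx],
                    total_hemes = as.integer(hemes[hit_ids]),
                    identity = unname(best[hit_ids]), stringsAsFactors = FALSE)
  if (!is.na(min_hemes)) out <- out[out$total_hemes >= min_hemes, , drop = FALSE]
  if (!is.na(max_hemes)) out <- out[out$total_hemes <= max_hemes, , drop = FALSE]
  out <- out[order(out$contig_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# role candidates for every role of a definition
role_candidates_for_def <- function(genome, definition, catalog,
                                    profiles = NULL, min_id = 30,
                                    min_cov = 0.7, prefilter = 0.02) {
  if (is.null(profiles)) profiles <- profile_genome(genome)$profiles
  roles <- definition$roles
  cands <- lapply(seq_len(nrow(roles)), function(i)
    find_role_candidates(genome, roles$role[i], catalog, profiles = profiles,
                         min_id = min_id, min_cov = min_cov,
                         min_hemes = roles$min_hemes[i],
                         max_hemes = roles$max_hemes[i],
                         prefilter = prefilter))
  names(cands) <- roles$role
  cands
}

#' Call one complex in one genome
#'
#' The anchor is the first required cytochrome role (first required role with
#' a heme constraint, else the first required role). The verdict is
#' `complete` when, for some anchor hit, every required role has a hit on the
#' same contig within `window` gene ranks of the anchor; `complete-variant`
#' when additionally a role marked `variant_dup` has two or more distinct
#' hits in that window (e.g. a duplicated periplasmic PCC3 cytochrome);
#' `partial` when at least one but not all required roles have hits
#' genome-wide; `absent` otherwise. Among satisfying windows the smallest
#' rank span, then the lowest anchor rank, is chosen.
#'
#' @param genome a `genome_annotation`.
#' @param definition one element of [complex_definitions()].
#' @param candidates named list of role-candidate data.frames (from
#'   [find_role_candidates()]); computed if `NULL`.
#' @param catalog catalog used when `candidates` is `NULL`.
#' @param ... thresholds passed to the role search.
#' @return list: `genome_id`, `complex_name`, `verdict`, `subunit_map`
#'   (role -> locus tags), `anchor_contig`, `span` (rank interval).
#' @export
call_complex <- function(genome, definition, candidates = NULL,
                         catalog = reference_catalog(), ...) {
  if (is.null(candidates))
    candidates <- role_candidates_for_def(genome, definition, catalog, ...)
  roles <- definition$roles
  req <- roles$role[roles$required]
  window <- definition$window
  n_req_present <- sum(vapply(req, function(r) nrow(candidates[[r]]) > 0L,
                              logical(1)))
  result <- list(genome_id = genome$genome_id, complex_name = definition$name,
                 verdict = "absent", subunit_map = list(),
                 anchor_contig = NA_character_, span = c(NA_integer_, NA_integer_))
  if (n_req_present == 0L) return(result)
  # anchor: first required role with a heme constraint, else first required
  heme_req <- req[!is.na(roles$min_hemes[match(req, roles$role)])]
  anchor_role <- if (length(heme_req) > 0L) heme_req[1L] else req[1L]
  anchors <- candidates[[anchor_role]]
  best <- NULL
  if (nrow(anchors) > 0L) {
    for (ai in seq_len(nrow(anchors))) {
      actg <- anchors$contig_id[ai]; arank <- anchors$rank[ai]
      in_window <- function(df) {
        sel <- df$contig_id == actg & abs(df$rank - arank) <= window
        df[sel, , drop = FALSE]
      }
      picks <- list()
      ok <- TRUE
      used <- character(0)
      for (r in req) {
        w <- in_window(candidates[[r]])
        w <- w[!(w$protein_id %in% used), , drop = FALSE]
        if (nrow(w) == 0L) { ok <- FALSE; break }
        w <- w[order(abs(w$rank - arank), w$rank), , drop = FALSE]
        picks[[r]] <- w[1L, ]
        used <- c(used, w$protein_id[1L])
      }
      if (!ok) next
      ranks <- vapply(picks, function(x) x$rank, numeric(1))
      span <- max(ranks) - min(ranks)
      if (is.null(best) || span < best$span ||
          (span == best$span && arank < best$arank)) {
        # optional roles present in the same window
        opt <- setdiff(roles$role, req)
        for (r in opt) {
          w <- in_window(candidates[[r]])
          if (nrow(w) > 0L) picks[[r]] <- w
        }
        # duplicated-variant role check
        variant <- FALSE
        vroles <- roles$role[roles$variant_dup]
        for (vr in vroles) {
          w <- in_window(candidates[[vr]])
          if (nrow(w) >= 2L) variant <- TRUE
        }
        best <- list(span = span, arank = arank, contig = actg,
                     picks = picks, variant = variant,
                     lo = min(ranks), hi = max(ranks))
      }
    }
  }
  if (!is.null(best)) {
    result$verdict <- if (best$variant) "complete-variant" else "complete"
    result$subunit_map <- lapply(best$picks, function(x) x$locus_tag)
    result$anchor_contig <- best$contig
    result$span <- c(best$lo, best$hi)
  } else {
    result$verdict <- "partial"
    result$subunit_map <- lapply(candidates[req], function(x) x$locus_tag)
    result$subunit_map <-
      result$subunit_map[vapply(result$subunit_map, length, integer(1)) > 0L]
  }
  result
}

#' Genome x complex verdict matrix for a cohort
#'
#' @param genomes list of `genome_annotation` objects.
#' @param definitions list from [complex_definitions()].
#' @param catalog a `reference_catalog`.
#' @param profiles optional cohort profile data.frame from [profile_cohort()]
#'   (column `genome_id` required); recomputed if missing.
#' @param ... thresholds passed to the role search.
#' @return list with `matrix` (data.frame: genome_id x complex verdicts),
#'   `calls` (nested list of full call objects) and `summary` (verdict counts
#'   per complex).
#' @export
cohort_complex_matrix <- function(genomes, definitions = complex_definitions(),
                                  catalog = reference_catalog(),
                                  profiles = NULL, ...) {
  if (length(genomes) == 0L) {
    empty <- data.frame(genome_id = character(0))
    for (d in definitions) empty[[d$name]] <- character(0)
    return(list(matrix = empty, calls = list(),
                summary = data.frame(complex = character(0))))
  }
  calls <- lapply(genomes, function(g) {
    prof <- if (!is.null(profiles))
      profiles[profiles$genome_id == g$genome_id, , drop = FALSE]
    else profile_genome(g)$profiles
    lapply(definitions, function(d) {
      cands <- role_candidates_for_def(g, d, catalog, profiles = prof, ...)
      call_complex(g, d, candidates = cands)
    })
  })
  mat <- data.frame(
    genome_id = vapply(genomes, function(g) g$genome_id, character(1)),
    stringsAsFactors = FALSE)
  for (d in names(definitions))
    mat[[d]] <- vapply(calls, function(x) x[[d]]$verdict, character(1))
  rownames(mat) <- NULL
  verdicts <- c("complete", "complete-variant", "partial", "absent")
  summ <- do.call(rbind, lapply(names(definitions), function(d) {
    counts <- table(factor(mat[[d]], levels = verdicts))
    cbind(data.frame(complex = d, stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(counts))))
  }))
  rownames(summ) <- NULL
  list(matrix = mat, calls = calls, summary = summ)
}
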