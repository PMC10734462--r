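# Metabolic marker profiling: presence/absence of marker genes per genome
# from homology to the reference catalog, with per-group percent summaries
# and derived capability flags.

#' Detect one metabolic marker in one genome
#'
#' A marker is present when the fraction of its subunit roles with at least
#' one qualifying hit reaches `rule`. Heme-count constraints (e.g. the
#' exactly-one-heme check of the cyc2 iron oxidase, decaheme mtoA) apply to
#' cytochrome markers.
#'
#' @param genome a `genome_annotation`.
#' @param definition one row of [marker_definitions()].
#' @param catalog a `reference_catalog`.
#' @param profiles optional precomputed profiles from [profile_genome()].
#' @param min_id,min_cov,prefilter role-search thresholds.
#' @return list: `marker_name`, `present`, `n_subunits`, `n_found`,
#'   `subunit_hits` (role -> data.frame of hits).
#' @export
detect_marker <- function(genome, definition, catalog = reference_catalog(),
                          profiles = NULL, min_id = 30, min_cov = 0.7,
                          prefilter = 0.02) {
  subunits <- strsplit(definition$subunits, ";", fixed = TRUE)[[1]]
  missing_refs <- setdiff(subunits, catalog$entries$role_label)
  if (length(missing_refs) > 0L)
    stop_input("marker subunit(s) without reference: ",
               paste(missing_refs, collapse = ", "))
  if (is.null(profiles)) profiles <- profile_genome(genome)$profiles
  hits <- lapply(subunits, function(r)
    find_role_candidates(genome, r, catalog, profiles = profiles,
                         min_id = min_id, min_cov = min_cov,
                         min_hemes = definition$min_hemes,
                         max_hemes = definition$max_hemes,
                         prefilter = prefilter))
  names(hits) <- subunits
  n_found <- sum(vapply(hits, nrow, integer(1)) > 0L)
  list(marker_name = definition$marker_name,
       present = (n_found / length(subunits)) >= definition$rule,
       n_subunits = length(subunits), n_found = n_found,
       subunit_hits = hits)
}

#' Genome x marker presence/absence matrix
#'
#' @param genomes list of `genome_annotation` objects.
#' @param definitions data.frame from [marker_definitions()].
#' @param catalog a `reference_catalog`.
#' @param profiles optional cohort profiles from [profile_cohort()].
#' @param ... thresholds passed to [detect_marker()].
#' @return list with `matrix` (data.frame, genome_id + one 0/1 column per
#'   marker) and `details` (per-hit data.frame: genome_id, marker, role,
#'   locus_tag, identity).
#' @export
marker_matrix <- function(genomes, definitions = marker_definitions(),
                          catalog = reference_catalog(), profiles = NULL, ...) {
  rows <- list(); det <- list()
  for (g in genomes) {
    prof <- if (!is.null(profiles))
      profiles[profiles$genome_id == g$genome_id, , drop = FALSE]
    else profile_genome(g)$profiles
    row <- list(genome_id = g$genome_id)
    for (i in seq_len(nrow(definitions))) {
      d <- definitions[i, , drop = FALSE]
      r <- detect_marker(g, d, catalog, profiles = prof, ...)
      row[[d$marker_name]] <- as.integer(r$present)
      for (role in names(r$subunit_hits)) {
        h <- r$subunit_hits[[role]]
        if (nrow(h) > 0L)
          det[[length(det) + 1L]] <- data.frame(
            genome_id = g$genome_id, marker = d$marker_name, role = role,
            locus_tag = h$locus_tag, identity = h$identity,
            stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE,
                                               check.names = FALSE)
  }
  details <- if (length(det) > 0L) do.call(rbind, det) else
    data.frame(genome_id = character(0), marker = character(0),
               role = character(0), locus_tag = character(0),
               identity = numeric(0))
  list(matrix = do.call(rbind, rows), details = details)
}

#' Per-group marker prevalence table
#'
#' @param matrix data.frame from [marker_matrix()] (`$matrix`).
#' @param grouping named character vector genome_id -> group label.
#' @return data.frame: `group`, `n_genomes`, then one percent column per
#'   marker (100 x genomes in group with the marker / group size), plus a
#'   companion count data.frame in attribute `"counts"`.
#' @export
group_percent <- function(matrix, grouping) {
  miss <- setdiff(matrix$genome_id, names(grouping))
  if (length(miss) > 0L)
    stop_input("genomes without group label: ", paste(miss, collapse = ", "))
  groups <- grouping[matrix$genome_id]
  if (any(is.na(groups) | !nzchar(groups)))
    stop_input("empty group label")
  markers <- setdiff(names(matrix), "genome_id")
  out <- list(); cnt <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    n <- sum(sel)
    counts <- vapply(markers, function(m) sum(matrix[[m]][sel]), numeric(1))
    out[[g]] <- c(list(group = g, n_genomes = n),
                  as.list(100 * counts / n))
    cnt[[g]] <- c(list(group = g, n_genomes = n), as.list(counts))
  }
  pct <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE,
                               check.names = FALSE))
  rownames(pct) <- NULL
  counts_df <- do.call(rbind, lapply(cnt, as.data.frame,
                                     stringsAsFactors = FALSE,
                                     check.names = FALSE))
  rownames(counts_df) <- NULL
  attr(pct, "counts") <- counts_df
  pct
}

#' Derived per-genome capability flags
#'
#' Pure boolean functions of a marker-matrix row: joint and either presence
#' of the two iron-oxidation genes, and denitrification capability to N2O
#' ((narGH or napAB) and (nirK or nirS) and a nitric oxide reductase).
#'
#' @param matrix data.frame from [marker_matrix()] (`$matrix`).
#' @return data.frame: genome_id, `cyc2_and_mtoA`, `cyc2_or_mtoA`,
#'   `denitrification_to_n2o`.
#' @export
combo_flags <- function(matrix) {
  get0col <- function(m) if (m %in% names(matrix)) matrix[[m]] == 1L
  else rep(FALSE, nrow(matrix))
  cyc2 <- get0col("cyc2"); mtoA <- get0col("mtoA")
  nor <- get0col("norBC") | get0col("eNOR")
  data.frame(
    genome_id = matrix$genome_id,
    cyc2_and_mtoA = cyc2 & mtoA,
    cyc2_or_mtoA = cyc2 | mtoA,
    denitrification_to_n2o =
      (get0col("narGH") | get0col("napAB")) &
      (get0col("nirK") | get0col("nirS")) & nor,
    stringsAsFactors = FALSE)
}
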