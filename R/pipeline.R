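# End-to-end orchestration: quality filter -> heme census -> clustering ->
# classification -> complex calling -> marker profiling -> similarity
# metrics -> phylogeny, with every stage's tables written to an output
# directory and a manifest recording inputs, parameters, counts and
# checksums.

#' Run the full pipeline on a cohort
#'
#' @param cohort path to a cohort sheet TSV (see [read_cohort_sheet()]) or a
#'   named list of `genome_annotation` objects.
#' @param out_dir output directory (created if needed).
#' @param seed seed for the bootstrap stage.
#' @param min_completeness,max_contamination quality-filter thresholds.
#' @param bin_edges heme category bins.
#' @param cluster_min_cov,cluster_min_id clustering thresholds.
#' @param bootstraps phylogeny bootstrap replicates, default 100.
#' @param compute_metrics compute AAI/ANI/16S matrices (the slowest stage),
#'   default TRUE.
#' @param catalog reference catalog.
#' @return list of stage results (invisibly); artifacts and `manifest.json`
#'   written under `out_dir`.
#' @export
run_all <- function(cohort, out_dir, seed = 1L,
                    min_completeness = 80, max_contamination = 7,
                    bin_edges = c(1L, 2L, 3L, 4L, 10L),
                    cluster_min_cov = 0.8, cluster_min_id = 30,
                    bootstraps = 100L, compute_metrics = TRUE,
                    catalog = reference_catalog()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ironcensus",
                   parameters = list(
                     seed = seed, min_completeness = min_completeness,
                     max_contamination = max_contamination,
                     bin_edges = bin_edges,
                     cluster_min_cov = cluster_min_cov,
                     cluster_min_id = cluster_min_id,
                     bootstraps = bootstraps),
                   stages = list(), status = "ok")
  results <- list()
  fail <- function(stage, err) {
    manifest$status <<- paste0("failed at stage: ", stage)
    manifest$error <<- conditionMessage(err)
    write_manifest(manifest, out_dir)
    stop("stage ", stage, " failed: ", conditionMessage(err), call. = FALSE)
  }
  stage <- function(name, expr) {
    message("[", name, "] starting")
    val <- tryCatch(expr, error = function(e) fail(name, e))
    manifest$stages[[name]] <<- list(done = TRUE)
    val
  }
  genomes <- stage("load", {
    if (is.character(cohort)) load_cohort(read_cohort_sheet(cohort))
    else cohort
  })
  manifest$stages$load$n_genomes <- length(genomes)

  flt <- stage("filter", filter_cohort(genomes, min_completeness,
                                       max_contamination))
  write_tsv(flt$exclusions, file.path(out_dir, "exclusions.tsv"))
  genomes <- flt$retained
  manifest$stages$filter$n_retained <- length(genomes)
  manifest$stages$filter$n_excluded <- nrow(flt$exclusions)
  results$filter <- flt
  if (length(genomes) == 0L) {
    manifest$status <- "failed at stage: filter"
    manifest$error <- "all genomes excluded by quality filter"
    write_manifest(manifest, out_dir)
    stop("all genomes excluded by quality filter; pipeline stopped",
         call. = FALSE)
  }

  hemes <- stage("hemes", profile_cohort(genomes, bin_edges = bin_edges))
  write_tsv(hemes$profiles, file.path(out_dir, "hemes.tsv"))
  write_tsv(hemes$per_genome, file.path(out_dir, "heme_histogram.tsv"))
  manifest$stages$hemes$n_motif_proteins <- nrow(hemes$profiles)
  results$hemes <- hemes
  message("[hemes] ", nrow(hemes$profiles), " motif-bearing proteins")

  clus <- stage("cluster", {
    prot <- hemes$profiles
    seqs <- do.call(rbind, lapply(genomes, function(g)
      data.frame(protein_id = g$proteins$protein_id,
                 genome_id = g$genome_id,
                 sequence = g$proteins$sequence, stringsAsFactors = FALSE)))
    motif <- seqs[seqs$protein_id %in% prot$protein_id, , drop = FALSE]
    edges <- similarity_edges(motif, min_cov = cluster_min_cov,
                              min_id = cluster_min_id)
    cl <- greedy_cluster(motif, edges)
    labels <- classify_clusters(cl, motif, catalog)
    bins <- pangenome_bins(cl, motif, n_genomes = length(genomes))
    merged <- merge(cl, motif[, c("protein_id", "genome_id")],
                    by = "protein_id", sort = FALSE)
    merged <- merge(merged, labels[, c("cluster_id", "label", "label_source")],
                    by = "cluster_id", sort = FALSE)
    merged <- merged[order(merged$cluster_id, merged$protein_id), ]
    list(assignments = merged, labels = labels, bins = bins, edges = edges)
  })
  write_tsv(clus$assignments[, c("cluster_id", "centroid_id", "protein_id",
                                 "genome_id", "label", "label_source")],
            file.path(out_dir, "clusters.tsv"))
  write_tsv(clus$bins, file.path(out_dir, "pangenome_bins.tsv"))
  manifest$stages$cluster$n_clusters <- nrow(clus$labels)
  results$cluster <- clus
  message("[cluster] ", nrow(clus$labels), " clusters")

  cx <- stage("complexes", cohort_complex_matrix(
    genomes, catalog = catalog, profiles = hemes$profiles))
  write_tsv(cx$matrix, file.path(out_dir, "complexes.tsv"))
  write_tsv(cx$summary, file.path(out_dir, "complex_summary.tsv"))
  manifest$stages$complexes$n_complete <-
    sum(cx$summary$complete + cx$summary$`complete-variant`)
  results$complexes <- cx

  mk <- stage("markers", {
    mm <- marker_matrix(genomes, catalog = catalog,
                        profiles = hemes$profiles)
    grouping <- setNames(vapply(genomes, function(g) g$group, character(1)),
                         vapply(genomes, function(g) g$genome_id,
                                character(1)))
    pct <- group_percent(mm$matrix, grouping)
    flags <- combo_flags(mm$matrix)
    list(matrix = mm$matrix, details = mm$details, percent = pct,
         flags = flags)
  })
  write_tsv(mk$matrix, file.path(out_dir, "markers.tsv"))
  write_tsv(mk$percent, file.path(out_dir, "marker_group_percent.tsv"))
  write_tsv(mk$details, file.path(out_dir, "marker_hits.tsv"))
  write_tsv(mk$flags, file.path(out_dir, "combo_flags.tsv"))
  results$markers <- mk

  if (compute_metrics) {
    met <- stage("metrics", {
      aai_m <- similarity_matrix(genomes, "AAI")
      has_nt <- all(vapply(genomes, function(g) !is.null(g$cds_nt),
                           logical(1)))
      ani_m <- if (has_nt) similarity_matrix(genomes, "ANI") else NULL
      has_16s <- any(vapply(genomes, function(g) !is.null(g$rrna_16s),
                            logical(1)))
      s16_m <- if (has_16s) similarity_matrix(genomes, "16S") else NULL
      list(aai = aai_m, ani = ani_m, s16 = s16_m)
    })
    write_matrix_tsv(met$aai$values, file.path(out_dir, "aai.tsv"))
    write_matrix_tsv(met$aai$support, file.path(out_dir, "aai_support.tsv"))
    if (!is.null(met$ani)) {
      write_matrix_tsv(met$ani$values, file.path(out_dir, "ani.tsv"))
      write_matrix_tsv(met$ani$support, file.path(out_dir, "ani_support.tsv"))
    }
    if (!is.null(met$s16))
      write_matrix_tsv(met$s16$values, file.path(out_dir, "rrna_identity.tsv"))
    results$metrics <- met
  }

  tre <- stage("tree", {
    mks <- extract_markers(genomes, catalog = catalog)
    blocks <- lapply(mks$sequences, align_marker)
    ids <- vapply(genomes, function(g) g$genome_id, character(1))
    concat <- mask_and_concat(blocks, genome_ids = ids,
                              marker_order = names(mks$sequences))
    tree <- nj_tree(concat$alignment, bootstraps = bootstraps, seed = seed)
    list(markers = mks, concat = concat, tree = tree)
  })
  ape::write.tree(tre$tree, file.path(out_dir, "tree.nwk"))
  write_fasta(rownames(tre$concat$alignment),
              apply(tre$concat$alignment, 1L, paste, collapse = ""),
              file.path(out_dir, "concat_alignment.fasta"))
  write_tsv(tre$concat$column_map, file.path(out_dir, "column_map.tsv"))
  results$tree <- tre

  write_manifest(manifest, out_dir)
  results$manifest <- manifest
  invisible(results)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

write_manifest <- function(manifest, out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  paths <- file.path(out_dir, files)
  manifest$outputs <- lapply(seq_along(files), function(i)
    list(file = files[i], size = file.info(paths[i])$size,
         md5 = unname(tools::md5sum(paths[i]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Cohort summary report
#'
#' Collects the pipeline's headline tables — per-genome heme histogram,
#' genome x marker matrix with group percents, genome x complex verdicts,
#' similarity matrices and the Newick tree — into one JSON report mirroring
#' the written TSVs.
#'
#' @param results list returned by [run_all()].
#' @param path optional path for the JSON report.
#' @return the report list, invisibly.
#' @export
summary_report <- function(results, path = NULL) {
  need <- c("hemes", "complexes", "markers", "tree")
  miss <- need[!need %in% names(results)]
  if (length(miss) > 0L)
    stop_input("missing stage output(s): ", paste(miss, collapse = ", "))
  report <- list(
    heme_histogram = results$hemes$per_genome,
    marker_matrix = results$markers$matrix,
    marker_group_percent = results$markers$percent,
    complex_verdicts = results$complexes$matrix,
    complex_summary = results$complexes$summary,
    tree_newick = ape::write.tree(results$tree$tree))
  if (!is.null(results$metrics)) {
    report$aai <- as.data.frame(results$metrics$aai$values)
    if (!is.null(results$metrics$ani))
      report$ani <- as.data.frame(results$metrics$ani$values)
  }
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(report)
}
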