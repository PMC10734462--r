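# Readers for the external formats the pipeline touches (protein FASTA, GFF3
# CDS subset, cohort sheet) and assembly of per-genome annotation objects.

#' Read a protein (or nucleotide) FASTA file
#'
#' Minimal multi-record FASTA reader: headers start with `>`, sequences may be
#' wrapped over any number of lines and are uppercased on ingest. The first
#' whitespace-delimited token of the header is the record id, the remainder its
#' description.
#'
#' @param path path to a FASTA file.
#' @return `data.frame` with columns `id`, `description`, `sequence`, in file
#'   order.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MCAA", "CHK"), tf)
#' read_protein_fasta(tf)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_input("no records in ", path)
  rec <- cumsum(hdr)
  if (any(rec == 0L)) stop_input("sequence before first header in ", path)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out_seq <- character(length(ids))
  names_present <- names(seqs)
  out_seq[as.integer(names_present)] <- seqs
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_input("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(out_seq)))
    stop_input("empty sequence for record(s): ",
               paste(ids[!nzchar(out_seq)], collapse = ", "))
  data.frame(id = ids, description = desc, sequence = out_seq,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#' @param ids,sequences character vectors of equal length.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Consumes only rows with feature type `CDS`. Coordinates are kept 1-based
#' inclusive as on disk. The `ID` attribute is required; `locus_tag` falls back
#' to `ID` when absent.
#'
#' @param path path to a GFF3 file (tab-separated, 9 columns).
#' @return `data.frame` with columns `contig_id`, `start`, `end`, `strand`,
#'   `locus_tag`, `protein_id`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  out <- list()
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    if (f[3] != "CDS") next
    start <- as.integer(f[4]); end <- as.integer(f[5])
    if (is.na(start) || is.na(end) || end < start)
      stop_input("CDS with end < start at line ", i)
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    id <- vals[match("ID", keys)]
    if (is.na(id) || !nzchar(id))
      stop_input("CDS without ID attribute at line ", i)
    lt <- vals[match("locus_tag", keys)]
    if (is.na(lt) || !nzchar(lt)) lt <- id
    out[[length(out) + 1L]] <- data.frame(
      contig_id = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else "unknown",
      locus_tag = lt, protein_id = id, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      locus_tag = character(0), protein_id = character(0)))
  do.call(rbind, out)
}

#' Assemble a genome annotation from FASTA and CDS records
#'
#' Joins protein sequences onto CDS coordinates and assigns a 0-based
#' gene-order `rank` per contig by ascending start coordinate. Metadata
#' (genome id, group, completeness, contamination) is copied verbatim from the
#' cohort-sheet row.
#'
#' @param fasta `data.frame` from [read_protein_fasta()].
#' @param cds `data.frame` from [read_gff_cds()].
#' @param meta list or one-row data.frame with at least `genome_id`, `group`,
#'   `completeness`, `contamination`.
#' @param rrna_16s optional 16S rRNA nucleotide sequence.
#' @param cds_nt optional `data.frame` of nucleotide gene records with columns
#'   `id`, `type` (`CDS`/`rRNA`/`tRNA`), `sequence` (used by [ani()]).
#' @return A `genome_annotation` list with element `proteins`, a data.frame
#'   holding one row per CDS (protein_id, locus_tag, contig_id, rank, strand,
#'   start, end, sequence).
#' @export
assemble_genome <- function(fasta, cds, meta, rrna_16s = NULL, cds_nt = NULL) {
  miss <- setdiff(cds$protein_id, fasta$id)
  if (length(miss) > 0L)
    stop_input("CDS without sequence: ", paste(miss, collapse = ", "))
  extra <- setdiff(fasta$id, cds$protein_id)
  if (length(extra) > 0L)
    message(length(extra), " FASTA record(s) without CDS ignored for genome ",
            meta$genome_id)
  p <- cds
  p$sequence <- fasta$sequence[match(p$protein_id, fasta$id)]
  p <- p[order(p$contig_id, p$start, p$protein_id), , drop = FALSE]
  p$rank <- as.integer(stats::ave(seq_len(nrow(p)), p$contig_id,
                                  FUN = seq_along)) - 1L
  rownames(p) <- NULL
  g <- list(genome_id = as.character(meta$genome_id),
            group = as.character(meta$group %||% NA_character_),
            completeness = as.numeric(meta$completeness %||% NA_real_),
            contamination = as.numeric(meta$contamination %||% NA_real_),
            proteins = p[, c("protein_id", "locus_tag", "contig_id", "rank",
                             "strand", "start", "end", "sequence")],
            rrna_16s = rrna_16s,
            cds_nt = cds_nt)
  class(g) <- "genome_annotation"
  g
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>", x$genome_id, "group:", x$group,
      sprintf("(%d proteins, completeness %.1f%%, contamination %.1f%%)\n",
              nrow(x$proteins), x$completeness, x$contamination))
  invisible(x)
}

#' Read a cohort sheet
#'
#' Tab-separated with header columns `genome_id`, `group`, `fasta`, `gff`,
#' `completeness`, `contamination` and optionally `cds_nt` and `rrna_16s`
#' (paths). Relative paths are resolved against the sheet's directory.
#'
#' @param path path to the cohort TSV.
#' @return `data.frame`, one row per genome.
#' @export
read_cohort_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genome_id", "group", "fasta", "gff", "completeness", "contamination")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0L)
    stop_input("cohort sheet missing column(s): ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "", p,
                            ifelse(grepl("^/", p), p, file.path(base, p)))
  for (col in intersect(c("fasta", "gff", "cds_nt", "rrna_16s"), names(sheet)))
    sheet[[col]] <- fix(sheet[[col]])
  sheet
}

#' Load all genomes listed in a cohort sheet
#' @param sheet data.frame from [read_cohort_sheet()].
#' @return list of `genome_annotation` objects, named by genome id.
#' @export
load_cohort <- function(sheet) {
  genomes <- lapply(seq_len(nrow(sheet)), function(i) {
    row <- sheet[i, , drop = FALSE]
    fasta <- read_protein_fasta(row$fasta)
    cds <- read_gff_cds(row$gff)
    rrna <- NULL
    if (!is.null(row$rrna_16s) && !is.na(row$rrna_16s) && nzchar(row$rrna_16s) &&
        file.exists(row$rrna_16s)) {
      rr <- read_protein_fasta(row$rrna_16s)
      rrna <- rr$sequence[1]
    }
    cds_nt <- NULL
    if (!is.null(row$cds_nt) && !is.na(row$cds_nt) && nzchar(row$cds_nt) &&
        file.exists(row$cds_nt)) {
      nt <- read_protein_fasta(row$cds_nt)
      type <- ifelse(grepl("type=rRNA", nt$description), "rRNA",
                     ifelse(grepl("type=tRNA", nt$description), "tRNA", "CDS"))
      cds_nt <- data.frame(id = nt$id, type = type, sequence = nt$sequence,
                           stringsAsFactors = FALSE)
    }
    assemble_genome(fasta, cds, row, rrna_16s = rrna, cds_nt = cds_nt)
  })
  names(genomes) <- sheet$genome_id
  genomes
}

#' Quality-filter a genome cohort
#'
#' Retains genomes with completeness at or above `min_completeness` and
#' contamination at or below `max_contamination`; the boundary values
#' themselves are retained (removal requires strictly lower completeness or
#' strictly higher contamination).
#'
#' @param genomes list of `genome_annotation` objects.
#' @param min_completeness percent, default 80.
#' @param max_contamination percent, default 7.
#' @return list with `retained` (genome list) and `exclusions` (data.frame
#'   genome_id, completeness, contamination, reason).
#' @export
filter_cohort <- function(genomes, min_completeness = 80, max_contamination = 7) {
  comp <- vapply(genomes, function(g) g$completeness, numeric(1))
  cont <- vapply(genomes, function(g) g$contamination, numeric(1))
  bad_comp <- comp < min_completeness
  bad_cont <- cont > max_contamination
  drop <- bad_comp | bad_cont
  reason <- ifelse(bad_comp & bad_cont, "completeness;contamination",
                   ifelse(bad_comp, "completeness", "contamination"))
  exclusions <- data.frame(
    genome_id = vapply(genomes, function(g) g$genome_id, character(1))[drop],
    completeness = comp[drop], contamination = cont[drop],
    reason = reason[drop], stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  if (all(drop)) warning("all genomes excluded by quality filter")
  list(retained = genomes[!drop], exclusions = exclusions)
}
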