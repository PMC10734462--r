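# Synthetic reference catalog. Real isolate reference proteins (e.g. the
# S. lithotrophicus ES-1 Mto and Slit_1321-1325 loci) cannot be shipped, so
# the package generates a deterministic synthetic catalog whose roles, heme
# counts and complex memberships mirror the field's described architectures:
# Cyc2 (fused monoheme cytochrome-porin), MtoAB(+MtrC) porin-decaheme
# complex, PCC3 (periplasmic >= 20-heme MHC, 10-35-heme extracellular MHC,
# porin, inner-membrane protein), the undecaheme Uet complex, and the
# Slit-type periplasmic cytochrome gene cluster. Background residues exclude
# C and H so heme-binding motifs occur only where planted.

CATALOG_SEED <- 104729L

# role table: role, complex, hemes planted in the reference, min/max heme
# expectation used by role searches (NA = unconstrained), reference length
catalog_role_table <- function() {
  r <- function(role, complex, hemes, lo, hi, len)
    data.frame(role_label = role, complex_name = complex, hemes = hemes,
               expected_min_hemes = lo, expected_max_hemes = hi, length = len,
               stringsAsFactors = FALSE)
  rbind(
    r("cyc2", "Cyc2", 1L, 1L, 1L, 420L),
    r("mtoA", "Mto", 10L, 10L, 10L, 330L),
    r("mtoB", "Mto", 0L, NA, NA, 280L),
    r("mtoC", "Mto", 4L, NA, NA, 200L),
    r("mtoD", "Mto", 1L, 1L, 1L, 120L),
    r("cymA", "Mto", 4L, NA, NA, 190L),
    r("mtrC", "Mto", 10L, 10L, 10L, 310L),
    r("pcc3_periplasmic", "PCC3", 24L, 20L, NA, 400L),
    r("pcc3_extracellular", "PCC3", 14L, 10L, 35L, 350L),
    r("pcc3_porin", "PCC3", 0L, NA, NA, 260L),
    r("pcc3_imp", "PCC3", 0L, NA, NA, 210L),
    r("uetA", "Uet", 4L, 4L, 4L, 160L),
    r("uetJ", "Uet", 11L, 11L, 11L, 230L),
    r("uetB", "Uet", 0L, NA, NA, 170L),
    r("uetC", "Uet", 0L, NA, NA, 260L),
    r("uetD", "Uet", 3L, 3L, 3L, 130L),
    r("uetE", "Uet", 3L, 3L, 3L, 135L),
    r("uetG", "Uet", 3L, 3L, 3L, 140L),
    r("uetH", "Uet", 0L, NA, NA, 150L),
    r("uetI", "Uet", 0L, NA, NA, 155L),
    r("slit1321", "Slit", 0L, NA, NA, 180L),
    r("slit1322", "Slit", 0L, NA, NA, 140L),
    r("slit1323", "Slit", 1L, 1L, 1L, 110L),
    r("slit1324", "Slit", 2L, 2L, 2L, 120L),
    r("slit1325", "Slit", 0L, NA, NA, 200L)
  )
}

# metabolic marker subunit roles (no heme constraint; detected by homology)
marker_subunit_roles <- function() {
  c("nxrA", "nxrB", "ccoN", "cydA", "cydB", "bc1", "acIII",
    "narG", "narH", "napA", "napB", "nasA", "nirK", "nirS", "nirB", "nirD",
    "norB", "norC", "eNOR", "nosZ",
    "soxA", "soxB", "soxX", "soxY", "soxZ", "dsrA", "dsrB", "sqr",
    "sorA", "sorB",
    "hoxF", "hoxU", "hoxH", "hoxY", "hyaA", "hyaB", "hupU", "hupV",
    "cbbL", "cbbS", "cbbM", "cbbQ",
    "lutA", "lutB", "lutC", "lutP", "gtsA", "gtsB", "gtsC", "msmX",
    "sfz", "nifD", "nifH", "nifK", "mcoA", "moxA", "mofA", "mnxG")
}

# the 13 ribosomal proteins of the concatenated phylogeny
RIBO_MARKERS <- c("L19", "L20", "L28", "L17", "L9_C", "S16", "L21p", "L27",
                  "L35p", "S11", "S20p", "S6", "S9")

# Build one sequence with `hemes` planted motifs; returns chars + anchor mask.
plant_motifs <- function(len, hemes) {
  chars <- sample(AA_BACKGROUND, len, replace = TRUE)
  protected <- logical(len)
  if (hemes > 0L) {
    seg <- len %/% hemes
    stopifnot(seg >= 9L)
    for (h in seq_len(hemes)) {
      span <- sample(5:7, 1L)
      off <- sample.int(seg - span - 1L, 1L)
      s <- (h - 1L) * seg + off
      chars[s] <- "C"
      chars[s + span - 2L] <- "C"
      chars[s + span - 1L] <- "H"
      protected[c(s, s + span - 2L, s + span - 1L)] <- TRUE
    }
  }
  list(chars = chars, protected = protected)
}

#' Synthetic labelled reference catalog
#'
#' Deterministically generated catalog of reference proteins for complex
#' subunit roles (Cyc2, Mto, PCC3, Uet, Slit cluster), metabolic marker
#' subunits and the 13 ribosomal phylogeny markers. Sequences are synthetic;
#' roles, planted heme counts and heme-count expectations follow the
#' described complex architectures.
#'
#' @return object of class `reference_catalog`: list with `entries`
#'   (data.frame: ref_id, role_label, complex_name, expected_min_hemes,
#'   expected_max_hemes, hemes, sequence) and `anchors` (named list of
#'   protected motif-anchor positions per ref_id, used by the simulator).
#' @export
reference_catalog <- function() {
  if (!is.null(.align_env$catalog)) return(.align_env$catalog)
  cat <- with_seed(CATALOG_SEED, {
    roles <- catalog_role_table()
    ms <- marker_subunit_roles()
    roles <- rbind(roles, data.frame(
      role_label = ms, complex_name = NA_character_, hemes = 0L,
      expected_min_hemes = NA_integer_, expected_max_hemes = NA_integer_,
      length = sample(150:300, length(ms), replace = TRUE),
      stringsAsFactors = FALSE))
    roles <- rbind(roles, data.frame(
      role_label = paste0("ribo_", RIBO_MARKERS), complex_name = NA_character_,
      hemes = 0L, expected_min_hemes = NA_integer_,
      expected_max_hemes = NA_integer_,
      length = sample(95:140, length(RIBO_MARKERS), replace = TRUE),
      stringsAsFactors = FALSE))
    seqs <- character(nrow(roles))
    anchors <- vector("list", nrow(roles))
    for (i in seq_len(nrow(roles))) {
      pm <- plant_motifs(roles$length[i], roles$hemes[i])
      seqs[i] <- chars_to_seq(pm$chars)
      anchors[[i]] <- which(pm$protected)
    }
    entries <- cbind(ref_id = paste0("ref_", roles$role_label), roles,
                     stringsAsFactors = FALSE)
    entries$sequence <- seqs
    names(anchors) <- entries$ref_id
    structure(list(entries = entries[, c("ref_id", "role_label",
                                         "complex_name", "expected_min_hemes",
                                         "expected_max_hemes", "hemes",
                                         "sequence")],
                   anchors = anchors),
              class = "reference_catalog")
  })
  .align_env$catalog <- cat
  cat
}

#' @export
print.reference_catalog <- function(x, ...) {
  cat("<reference_catalog>", nrow(x$entries), "synthetic reference entries,",
      sum(x$entries$hemes > 0), "heme-bearing\n")
  invisible(x)
}

#' Shipped porin-cytochrome complex and gene-cluster definitions
#'
#' Role composition, heme-count constraints and colocalization windows for
#' the five shipped complex/cluster models: Cyc2 (single fused
#' cytochrome-porin gene, exactly one heme), MtoAB core (decaheme MtoA plus
#' porin MtoB required; MtoC/MtoD/CymA/MtrC optional), PCC3 (>=20-heme
#' periplasmic MHC, 10-35-heme extracellular MHC, porin and inner-membrane
#' protein all required; a duplicated periplasmic MHC marks the
#' complete-variant form), Uet (UetA/J/D/E/G cytochromes with fixed heme
#' counts plus UetB/H/I required; the UetC porin optional), and the Slit-type
#' periplasmic cluster (cytochrome b, monoheme and diheme cytochromes
#' required; hypothetical protein and chaperone optional).
#'
#' @param window maximum gene-rank separation from the anchor subunit,
#'   default 15.
#' @return named list of complex definitions; each has `name`, `window`,
#'   `same_contig` and a `roles` data.frame (`role`, `required`, `min_hemes`,
#'   `max_hemes`, `variant_dup`).
#' @export
complex_definitions <- function(window = 15L) {
  role_df <- function(role, required, lo, hi, vd = FALSE)
    data.frame(role = role, required = required, min_hemes = lo, max_hemes = hi,
               variant_dup = vd, stringsAsFactors = FALSE)
  defs <- list(
    Cyc2 = list(name = "Cyc2", window = 1L, same_contig = TRUE, roles = rbind(
      role_df("cyc2", TRUE, 1L, 1L))),
    Mto = list(name = "Mto", window = window, same_contig = TRUE, roles = rbind(
      role_df("mtoA", TRUE, 10L, 10L),
      role_df("mtoB", TRUE, NA_integer_, NA_integer_),
      role_df("mtoC", FALSE, NA_integer_, NA_integer_),
      role_df("mtoD", FALSE, 1L, 1L),
      role_df("cymA", FALSE, NA_integer_, NA_integer_),
      role_df("mtrC", FALSE, 10L, 10L))),
    PCC3 = list(name = "PCC3", window = window, same_contig = TRUE, roles = rbind(
      role_df("pcc3_periplasmic", TRUE, 20L, NA_integer_, vd = TRUE),
      role_df("pcc3_extracellular", TRUE, 10L, 35L),
      role_df("pcc3_porin", TRUE, NA_integer_, NA_integer_),
      role_df("pcc3_imp", TRUE, NA_integer_, NA_integer_))),
    Uet = list(name = "Uet", window = window, same_contig = TRUE, roles = rbind(
      role_df("uetA", TRUE, 4L, 4L),
      role_df("uetJ", TRUE, 11L, 11L),
      role_df("uetD", TRUE, 3L, 3L),
      role_df("uetE", TRUE, 3L, 3L),
      role_df("uetG", TRUE, 3L, 3L),
      role_df("uetB", TRUE, NA_integer_, NA_integer_),
      role_df("uetH", TRUE, NA_integer_, NA_integer_),
      role_df("uetI", TRUE, NA_integer_, NA_integer_),
      role_df("uetC", FALSE, NA_integer_, NA_integer_))),
    Slit = list(name = "Slit", window = window, same_contig = TRUE, roles = rbind(
      role_df("slit1321", TRUE, NA_integer_, NA_integer_),
      role_df("slit1323", TRUE, 1L, 1L),
      role_df("slit1324", TRUE, 2L, 2L),
      role_df("slit1322", FALSE, NA_integer_, NA_integer_),
      role_df("slit1325", FALSE, NA_integer_, NA_integer_)))
  )
  defs
}

#' Shipped metabolic marker definitions
#'
#' Marker genes (iron oxidation, nitrite oxidation, respiration,
#' denitrification, sulfur oxidation, hydrogenases, carbon fixation and
#' utilization, nitrogen fixation, stalk formation, manganese oxidation) with
#' their subunit roles and the fraction of subunits required for a presence
#' call (`rule`, default 1 = all subunits; soxABXYZ uses 0.8). The cyc2 and
#' mtoA markers additionally carry the heme-count constraints of their roles.
#' Manganese-oxidase markers are flagged low-confidence.
#'
#' @return data.frame: `marker_name`, `subunits` (semicolon-joined role
#'   labels), `rule`, `min_hemes`, `max_hemes`, `low_confidence`.
#' @export
marker_definitions <- function() {
  m <- function(name, subunits, rule = 1.0, lo = NA_integer_,
                hi = NA_integer_, lowconf = FALSE)
    data.frame(marker_name = name, subunits = paste(subunits, collapse = ";"),
               rule = rule, min_hemes = lo, max_hemes = hi,
               low_confidence = lowconf, stringsAsFactors = FALSE)
  rbind(
    m("cyc2", "cyc2", lo = 1L, hi = 1L),
    m("mtoA", "mtoA", lo = 10L, hi = 10L),
    m("nxrAB", c("nxrA", "nxrB")),
    m("ccoN", "ccoN"),
    m("cydAB", c("cydA", "cydB")),
    m("bc1", "bc1"),
    m("ACIII", "acIII"),
    m("narGH", c("narG", "narH")),
    m("napAB", c("napA", "napB")),
    m("nasA", "nasA"),
    m("nirK", "nirK"),
    m("nirS", "nirS"),
    m("nirBD", c("nirB", "nirD")),
    m("norBC", c("norB", "norC")),
    m("eNOR", "eNOR"),
    m("nosZ", "nosZ"),
    m("soxABXYZ", c("soxA", "soxB", "soxX", "soxY", "soxZ"), rule = 0.8),
    m("dsrAB", c("dsrA", "dsrB")),
    m("sqr", "sqr"),
    m("sorAB", c("sorA", "sorB")),
    m("hoxFUHY", c("hoxF", "hoxU", "hoxH", "hoxY")),
    m("hyaAB", c("hyaA", "hyaB")),
    m("hupUV", c("hupU", "hupV")),
    m("cbbLS", c("cbbL", "cbbS")),
    m("cbbMQ", c("cbbM", "cbbQ")),
    m("lutABCP", c("lutA", "lutB", "lutC", "lutP")),
    m("gtsABC", c("gtsA", "gtsB", "gtsC")),
    m("msmX", "msmX"),
    m("sfz", "sfz"),
    m("nifDHK", c("nifD", "nifH", "nifK")),
    m("mcoA", "mcoA", lowconf = TRUE),
    m("moxA", "moxA", lowconf = TRUE),
    m("mofA", "mofA", lowconf = TRUE),
    m("mnxG", "mnxG", lowconf = TRUE)
  )
}
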