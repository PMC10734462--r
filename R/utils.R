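#' @keywords internal
"_PACKAGE"

#' @importFrom stats hclust as.dist setNames runif ave rpois
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so deterministic internals (catalog generation,
#' bootstraps) never disturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 18-letter background alphabet: the 20 standard residues minus C and H, so
# heme-binding motifs occur only where deliberately planted.
AA_BACKGROUND <- c("A","D","E","F","G","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
AA_STANDARD   <- sort(c(AA_BACKGROUND, "C", "H"))

random_background_seq <- function(len) {
  paste(sample(AA_BACKGROUND, len, replace = TRUE), collapse = "")
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

#' Distinct k-mers of a sequence
#' @param s character scalar sequence.
#' @param k word length.
#' @return character vector of distinct k-mers (empty if `nchar(s) < k`).
#' @keywords internal
kmer_set <- function(s, k = 4L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# Fraction of the smaller k-mer set shared by both sequences.
kmer_overlap <- function(ka, kb) {
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

stop_input <- function(...) stop(..., call. = FALSE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
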