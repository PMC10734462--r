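# Progressive multiple alignment for phylogeny markers: k-mer distances, a
# UPGMA guide tree, and profile-profile global alignment with affine gaps
# (Gotoh three-state recursion, row-vectorized). Deterministic: sequences are
# processed in canonical name order regardless of input order.

msa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K",
                             "M","F","P","S","T","W","Y","V","B","Z","X")

# column frequency matrix (alphabet x columns); gaps contribute zero weight
profile_freq <- function(block, alpha) {
  L <- ncol(block)
  f <- matrix(0, length(alpha), L, dimnames = list(alpha, NULL))
  for (j in seq_len(L)) {
    tab <- table(factor(block[, j][block[, j] != "-"], levels = alpha))
    f[, j] <- as.numeric(tab) / nrow(block)
  }
  f
}

# Global profile-profile alignment; returns merged character matrix.
profile_align <- function(A, B, open = 12, ext = 1) {
  alpha <- msa_alphabet()
  M62 <- blosum62()[alpha, alpha]
  FA <- profile_freq(A, alpha)
  FB <- profile_freq(B, alpha)
  S <- t(FA) %*% M62 %*% FB
  la <- ncol(A); lb <- ncol(B)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)  # gap columns in B (consume A)
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap columns in A (consume B)
  M[1L, 1L] <- 0
  if (la > 0L) X[2L:(la + 1L), 1L] <- -open - ext * (seq_len(la) - 1L)
  if (lb > 0L) Y[1L, 2L:(lb + 1L)] <- -open - ext * (seq_len(lb) - 1L)
  jj <- seq_len(lb)
  for (i in seq_len(la)) {
    bp <- pmax(M[i, ], X[i, ], Y[i, ])
    M[i + 1L, jj + 1L] <- S[i, ] + bp[jj]
    X[i + 1L, ] <- pmax(M[i, ] - open, X[i, ] - ext)
    # Y row: unrolled running max of current-row M scores
    a <- M[i + 1L, jj] + ext * jj
    Y[i + 1L, jj + 1L] <- cummax(a) - open - ext * (jj + 1L - 1L)
    Y[i + 1L, 1L] <- NEG
  }
  # traceback
  path <- matrix(0L, 0L, 2L)
  i <- la; j <- lb
  state <- which.max(c(M[i + 1L, j + 1L], X[i + 1L, j + 1L], Y[i + 1L, j + 1L]))
  ops <- list()
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ops[[length(ops) + 1L]] <- c(i, j)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      ops[[length(ops) + 1L]] <- c(i, 0L)
      if (i > 1L && abs(X[i + 1L, j + 1L] - (X[i, j + 1L] - ext)) < tol)
        state <- 2L
      else state <- 1L
      i <- i - 1L
    } else {
      ops[[length(ops) + 1L]] <- c(0L, j)
      if (j > 1L && abs(Y[i + 1L, j + 1L] - (Y[i + 1L, j] - ext)) < tol)
        state <- 3L
      else state <- 1L
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  ops <- rev(ops)
  L <- length(ops)
  out <- matrix("-", nrow(A) + nrow(B), L)
  rownames(out) <- c(rownames(A), rownames(B))
  for (k in seq_len(L)) {
    o <- ops[[k]]
    if (o[1] > 0L) out[seq_len(nrow(A)), k] <- A[, o[1]]
    if (o[2] > 0L) out[nrow(A) + seq_len(nrow(B)), k] <- B[, o[2]]
  }
  out
}

#' Progressive multiple alignment of one marker's sequences
#'
#' Pairwise k-mer distances feed a UPGMA guide tree; profiles are merged
#' bottom-up with global affine-gap profile alignment. Input row order does
#' not affect the result (sequences are processed in name order and the
#' original order is restored on output).
#'
#' @param sequences named character vector (>= 1 sequences).
#' @param gap_open,gap_extend affine gap costs for profile merges (cost of a
#'   length-L gap is `gap_open + (L-1) * gap_extend`).
#' @return character matrix, one row per input sequence (original order),
#'   gaps as `"-"`.
#' @export
align_marker <- function(sequences, gap_open = 12, gap_extend = 1) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences)))
    stop_input("sequences must have unique non-empty names")
  orig <- names(sequences)
  sequences <- sequences[order(names(sequences))]
  n <- length(sequences)
  if (n == 1L) {
    m <- matrix(seq_to_chars(sequences[[1]]), 1L)
    rownames(m) <- names(sequences)
    return(m[orig, , drop = FALSE])
  }
  ks <- lapply(sequences, kmer_set, k = 3L)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- 1 - kmer_overlap(ks[[i]], ks[[j]])
  hc <- hclust(as.dist(d), method = "average")
  blocks <- lapply(seq_len(n), function(i) {
    m <- matrix(seq_to_chars(sequences[[i]]), 1L)
    rownames(m) <- names(sequences)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    get_block <- function(idx) if (idx < 0L) blocks[[-idx]] else merged[[idx]]
    merged[[k]] <- profile_align(get_block(hc$merge[k, 1L]),
                                 get_block(hc$merge[k, 2L]),
                                 open = gap_open, ext = gap_extend)
  }
  out <- merged[[n - 1L]]
  out[orig, , drop = FALSE]
}

#' Mask gappy columns and concatenate marker alignments
#'
#' Emulates the usual manual curation of concatenated marker alignments:
#' leading/trailing columns are trimmed while their gap fraction exceeds
#' `end_trim`, then all columns with gap fraction strictly greater than
#' `gap_threshold` are masked, then blocks are concatenated in fixed
#' marker-name order with absent genomes padded by gaps.
#'
#' @param blocks named list of character matrices (rows = genomes); the
#'   concatenation order is the sorted block name order unless `marker_order`
#'   is given.
#' @param genome_ids character vector of all genomes for the concatenated
#'   matrix.
#' @param gap_threshold mask columns with gap fraction > this (strict),
#'   default 0.70.
#' @param end_trim trim end columns while gap fraction > this, default 0.5;
#'   `NA` disables end trimming.
#' @param marker_order optional explicit block order.
#' @return list: `alignment` (genome x column character matrix), `column_map`
#'   (data.frame: column, marker, marker_column), `dropped_blocks`.
#' @export
mask_and_concat <- function(blocks, genome_ids, gap_threshold = 0.70,
                            end_trim = 0.5, marker_order = NULL) {
  order_names <- marker_order %||% sort(names(blocks))
  pieces <- list(); maps <- list(); dropped <- character(0)
  for (mk in order_names) {
    b <- blocks[[mk]]
    if (is.null(b)) next
    gapfrac <- colMeans(b == "-")
    keep <- rep(TRUE, ncol(b))
    if (!is.na(end_trim)) {
      lo <- 1L
      while (lo <= ncol(b) && gapfrac[lo] > end_trim) { keep[lo] <- FALSE; lo <- lo + 1L }
      hi <- ncol(b)
      while (hi >= 1L && gapfrac[hi] > end_trim) { keep[hi] <- FALSE; hi <- hi - 1L }
    }
    keep <- keep & (gapfrac <= gap_threshold)
    if (!any(keep)) {
      warning("all columns masked in block ", mk, "; block dropped")
      dropped <- c(dropped, mk)
      next
    }
    cols <- which(keep)
    sub <- b[, cols, drop = FALSE]
    full <- matrix("-", length(genome_ids), ncol(sub),
                   dimnames = list(genome_ids, NULL))
    present <- intersect(genome_ids, rownames(sub))
    full[present, ] <- sub[present, ]
    pieces[[mk]] <- full
    maps[[mk]] <- data.frame(marker = mk, marker_column = cols,
                             stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) stop_input("no alignment columns retained")
  alignment <- do.call(cbind, pieces)
  colnames(alignment) <- NULL
  column_map <- do.call(rbind, maps)
  column_map <- cbind(column = seq_len(nrow(column_map)), column_map)
  rownames(column_map) <- NULL
  list(alignment = alignment, column_map = column_map,
       dropped_blocks = dropped)
}
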