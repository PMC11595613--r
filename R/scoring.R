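# Canonical NCBI BLOSUM62 (half-bit) 20x20 table, row/column order
# ARNDCQEGHILKMFPSTWYV; checksum-tested against an independent copy.
.BLOSUM62_TEXT <- "
  4  -1  -2  -2   0  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0  -3  -2   0
 -1   5   0  -2  -3   1   0  -2   0  -3  -2   2  -1  -3  -2  -1  -1  -3  -2  -3
 -2   0   6   1  -3   0   0   0   1  -3  -3   0  -2  -3  -2   1   0  -4  -2  -3
 -2  -2   1   6  -3   0   2  -1  -1  -3  -4  -1  -3  -3  -1   0  -1  -4  -3  -3
  0  -3  -3  -3   9  -3  -4  -3  -3  -1  -1  -3  -1  -2  -3  -1  -1  -2  -2  -1
 -1   1   0   0  -3   5   2  -2   0  -3  -2   1   0  -3  -1   0  -1  -2  -1  -2
 -1   0   0   2  -4   2   5  -2   0  -3  -3   1  -2  -3  -1   0  -1  -3  -2  -2
  0  -2   0  -1  -3  -2  -2   6  -2  -4  -4  -2  -3  -3  -2   0  -2  -2  -3  -3
 -2   0   1  -1  -3   0   0  -2   8  -3  -3  -1  -2  -1  -2  -1  -2  -2   2  -3
 -1  -3  -3  -3  -1  -3  -3  -4  -3   4   2  -3   1   0  -3  -2  -1  -3  -1   3
 -1  -2  -3  -4  -1  -2  -3  -4  -3   2   4  -2   2   0  -3  -2  -1  -2  -1   1
 -1   2   0  -1  -3   1   1  -2  -1  -3  -2   5  -1  -3  -1   0  -1  -3  -2  -2
 -1  -1  -2  -3  -1   0  -2  -3  -2   1   2  -1   5   0  -2  -1  -1  -1  -1   1
 -2  -3  -3  -3  -2  -3  -3  -3  -1   0   0  -3   0   6  -4  -2  -2   1   3  -1
 -1  -2  -2  -1  -3  -1  -1  -2  -2  -3  -3  -1  -2  -4   7  -1  -1  -4  -3  -2
  1  -1   1   0  -1   0   0   0  -1  -2  -2   0  -1  -2  -1   4   1  -3  -2  -2
  0  -1   0  -1  -1  -1  -1  -2  -2  -1  -1  -1  -1  -2  -1   1   5  -2  -2   0
 -3  -3  -4  -4  -2  -2  -3  -2  -2  -3  -2  -3  -1   1  -4  -3  -2  11   2  -3
 -2  -2  -2  -3  -2  -1  -2  -3   2  -1  -1  -2  -1   3  -3  -2  -2   2   7  -1
  0  -3  -3  -3  -1  -2  -2  -3  -3   3   1  -2   1  -1  -2  -2   0  -3  -1   4"

.BLOSUM62 <- {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  v <- scan(text = .BLOSUM62_TEXT, what = integer(), quiet = TRUE)
  m <- matrix(v, nrow = 20, ncol = 20, byrow = TRUE,
              dimnames = list(aa, aa))
  stopifnot(isSymmetric(m), m["C", "C"] == 9L, m["W", "W"] == 11L)
  m
}

#' BLOSUM62 substitution matrices
#'
#' `blosum62()` returns the canonical NCBI BLOSUM62 half-bit table.
#' `modified_blosum62()` returns the same table with the single Cys-Cys entry
#' raised (default 99), which forces pairwise aligners to pin the conserved
#' cysteine scaffold of LU domains onto itself before placing any gap.
#'
#' @param cys_score Replacement for the `(C, C)` entry (default 99).
#' @return A symmetric 20x20 integer matrix with amino-acid dimnames and a
#'   `"name"` attribute.
#' @examples
#' modified_blosum62()["C", "C"]   # 99
#' blosum62()["C", "C"]            # 9
#' @export
blosum62 <- function() {
  m <- .BLOSUM62
  attr(m, "name") <- "BLOSUM62"
  m
}

#' @rdname blosum62
#' @export
modified_blosum62 <- function(cys_score = 99) {
  m <- .BLOSUM62
  m["C", "C"] <- as.integer(cys_score)
  attr(m, "name") <- sprintf("BLOSUM62+CC%d", as.integer(cys_score))
  m
}

.seq_chars <- function(x) {
  if (inherits(x, "seq_record")) x <- x$sequence
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

.seq_id <- function(x, default) {
  if (inherits(x, "seq_record")) x$id else default
}

## Global alignment (Needleman-Wunsch, linear gaps) ---------------------------

#' Global pairwise alignment (Needleman-Wunsch, linear gap penalty)
#'
#' Optimal global alignment under a linear per-symbol gap penalty with
#' terminal gaps penalized. Ties among co-optimal traceback moves are broken
#' deterministically: substitution first, then gap in `b`, then gap in `a`;
#' the number of ties encountered on the optimal path is recorded in the
#' result so that tie-sensitive downstream statistics can be flagged.
#'
#' @param a,b `protein_record`s or plain sequence strings.
#' @param matrix Substitution matrix (default [modified_blosum62()]).
#' @param gap Penalty per gap symbol (default -10).
#' @return Object of class `pairwise_alignment`: ids, equal-length gapped
#'   strings `aligned_a`/`aligned_b`, `score`, `gap_penalty`, `n_ties`.
#' @export
global_align <- function(a, b, matrix = modified_blosum62(), gap = -10) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  n <- length(ca); m <- length(cb)
  if (n == 0L || m == 0L) stop("cannot align an empty sequence")
  S <- matrix[ca, cb, drop = FALSE]
  F <- base::matrix(0, n + 1L, m + 1L)
  F[1, ] <- gap * (0:m)
  F[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    srow <- S[i, ]
    frow <- F[i, ]      # row i (previous)
    cur <- numeric(m + 1L)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(frow[j] + srow[j],     # diagonal
                         frow[j + 1L] + gap,    # up: gap in b
                         cur[j] + gap)          # left: gap in a
    }
    F[i + 1L, ] <- cur
  }
  # deterministic traceback: diagonal > up (gap in b) > left (gap in a)
  aa <- character(0); ab <- character(0)
  i <- n; j <- m; ties <- 0L
  while (i > 0L || j > 0L) {
    here <- F[i + 1L, j + 1L]
    can_d <- i > 0L && j > 0L && here == F[i, j] + S[i, j]
    can_u <- i > 0L && here == F[i, j + 1L] + gap
    can_l <- j > 0L && here == F[i + 1L, j] + gap
    if (sum(can_d, can_u, can_l) > 1L) ties <- ties + 1L
    if (can_d) {
      aa <- c(ca[i], aa); ab <- c(cb[j], ab); i <- i - 1L; j <- j - 1L
    } else if (can_u) {
      aa <- c(ca[i], aa); ab <- c("-", ab); i <- i - 1L
    } else {
      aa <- c("-", aa); ab <- c(cb[j], ab); j <- j - 1L
    }
  }
  structure(list(seq_a_id = .seq_id(a, "a"), seq_b_id = .seq_id(b, "b"),
                 aligned_a = paste(aa, collapse = ""),
                 aligned_b = paste(ab, collapse = ""),
                 score = F[n + 1L, m + 1L], gap_penalty = gap,
                 matrix_name = attr(matrix, "name"), n_ties = ties),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment ", x$seq_a_id, " / ", x$seq_b_id,
      " (score ", x$score, ")\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

## Local alignment (Smith-Waterman, affine gaps) ------------------------------

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under affine gap scoring in which a gap run of
#' length k scores `gap_open + k * gap_extend` (BLAST-like; defaults -11/-1).
#' Among equal-scoring cells the end cell with the smallest `a` position,
#' then smallest `b` position, is chosen; traceback ties follow the same
#' substitution > gap-in-b > gap-in-a order as [global_align()]. When no
#' positive-scoring alignment exists the result is empty with score 0.
#'
#' @inheritParams global_align
#' @param gap_open,gap_extend Affine gap parameters (defaults -11, -1).
#' @return A `pairwise_alignment` with additional 0-based half-open
#'   coordinates `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
local_align <- function(a, b, matrix = blosum62(),
                        gap_open = -11, gap_extend = -1) {
  ca <- .seq_chars(a); cb <- .seq_chars(b)
  n <- length(ca); m <- length(cb)
  if (n == 0L || m == 0L) stop("cannot align an empty sequence")
  S <- matrix[ca, cb, drop = FALSE]
  NEG <- -1e9
  H <- base::matrix(0, n + 1L, m + 1L)
  E <- base::matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  G <- base::matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] + gap_open + gap_extend,
                               E[i + 1L, j] + gap_extend)
      G[i + 1L, j + 1L] <- max(H[i, j + 1L] + gap_open + gap_extend,
                               G[i, j + 1L] + gap_extend)
      H[i + 1L, j + 1L] <- max(0, H[i, j] + S[i, j],
                               E[i + 1L, j + 1L], G[i + 1L, j + 1L])
    }
  }
  best <- max(H)
  if (best <= 0) {
    res <- structure(list(seq_a_id = .seq_id(a, "a"), seq_b_id = .seq_id(b, "b"),
                          aligned_a = "", aligned_b = "", score = 0,
                          gap_open = gap_open, gap_extend = gap_extend,
                          matrix_name = attr(matrix, "name"),
                          a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L),
                     class = "pairwise_alignment")
    return(res)
  }
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- unname(hits[1, 1]) - 1L; j <- unname(hits[1, 2]) - 1L
  a_end <- i; b_end <- j
  aa <- character(0); ab <- character(0)
  state <- "H"
  while (TRUE) {
    if (state == "H") {
      here <- H[i + 1L, j + 1L]
      if (here == 0) break
      if (i > 0L && j > 0L && here == H[i, j] + S[i, j]) {
        aa <- c(ca[i], aa); ab <- c(cb[j], ab); i <- i - 1L; j <- j - 1L
      } else if (here == G[i + 1L, j + 1L]) {
        state <- "G"
      } else {
        state <- "E"
      }
    } else if (state == "G") {            # gap in b, consumes a
      aa <- c(ca[i], aa); ab <- c("-", ab)
      from_open <- G[i + 1L, j + 1L] == H[i, j + 1L] + gap_open + gap_extend
      i <- i - 1L
      if (from_open) state <- "H"
    } else {                              # gap in a, consumes b
      aa <- c("-", aa); ab <- c(cb[j], ab)
      from_open <- E[i + 1L, j + 1L] == H[i + 1L, j] + gap_open + gap_extend
      j <- j - 1L
      if (from_open) state <- "H"
    }
  }
  structure(list(seq_a_id = .seq_id(a, "a"), seq_b_id = .seq_id(b, "b"),
                 aligned_a = paste(aa, collapse = ""),
                 aligned_b = paste(ab, collapse = ""),
                 score = best, gap_open = gap_open, gap_extend = gap_extend,
                 matrix_name = attr(matrix, "name"),
                 a_start = i, a_end = a_end, b_start = j, b_end = b_end),
            class = "pairwise_alignment")
}

## Grouped-residue similarity -------------------------------------------------

#' Grouped-residue percent similarity of an alignment
#'
#' The fraction of alignment columns whose two symbols fall in the same
#' residue group (see [residue_groups()]), as a percentage of *all* columns.
#' The gap symbol is its own group, so a gap-vs-residue column never counts
#' as a coincidence; gap-vs-gap columns cannot occur in a valid pairwise
#' alignment and are rejected.
#'
#' @param alignment A `pairwise_alignment`, or a gapped string (then `b`
#'   must give the second gapped string).
#' @param b Second gapped row when `alignment` is a string.
#' @return Percent similarity in `[0, 100]`, unrounded.
#' @examples
#' group_similarity("KRC", "RKC")    # 100: K/R share a group, C with C
#' @export
group_similarity <- function(alignment, b = NULL) {
  if (inherits(alignment, "pairwise_alignment")) {
    ra <- alignment$aligned_a; rb <- alignment$aligned_b
  } else {
    ra <- alignment; rb <- b
  }
  if (nchar(ra) != nchar(rb)) stop("aligned rows differ in length")
  if (nchar(ra) == 0L) stop("zero-length alignment")
  ga <- classify_residue(strsplit(ra, "", fixed = TRUE)[[1]])
  gb <- classify_residue(strsplit(rb, "", fixed = TRUE)[[1]])
  if (any(ga == "gap" & gb == "gap"))
    stop("alignment has a gap-vs-gap column")
  100 * sum(ga == gb) / length(ga)
}

#' All-vs-all grouped-residue similarity matrix
#'
#' Aligns every row sequence against every column sequence with
#' [global_align()] and tabulates [group_similarity()] per pair.
#'
#' @param rows,cols Lists of `protein_record`s (unique ids).
#' @param matrix Substitution matrix (default [modified_blosum62()]).
#' @param gap Linear gap penalty (default -10).
#' @return A numeric matrix (class `similarity_matrix`) with row/column ids
#'   as dimnames; values in `[0, 100]`.
#' @export
all_vs_all_similarity <- function(rows, cols, matrix = modified_blosum62(),
                                  gap = -10) {
  if (inherits(rows, "seq_record")) rows <- list(rows)
  if (inherits(cols, "seq_record")) cols <- list(cols)
  if (!length(rows) || !length(cols)) stop("empty sequence set")
  rid <- vapply(rows, `[[`, "", "id")
  cid <- vapply(cols, `[[`, "", "id")
  if (anyDuplicated(rid) || anyDuplicated(cid))
    stop("duplicate ids in input sets")
  m <- base::matrix(NA_real_, length(rows), length(cols),
                    dimnames = list(rid, cid))
  for (i in seq_along(rows))
    for (j in seq_along(cols))
      m[i, j] <- group_similarity(global_align(rows[[i]], cols[[j]],
                                               matrix = matrix, gap = gap))
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Select the display submatrix of a similarity matrix
#'
#' Keeps rows whose maximum (over the full matrix) exceeds `threshold` and
#' columns whose maximum exceeds `threshold` (strictly greater), then appends
#' any `forced_rows` not already kept, preserving original order. If no
#' column passes, all columns are retained (with a message) so forced rows
#' remain displayable.
#'
#' @param m A `similarity_matrix` (or plain matrix with dimnames).
#' @param threshold Strict cutoff in percent (default 53).
#' @param forced_rows Row ids always included (e.g. a reference protein).
#' @return The selected submatrix, dimnames preserved.
#' @export
select_display_submatrix <- function(m, threshold = 53,
                                     forced_rows = character()) {
  unknown <- setdiff(forced_rows, rownames(m))
  if (length(unknown))
    stop("unknown forced row id(s): ", paste(unknown, collapse = ", "))
  keep_r <- apply(m, 1, max) > threshold
  keep_c <- apply(m, 2, max) > threshold
  rows <- rownames(m)[keep_r | rownames(m) %in% forced_rows]
  if (!any(keep_c)) {
    message("no column exceeds ", threshold, "%; retaining all columns")
    cols <- colnames(m)
  } else cols <- colnames(m)[keep_c]
  out <- m[rows, cols, drop = FALSE]
  class(out) <- class(m)
  out
}

#' Write a similarity matrix as TSV and long-format CSV
#'
#' @param m A `similarity_matrix`.
#' @param path Output TSV path (rows = row ids, values to 1 decimal).
#' @param long_csv Optional path for a long-format CSV
#'   (`row_id, col_id, similarity`).
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(m, path, long_csv = NULL) {
  df <- data.frame(id = rownames(m),
                   format(round(unclass(m), 1), nsmall = 1, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_csv)) {
    long <- data.frame(row_id = rep(rownames(m), times = ncol(m)),
                       col_id = rep(colnames(m), each = nrow(m)),
                       similarity = as.vector(unclass(m)))
    utils::write.csv(long, long_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
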