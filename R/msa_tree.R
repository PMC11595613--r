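#' Multiple alignment container
#'
#' Equal-length gapped rows over the protein alphabet plus `-`; degapping
#' row i recovers input sequence i; no all-gap column is allowed.
#'
#' @param ids Ordered sequence ids.
#' @param rows Equal-length gapped strings.
#' @return Object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(ids, rows) {
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  cm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (any(colMeans(cm == "-") == 1))
    stop("alignment contains an all-gap column")
  structure(list(ids = as.character(ids), rows = toupper(rows)),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple alignment:", length(x$ids), "sequences x",
      nchar(x$rows[1]), "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Aligned FASTA path (protein alphabet plus `-`).
#' @return A `multiple_alignment`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  multiple_alignment(sub("\\s.*$", "", names(set)), as.character(set))
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa A `multiple_alignment`.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(msa$ids)) {
    writeLines(paste0(">", msa$ids[k]), con)
    n <- nchar(msa$rows[k])
    starts <- seq(1L, n, by = width)
    writeLines(substring(msa$rows[k], starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

## Progressive MSA ------------------------------------------------------------

.kmer_profile <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) k <- 1L
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  table(kmers)
}

.kmer_cosine_dist <- function(seqs, k = 3L) {
  profs <- lapply(seqs, .kmer_profile, k = k)
  n <- length(seqs)
  d <- base::matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- profs[[i]]; b <- profs[[j]]
      keys <- union(names(a), names(b))
      va <- as.numeric(a[keys]); va[is.na(va)] <- 0
      vb <- as.numeric(b[keys]); vb[is.na(vb)] <- 0
      cs <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
      d[i, j] <- d[j, i] <- 1 - cs
    }
  }
  d
}

# mean-of-pairs column score; gap-vs-residue scores the gap penalty,
# gap-vs-gap scores 0
.profile_col_score <- function(colA, colB, matrix, gap) {
  tot <- 0
  for (x in colA) for (y in colB) {
    tot <- tot + if (x == "-" && y == "-") 0
                 else if (x == "-" || y == "-") gap
                 else matrix[x, y]
  }
  tot / (length(colA) * length(colB))
}

.profile_align <- function(A, B, matrix, gap) {
  n <- ncol(A); m <- ncol(B)
  S <- base::matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i, j] <- .profile_col_score(A[, i], B[, j], matrix, gap)
  F <- base::matrix(0, n + 1L, m + 1L)
  F[1, ] <- gap * (0:m)
  F[, 1] <- gap * (0:n)
  for (i in seq_len(n)) for (j in seq_len(m))
    F[i + 1L, j + 1L] <- max(F[i, j] + S[i, j], F[i, j + 1L] + gap,
                             F[i + 1L, j] + gap)
  # traceback (diag > up > left), building merged column list
  i <- n; j <- m
  cols <- list()
  gapA <- rep("-", nrow(A)); gapB <- rep("-", nrow(B))
  while (i > 0L || j > 0L) {
    here <- F[i + 1L, j + 1L]
    if (i > 0L && j > 0L && here == F[i, j] + S[i, j]) {
      cols[[length(cols) + 1L]] <- c(A[, i], B[, j]); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == F[i, j + 1L] + gap) {
      cols[[length(cols) + 1L]] <- c(A[, i], gapB); i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(gapA, B[, j]); j <- j - 1L
    }
  }
  do.call(cbind, rev(cols))
}

#' Progressive multiple sequence alignment
#'
#' A desk-scale progressive aligner: the guide order comes from UPGMA
#' (average-linkage `hclust`) on 3-mer count cosine distances; profiles are
#' merged by mean-of-pairs Needleman-Wunsch under a linear gap penalty, so
#' gaps introduced at an earlier merge are never removed ("once a gap,
#' always a gap"). Deterministic for fixed inputs.
#'
#' @param seqs List of `protein_record`s (at least 2).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap Linear gap penalty (default -10).
#' @return A `multiple_alignment` with rows in input order.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(), gap = -10) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ids <- vapply(seqs, `[[`, "", "id")
  chars <- lapply(seqs, function(s) strsplit(s$sequence, "", fixed = TRUE)[[1]])
  if (length(seqs) == 2L) {
    al <- global_align(seqs[[1]], seqs[[2]], matrix = matrix, gap = gap)
    return(multiple_alignment(ids, c(al$aligned_a, al$aligned_b)))
  }
  d <- .kmer_cosine_dist(vapply(seqs, `[[`, "", "sequence"))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # profiles: character matrices, rows = member sequences
  profs <- lapply(chars, function(x) base::matrix(x, nrow = 1))
  members <- as.list(seq_along(seqs))
  merged <- vector("list", nrow(hc$merge))
  mmem <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) list(p = profs[[-v]], m = members[[-v]])
                        else list(p = merged[[v]], m = mmem[[v]])
    A <- pick(hc$merge[k, 1]); B <- pick(hc$merge[k, 2])
    merged[[k]] <- .profile_align(A$p, B$p, matrix, gap)
    mmem[[k]] <- c(A$m, B$m)
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(unlist(mmem[[nrow(hc$merge)]]))
  rows <- apply(final[ord, , drop = FALSE], 1, paste, collapse = "")
  multiple_alignment(ids, rows)
}

## Distances from an MSA ------------------------------------------------------

#' Pairwise distances from a multiple alignment
#'
#' `p_distance`: fraction of mismatched columns among columns where neither
#' row has a gap (error if a pair shares no such column).
#' `group_dissimilarity`: `1 - group_similarity/100` over the pair's columns
#' after dropping columns gapped in both rows.
#'
#' @param msa A `multiple_alignment`.
#' @param mode `"p_distance"` or `"group_dissimilarity"`.
#' @return Symmetric numeric matrix with zero diagonal and id dimnames.
#' @export
msa_distance <- function(msa, mode = c("p_distance", "group_dissimilarity")) {
  mode <- match.arg(mode)
  cm <- .msa_char_matrix(msa)
  n <- nrow(cm)
  d <- base::matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- cm[i, ]; b <- cm[j, ]
      if (mode == "p_distance") {
        ok <- a != "-" & b != "-"
        if (!any(ok))
          stop("no comparable columns for pair '", msa$ids[i], "' / '",
               msa$ids[j], "'")
        d[i, j] <- d[j, i] <- mean(a[ok] != b[ok])
      } else {
        keep <- !(a == "-" & b == "-")
        d[i, j] <- d[j, i] <-
          1 - group_similarity(paste(a[keep], collapse = ""),
                               paste(b[keep], collapse = "")) / 100
      }
    }
  }
  d
}

## Neighbor joining -----------------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic pair selection
#' (lexicographic tie-break on the joined pair's ids). A negative branch
#' length is clamped to zero and its deficit transferred to the sibling
#' branch, preserving the pair's summed length. Exact on additive
#' distances. The result is unrooted, written with a trifurcating root.
#'
#' @param d Symmetric distance matrix with id dimnames (at least 3 taxa).
#' @return An [ape] `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  # subtree newick fragments (with full-precision branch lengths)
  node <- stats::setNames(labels, labels)
  fmt <- function(x) sprintf("%.15g", max(x, 0) + 0)   # drop -0
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(rownames(d)[cand[, 1]], rownames(d)[cand[, 2]])
    sel <- cand[order(key)[1], ]
    i <- sel[1]; j <- sel[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- paste0("(", node[rownames(d)[i]], ":", fmt(li), ",",
                      node[rownames(d)[j]], ":", fmt(lj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    nd <- d[keep, keep, drop = FALSE]
    nd <- rbind(cbind(nd, du), c(du, 0))
    id <- paste0("u", m)
    rownames(nd)[m - 1L] <- colnames(nd)[m - 1L] <- id
    node[id] <- new_lab
    d <- nd
  }
  # trifurcating root: closed-form three-taxon lengths
  lab3 <- rownames(d)
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", node[lab3[1]], ":", fmt(la), ",",
                node[lab3[2]], ":", fmt(lb), ",",
                node[lab3[3]], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

## Newick I/O -----------------------------------------------------------------

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimals; whitespace in labels is
#' replaced by underscores. Round-trips through [read_newick()].
#'
#' @param tree An ape `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$tip.label <- gsub("\\s+", "_", tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- gsub("\\s+", "_", tree$node.label)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(tree$tip.label[node])
    inner <- vapply(e, function(k) {
      paste0(rec(tree$edge[k, 2]), ":",
             sprintf("%.6f", tree$edge.length[k]))
    }, "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @param path Newick file path.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
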