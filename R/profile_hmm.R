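# Profile hidden Markov model for LU-domain discovery.
#
# Architecture (Krogh-style, local in sequence, global in model):
#   rows j = 0..n_match; row j > 0 has states M_j (emitting), D_j (silent),
#   and every row has I_j (emitting). Row 0's "M" slot is the begin state B.
#   Transitions go from row j to {M_{j+1} (or E at j = n), I_j, D_{j+1}}.
#   The model is flanked by free background-emitting states, so flanking
#   residues contribute exactly 0 to the log-odds score and the model may
#   start/end at any sequence position.
# All scoring is in log2 space (bits) against the background distribution.

.STATE_FROM <- c("M", "I", "D")

#' Build a profile HMM from a multiple alignment
#'
#' Columns whose gap fraction is below `match_gap_fraction` become match
#' states; other columns are treated as inserts (insert columns before the
#' first match column are ignored as flank). Emissions and transitions are
#' estimated from observed counts with an additive pseudocount, so all
#' probabilities are strictly positive.
#'
#' @param msa A `multiple_alignment`, list of equal-length gapped strings,
#'   or character matrix of single symbols.
#' @param match_gap_fraction Columns with gap fraction strictly below this
#'   become match states (default 0.5).
#' @param pseudocount Additive (Laplace) pseudocount (default 1).
#' @param background `"uniform"` (1/20 per letter, default) or
#'   `"blosum62"` (BLOSUM62 marginal amino-acid frequencies).
#' @return Object of class `profile_hmm` with elements `n_match`,
#'   `match_emissions` (n x 20), `insert_emissions` ((n+1) x 20, rows 0..n),
#'   `transitions` ((n+1) x 3 x 3 array, from {M,I,D} to {M,I,D}; the "M"
#'   target at row n is the end state), `background`.
#' @export
build_profile <- function(msa, match_gap_fraction = 0.5, pseudocount = 1,
                          background = c("uniform", "blosum62")) {
  background <- match.arg(background)
  cm <- .msa_char_matrix(msa)
  if (nrow(cm) < 2L) stop("need at least 2 aligned sequences")
  gapfrac <- colMeans(cm == "-")
  is_match <- gapfrac < match_gap_fraction
  n <- sum(is_match)
  if (n == 0L) stop("alignment yields zero match columns")
  aa <- .AA20
  me <- base::matrix(pseudocount, n, 20, dimnames = list(NULL, aa))
  ie <- base::matrix(pseudocount, n + 1L, 20, dimnames = list(NULL, aa))
  tr <- array(0, dim = c(n + 1L, 3L, 3L),
              dimnames = list(NULL, .STATE_FROM, .STATE_FROM))

  # map each column to its model row: match columns are rows 1..n; insert
  # columns belong to the preceding match row (0 before the first)
  col_row <- cumsum(is_match)
  match_idx <- integer(ncol(cm)); match_idx[is_match] <- seq_len(n)

  for (s in seq_len(nrow(cm))) {
    prev <- c(row = 0L, type = 1L)  # begin state = "M" slot of row 0
    for (j in seq_len(ncol(cm))) {
      sym <- cm[s, j]
      if (is_match[j]) {
        row <- match_idx[j]
        type <- if (sym == "-") 3L else 1L    # D or M
        tr[prev["row"] + 1L, prev["type"], type] <-
          tr[prev["row"] + 1L, prev["type"], type] + 1
        if (type == 1L) me[row, sym] <- me[row, sym] + 1
        prev <- c(row = row, type = type)
      } else if (sym != "-") {                 # insert emission
        row <- col_row[j]
        if (row == 0L && prev["type"] == 1L && prev["row"] == 0L) {
          # leading insert column: treated as flank, not counted
          next
        }
        tr[prev["row"] + 1L, prev["type"], 2L] <-
          tr[prev["row"] + 1L, prev["type"], 2L] + 1
        ie[row + 1L, sym] <- ie[row + 1L, sym] + 1
        prev <- c(row = row, type = 2L)
      }
    }
    # exit to E (the "M" target of row n)
    tr[prev["row"] + 1L, prev["type"], 1L] <-
      tr[prev["row"] + 1L, prev["type"], 1L] + 1
  }

  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  # pseudocount + normalize transitions; row n has no D target
  for (r in seq_len(n + 1L)) {
    targets <- if (r == n + 1L) c(1L, 2L) else 1:3
    for (f in 1:3) {
      tr[r, f, targets] <- tr[r, f, targets] + pseudocount
      tr[r, f, ] <- tr[r, f, ] / sum(tr[r, f, ])
    }
  }
  bg <- if (background == "uniform") stats::setNames(rep(1 / 20, 20), aa)
        else .blosum62_marginals()[aa]
  structure(list(n_match = n, match_emissions = me, insert_emissions = ie,
                 transitions = tr, background = bg,
                 match_gap_fraction = match_gap_fraction,
                 pseudocount = pseudocount),
            class = "profile_hmm")
}

.blosum62_marginals <- function() {
  # amino-acid frequencies implied by the BLOSUM62 target distribution;
  # approximated by the Robinson-Robinson frequencies used by BLAST
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
         E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.090, K = 0.057,
         M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
         Y = 0.032, V = 0.064)
  f / sum(f)
}

.msa_char_matrix <- function(msa) {
  if (inherits(msa, "multiple_alignment"))
    return(do.call(rbind, strsplit(msa$rows, "", fixed = TRUE)))
  if (is.matrix(msa)) return(msa)
  if (is.list(msa) && all(vapply(msa, inherits, TRUE, "seq_record")))
    msa <- vapply(msa, `[[`, "", "sequence")
  rows <- strsplit(toupper(unlist(msa)), "", fixed = TRUE)
  if (length(unique(lengths(rows))) != 1L)
    stop("aligned sequences differ in length")
  do.call(rbind, rows)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM:", x$n_match, "match states,",
      "pseudocount", x$pseudocount, "\n")
  invisible(x)
}

# precompute log2 parameter tables shared by viterbi/forward
.hmm_logs <- function(hmm) {
  list(lM = log2(sweep(hmm$match_emissions, 2, hmm$background, "/")),
       lI = log2(sweep(hmm$insert_emissions, 2, hmm$background, "/")),
       lt = log2(hmm$transitions))
}

.lse2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log2(sum(2^(x - m)))
}

#' Viterbi alignment of a sequence to a profile HMM
#'
#' Computes the optimal state path and its log-odds score in bits,
#' `log2(P(seq, path | model) / P(seq | background))`, under the
#' local-in-sequence architecture (free background-emitting flanks).
#'
#' @param hmm A `profile_hmm`.
#' @param seq A `protein_record` or sequence string.
#' @return List with `bits`, `path` (character vector of state tokens such
#'   as `"M1"`, `"I2"`, `"D3"`), and the 0-based half-open envelope
#'   `start`/`end` of sequence positions emitted by core states.
#' @export
hmm_viterbi <- function(hmm, seq) {
  x <- .seq_chars(seq)
  L <- length(x)
  if (L == 0L) stop("empty sequence")
  lg <- .hmm_logs(hmm)
  n <- hmm$n_match
  NEG <- -Inf
  VM <- base::matrix(NEG, L + 1L, n + 1L)  # col j+1 = row j (j=0 is B, value 0)
  VI <- base::matrix(NEG, L + 1L, n + 1L)  # col j+1 = I_j, j = 0..n
  VD <- base::matrix(NEG, L + 1L, n + 1L)
  PM <- base::matrix(0L, L + 1L, n + 1L)   # backpointers: 1=M,2=I,3=D,4=B
  PI <- base::matrix(0L, L + 1L, n + 1L)
  PD <- base::matrix(0L, L + 1L, n + 1L)
  VM[, 1] <- 0                             # begin state, free flank before

  # delete chains reachable with no emission (before the first position)
  for (j in seq_len(n)) {
    cand <- c(VM[1, j] + lg$lt[j, 1, 3], VI[1, j] + lg$lt[j, 2, 3],
              VD[1, j] + lg$lt[j, 3, 3])
    w <- which.max(cand)
    VD[1, j + 1L] <- cand[w]
    PD[1, j + 1L] <- w
  }

  for (i in seq_len(L) + 1L) {             # matrix row index = position + 1
    xi <- x[i - 1L]
    # I_0 from B (free flank) or I_0
    cand <- c(VM[i - 1L, 1] + lg$lt[1, 1, 2], VI[i - 1L, 1] + lg$lt[1, 2, 2])
    w <- which.max(cand)
    VI[i, 1] <- lg$lI[1, xi] + cand[w]
    PI[i, 1] <- c(1L, 2L)[w]
    for (j in seq_len(n)) {
      cand <- c(VM[i - 1L, j] + lg$lt[j, 1, 1],
                VI[i - 1L, j] + lg$lt[j, 2, 1],
                VD[i - 1L, j] + lg$lt[j, 3, 1])
      w <- which.max(cand)
      VM[i, j + 1L] <- lg$lM[j, xi] + cand[w]
      PM[i, j + 1L] <- w
      cand <- c(VM[i - 1L, j + 1L] + lg$lt[j + 1L, 1, 2],
                VI[i - 1L, j + 1L] + lg$lt[j + 1L, 2, 2],
                VD[i - 1L, j + 1L] + lg$lt[j + 1L, 3, 2])
      w <- which.max(cand)
      VI[i, j + 1L] <- lg$lI[j + 1L, xi] + cand[w]
      PI[i, j + 1L] <- w
    }
    for (j in seq_len(n)) {
      cand <- c(VM[i, j] + lg$lt[j, 1, 3],
                VI[i, j] + lg$lt[j, 2, 3],
                VD[i, j] + lg$lt[j, 3, 3])
      w <- which.max(cand)
      VD[i, j + 1L] <- cand[w]
      PD[i, j + 1L] <- w
    }
  }
  # exit: target "M" at row n is E; free flank after
  ex <- cbind(VM[, n + 1L] + lg$lt[n + 1L, 1, 1],
              VI[, n + 1L] + lg$lt[n + 1L, 2, 1],
              VD[, n + 1L] + lg$lt[n + 1L, 3, 1])
  best <- which(ex == max(ex), arr.ind = TRUE)[1, ]
  bits <- ex[best[1], best[2]]

  # traceback
  path <- character(0)
  i <- best[1]; j <- n; type <- best[2]
  emitted <- integer(0)
  while (!(type == 1L && j == 0L)) {
    path <- c(paste0(c("M", "I", "D")[type], j), path)
    if (type == 1L) {
      w <- PM[i, j + 1L]; emitted <- c(i - 1L, emitted)
      i <- i - 1L; j <- j - 1L
    } else if (type == 2L) {
      w <- PI[i, j + 1L]; emitted <- c(i - 1L, emitted)
      i <- i - 1L
    } else {
      w <- PD[i, j + 1L]; j <- j - 1L
    }
    type <- w
  }
  env <- if (length(emitted)) c(min(emitted) - 1L, max(emitted)) else c(0L, 0L)
  list(bits = bits, path = path, start = env[1], end = env[2])
}

#' Forward score of a sequence under a profile HMM
#'
#' `log2` of the summed likelihood ratio over all state paths (same
#' architecture as [hmm_viterbi()]); always at least the Viterbi bit score.
#'
#' @inheritParams hmm_viterbi
#' @return Forward score in bits.
#' @export
hmm_forward <- function(hmm, seq) {
  x <- .seq_chars(seq)
  L <- length(x)
  if (L == 0L) stop("empty sequence")
  lg <- .hmm_logs(hmm)
  n <- hmm$n_match
  VM <- base::matrix(-Inf, L + 1L, n + 1L)
  VI <- base::matrix(-Inf, L + 1L, n + 1L)
  VD <- base::matrix(-Inf, L + 1L, n + 1L)
  VM[, 1] <- 0
  for (i in c(1L, seq_len(L) + 1L)) {
    if (i > 1L) {
      xi <- x[i - 1L]
      VI[i, 1] <- lg$lI[1, xi] +
        .lse2(c(VM[i - 1L, 1] + lg$lt[1, 1, 2], VI[i - 1L, 1] + lg$lt[1, 2, 2]))
      for (j in seq_len(n)) {
        VM[i, j + 1L] <- lg$lM[j, xi] +
          .lse2(c(VM[i - 1L, j] + lg$lt[j, 1, 1],
                  VI[i - 1L, j] + lg$lt[j, 2, 1],
                  VD[i - 1L, j] + lg$lt[j, 3, 1]))
        VI[i, j + 1L] <- lg$lI[j + 1L, xi] +
          .lse2(c(VM[i - 1L, j + 1L] + lg$lt[j + 1L, 1, 2],
                  VI[i - 1L, j + 1L] + lg$lt[j + 1L, 2, 2],
                  VD[i - 1L, j + 1L] + lg$lt[j + 1L, 3, 2]))
      }
    }
    for (j in seq_len(n)) {
      VD[i, j + 1L] <- .lse2(c(VM[i, j] + lg$lt[j, 1, 3],
                               VI[i, j] + lg$lt[j, 2, 3],
                               VD[i, j] + lg$lt[j, 3, 3]))
    }
  }
  ex <- cbind(VM[, n + 1L] + lg$lt[n + 1L, 1, 1],
              VI[, n + 1L] + lg$lt[n + 1L, 2, 1],
              VD[, n + 1L] + lg$lt[n + 1L, 3, 1])
  .lse2(as.vector(ex))
}

#' Scan proteins for domain hits
#'
#' Greedy extraction of non-overlapping domain envelopes: per protein, the
#' best Viterbi hit is taken if it reaches `bit_threshold`, then the flanks
#' left and right of its envelope are re-scanned recursively. Hits are
#' returned sorted by protein id, then envelope start, and are invariant to
#' the input order of the proteins.
#'
#' @param hmm A `profile_hmm`.
#' @param proteins List of `protein_record`s.
#' @param bit_threshold Minimum Viterbi bit score (default 15).
#' @return data.frame with columns `protein_id`, `start`, `end` (0-based
#'   half-open), `bit_score`, `viterbi_path`.
#' @export
scan_proteins <- function(hmm, proteins, bit_threshold = 15) {
  if (inherits(proteins, "seq_record")) proteins <- list(proteins)
  if (!length(proteins)) stop("no proteins to scan")
  min_len <- 5L
  scan1 <- function(seqstr, offset) {
    if (nchar(seqstr) < min_len) return(NULL)
    v <- hmm_viterbi(hmm, seqstr)
    if (v$bits < bit_threshold || v$end <= v$start) return(NULL)
    hit <- data.frame(start = offset + v$start, end = offset + v$end,
                      bit_score = v$bits,
                      viterbi_path = paste(v$path, collapse = ","),
                      stringsAsFactors = FALSE)
    left <- if (v$start >= min_len)
      scan1(substr(seqstr, 1L, v$start), offset) else NULL
    right <- if (nchar(seqstr) - v$end >= min_len)
      scan1(substr(seqstr, v$end + 1L, nchar(seqstr)), offset + v$end)
      else NULL
    rbind(hit, left, right)
  }
  out <- list()
  for (p in proteins) {
    h <- scan1(p$sequence, 0L)
    if (!is.null(h)) {
      h <- cbind(protein_id = p$id, h, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), bit_score = numeric(),
                      viterbi_path = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Serialize / restore a profile HMM as JSON
#'
#' @param hmm A `profile_hmm`.
#' @param path JSON file path.
#' @return `write_profile_json` returns `path` invisibly;
#'   `read_profile_json` returns the restored `profile_hmm`.
#' @export
write_profile_json <- function(hmm, path) {
  obj <- list(format_version = 1L, n_match = hmm$n_match,
              alphabet = colnames(hmm$match_emissions),
              match_emissions = unclass(hmm$match_emissions),
              insert_emissions = unclass(hmm$insert_emissions),
              transitions = as.vector(hmm$transitions),
              background = as.list(hmm$background),
              match_gap_fraction = hmm$match_gap_fraction,
              pseudocount = hmm$pseudocount)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported profile JSON format version")
  n <- obj$n_match
  aa <- obj$alphabet
  tr <- array(obj$transitions, dim = c(n + 1L, 3L, 3L),
              dimnames = list(NULL, .STATE_FROM, .STATE_FROM))
  structure(list(n_match = n,
                 match_emissions = base::matrix(obj$match_emissions, n, 20,
                                                dimnames = list(NULL, aa)),
                 insert_emissions = base::matrix(obj$insert_emissions, n + 1L,
                                                 20, dimnames = list(NULL, aa)),
                 transitions = tr,
                 background = unlist(obj$background),
                 match_gap_fraction = obj$match_gap_fraction,
                 pseudocount = obj$pseudocount),
            class = "profile_hmm")
}
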