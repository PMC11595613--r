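# Independent brute-force oracles. These deliberately enumerate every
# alignment / state path instead of running dynamic programming, so they
# stay independent of the implementations they check. Only usable at tiny
# problem sizes.

rand_protein <- function(n, letters = c("A", "C", "D", "E", "G", "K", "L",
                                        "R", "S", "W")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# all global alignments under a linear gap penalty, maximum score
enum_global_score <- function(a, b, mat, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) + mat[ca[i], cb[j]])
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# all global alignments under affine gaps (run of length k costs
# gap_open + k * gap_extend); alignment built right to left, the opening
# charge falls on the rightmost symbol of each run
enum_affine_global_score <- function(ca, cb, mat, go, ge) {
  rec <- function(i, j, right) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L, "D") + mat[ca[i], cb[j]])
    if (i > 0L)
      best <- max(best, rec(i - 1L, j, "U") + ge +
                    if (right != "U") go else 0)
    if (j > 0L)
      best <- max(best, rec(i, j - 1L, "L") + ge +
                    if (right != "L") go else 0)
    best
  }
  rec(length(ca), length(cb), "D")
}

# best local alignment score: maximum over all subsegment pairs of the
# affine global score, floored at 0
enum_local_score <- function(a, b, mat, go, ge) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca))
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb))
      best <- max(best, enum_affine_global_score(ca[i1:i2], cb[j1:j2],
                                                 mat, go, ge))
  best
}

# explicit enumeration of all state paths through a profile HMM under the
# free-flank architecture; returns every path's log-odds score in bits
enum_hmm_path_scores <- function(hmm, seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  L <- length(x)
  n <- hmm$n_match
  lt <- log2(hmm$transitions)
  lM <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lI <- log2(sweep(hmm$insert_emissions, 2, hmm$background, "/"))
  scores <- numeric(0)
  rec <- function(row, type, i, acc) {
    # exit to E (the "M" target at row n)
    if (row == n)
      scores[[length(scores) + 1L]] <<- acc + lt[row + 1L, type, 1L]
    if (row < n && i < L)  # M_{row+1}
      rec(row + 1L, 1L, i + 1L,
          acc + lt[row + 1L, type, 1L] + lM[row + 1L, x[i + 1L]])
    if (i < L)             # I_row
      rec(row, 2L, i + 1L,
          acc + lt[row + 1L, type, 2L] + lI[row + 1L, x[i + 1L]])
    if (row < n)           # D_{row+1}
      rec(row + 1L, 3L, i, acc + lt[row + 1L, type, 3L])
  }
  for (s in 0:L) rec(0L, 1L, s, 0)   # enter B after s free flank symbols
  scores
}

# tiny helper: sliding-window hydropathy by direct enumeration
enum_hydropathy_segments <- function(seq, window, threshold) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  h <- kd[strsplit(seq, "")[[1]]]
  L <- length(h)
  pass <- vapply(1:(L - window + 1L),
                 function(i) mean(h[i:(i + window - 1L)]) >= threshold,
                 TRUE)
  segs <- list()
  i <- 1L
  while (i <= length(pass)) {
    if (pass[i]) {
      j <- i
      while (j < length(pass) && pass[j + 1L]) j <- j + 1L
      segs[[length(segs) + 1L]] <- c(i - 1L, j - 1L + window)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(segs)) return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(segs, function(s) as.integer(s[1]), 0L),
             end = vapply(segs, function(s) as.integer(s[2]), 0L))
}
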