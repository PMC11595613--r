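test_that("embedded BLOSUM62 equals the canonical table and is symmetric", {
  m <- blosum62()
  expect_true(isSymmetric(unclass(m)))
  expect_equal(m["C", "C"], 9)
  expect_equal(m["W", "W"], 11)
  # checksum against an independent copy of the table
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ref <- BLOSUM62[rownames(m), colnames(m)]
  expect_equal(matrix(as.numeric(m), 20), matrix(as.numeric(ref), 20))
})

test_that("the modified matrix changes only the Cys-Cys entry", {
  m <- modified_blosum62()
  s <- blosum62()
  expect_equal(m["C", "C"], 99)
  m["C", "C"] <- s["C", "C"]
  attr(m, "name") <- attr(s, "name")
  expect_identical(m, s)
})

test_that("global alignment reproduces hand-scored examples", {
  al <- global_align("MKC", "MKC")
  expect_equal(al$score, 5 + 5 + 99)     # M,K diagonal + modified C-C
  expect_equal(al$aligned_a, "MKC")
  al <- global_align("AC", "A")
  expect_equal(al$score, 4 - 10)         # one terminal gap, penalized
  expect_error(global_align("A", ""), "empty")
  # degapping recovers inputs and no double-gap columns
  al <- global_align("MKWWLC", "MLC")
  expect_equal(gsub("-", "", al$aligned_a), "MKWWLC")
  expect_equal(gsub("-", "", al$aligned_b), "MLC")
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  expect_false(any(ca == "-" & cb == "-"))
})

test_that("global and local scores equal brute-force enumeration", {
  set.seed(101)
  mat <- modified_blosum62()
  std <- blosum62()
  for (trial in 1:120) {
    a <- rand_protein(sample(1:6, 1))
    b <- rand_protein(sample(1:6, 1))
    expect_equal(global_align(a, b, mat, gap = -10)$score,
                 enum_global_score(a, b, mat, -10))
  }
  for (trial in 1:80) {
    a <- rand_protein(sample(1:6, 1))
    b <- rand_protein(sample(1:6, 1))
    al <- local_align(a, b, std, gap_open = -11, gap_extend = -1)
    expect_equal(al$score, enum_local_score(a, b, std, -11, -1))
  }
})

test_that("global alignment score matches an independent aligner", {
  set.seed(102)
  for (trial in 1:5) {
    a <- rand_protein(sample(20:40, 1))
    b <- rand_protein(sample(20:40, 1))
    mine <- global_align(a, b, blosum62(), gap = -10)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = blosum62(), gapOpening = 0,
      gapExtension = 10, type = "global", scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("local alignment handles degenerate cases", {
  # identical sequences: full-length hit scoring the diagonal sum
  al <- local_align("MKWC", "MKWC")
  expect_equal(al$score, 5 + 5 + 11 + 9)
  expect_equal(c(al$a_start, al$a_end, al$b_start, al$b_end), c(0, 4, 0, 4))
  # no positive-scoring pair: empty alignment, score 0
  al <- local_align("WWW", "DDD")
  expect_equal(al$score, 0)
  expect_equal(al$aligned_a, "")
})

test_that("group similarity scores columns by residue class", {
  expect_equal(group_similarity("KRC", "RKC"), 100)
  expect_equal(group_similarity("AC-D", "ACKD"), 75)
  expect_error(group_similarity("", ""), "zero-length")
  expect_error(group_similarity("A-", "A-"), "gap-vs-gap")
  # symmetry under row swap
  set.seed(103)
  for (trial in 1:20) {
    al <- global_align(rand_protein(15), rand_protein(12))
    expect_equal(group_similarity(al$aligned_a, al$aligned_b),
                 group_similarity(al$aligned_b, al$aligned_a))
  }
})

test_that("self-similarity is exactly 100 and within-group swaps are free", {
  set.seed(104)
  for (trial in 1:10) {
    s <- rand_protein(30)
    expect_identical(group_similarity(s, s), 100)
  }
  # replacing a residue by a group-mate leaves a fixed alignment unchanged
  a <- "MKCDEAST"
  b <- "LRCEDVTS"   # every column same-group as a
  expect_equal(group_similarity(a, b), 100)
  groups <- residue_groups()
  set.seed(105)
  for (trial in 1:20) {
    al <- global_align(rand_protein(20), rand_protein(20))
    base <- group_similarity(al$aligned_a, al$aligned_b)
    cb <- strsplit(al$aligned_b, "")[[1]]
    p <- sample(which(cb != "-"), 1)
    g <- classify_residue(cb[p])
    alt <- setdiff(groups[[g]], cb[p])
    if (!length(alt)) next
    cb[p] <- sample(alt, 1)
    expect_equal(group_similarity(al$aligned_a, paste(cb, collapse = "")),
                 base)
  }
})

test_that("the Cys-Cys upweight never lowers a fixed alignment's score", {
  score_alignment <- function(ra, rb, mat, gap) {
    ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
    sum(ifelse(ca == "-" | cb == "-", gap,
               mat[cbind(ifelse(ca == "-", "A", ca),
                         ifelse(cb == "-", "A", cb))]))
  }
  set.seed(106)
  for (trial in 1:20) {
    al <- global_align(rand_protein(20), rand_protein(20))
    s_std <- score_alignment(al$aligned_a, al$aligned_b, blosum62(), -10)
    s_mod <- score_alignment(al$aligned_a, al$aligned_b,
                             modified_blosum62(), -10)
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    n_cc <- sum(ca == "C" & cb == "C")
    expect_equal(s_mod - s_std, n_cc * 90)
  }
})

test_that("all-vs-all similarity is cell-wise reproducible and bounded", {
  set.seed(107)
  rows <- lapply(1:4, function(i) protein_record(paste0("r", i),
                                                 rand_protein(25)))
  cols <- lapply(1:3, function(i) protein_record(paste0("c", i),
                                                 rand_protein(30)))
  m <- all_vs_all_similarity(rows, cols)
  expect_equal(dim(m), c(4, 3))
  expect_true(all(m >= 0 & m <= 100))
  for (i in 1:4) for (j in 1:3)
    expect_equal(m[i, j],
                 group_similarity(global_align(rows[[i]], cols[[j]])))
  # a sequence present in both sets scores 100 against itself
  m2 <- all_vs_all_similarity(rows, rows[2])
  expect_equal(unname(m2["r2", 1]), 100)
})

test_that("display submatrix selection follows the threshold rule", {
  m <- matrix(c(60, 10, 20, 30), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  sub <- select_display_submatrix(m, threshold = 53)
  expect_equal(dim(sub), c(1, 1))
  expect_equal(unname(sub["r1", "c1"]), 60)
  # forced row appended even when it fails the threshold
  sub2 <- select_display_submatrix(m, threshold = 53, forced_rows = "r2")
  expect_equal(rownames(sub2), c("r1", "r2"))
  expect_equal(colnames(sub2), "c1")
  # degenerate: nothing passes, columns fall back to all
  m3 <- matrix(c(40, 30, 20, 10), 2, 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_message(sub3 <- select_display_submatrix(m3, forced_rows = "r1"),
                 "retaining all columns")
  expect_equal(rownames(sub3), "r1")
  expect_equal(colnames(sub3), c("c1", "c2"))
  # threshold is strict
  m4 <- matrix(53, 1, 1, dimnames = list("r", "c"))
  expect_message(sub4 <- select_display_submatrix(m4))
  expect_equal(nrow(sub4), 0)
  expect_error(select_display_submatrix(m, forced_rows = "nope"), "unknown")
})

test_that("similarity TSV output round-trips values to one decimal", {
  set.seed(108)
  rows <- lapply(1:2, function(i) protein_record(paste0("r", i),
                                                 rand_protein(20)))
  m <- all_vs_all_similarity(rows, rows)
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".csv")
  write_similarity_tsv(m, f, long_csv = g)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$id, rownames(m))
  expect_equal(as.numeric(back[1, -1]), unname(round(unclass(m)[1, ], 1)))
  long <- utils::read.csv(g)
  expect_equal(nrow(long), 4)
})
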