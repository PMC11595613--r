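test_that("multiple alignment container enforces its invariants", {
  expect_error(multiple_alignment(c("a", "b"), c("MK-", "MKCC")), "length")
  expect_error(multiple_alignment(c("a", "b"), c("M-C", "M-C")), "all-gap")
  msa <- multiple_alignment(c("a", "b"), c("MKC", "M-C"))
  expect_s3_class(msa, "multiple_alignment")
})

test_that("progressive alignment handles identical and tiny inputs", {
  a <- protein_record("a", "MKCW")
  b <- protein_record("b", "MKCW")
  al <- progressive_msa(list(a, b))
  expect_equal(al$rows, c("MKCW", "MKCW"))
  al2 <- progressive_msa(list(protein_record("a", "MKC"),
                              protein_record("b", "MC")))
  expect_equal(al2$rows, c("MKC", "M-C"))
  expect_error(progressive_msa(list(a)), "at least 2")
})

test_that("progressive alignment degaps to its inputs, deterministically", {
  set.seed(501)
  seqs <- lapply(1:7, function(i)
    protein_record(paste0("s", i), rand_protein(sample(30:50, 1))))
  m1 <- progressive_msa(seqs)
  m2 <- progressive_msa(seqs)
  expect_identical(m1, m2)
  expect_equal(gsub("-", "", m1$rows),
               vapply(seqs, `[[`, "", "sequence"))
  cm <- do.call(rbind, strsplit(m1$rows, ""))
  expect_false(any(colMeans(cm == "-") == 1))
})

test_that("MSA distances match direct column counting", {
  msa <- multiple_alignment(c("a", "b"), c("AAAA", "AAAT"))
  expect_equal(msa_distance(msa, "p_distance")["a", "b"], 0.25)
  msa2 <- multiple_alignment(c("a", "b"), c("MKC", "MKC"))
  expect_equal(max(msa_distance(msa2, "p_distance")), 0)
  expect_equal(max(msa_distance(msa2, "group_dissimilarity")), 0)
  # no comparable columns is an error naming the pair
  msa3 <- multiple_alignment(c("x", "y", "z"), c("A--A", "-GG-", "AGGA"))
  expect_error(msa_distance(msa3, "p_distance"), "'x' / 'y'")
  # random MSAs: symmetric, zero diagonal, equals the direct count
  set.seed(502)
  for (trial in 1:10) {
    rows <- vapply(1:4, function(i) rand_protein(12), "")
    msa <- multiple_alignment(paste0("s", 1:4), rows)
    d <- msa_distance(msa, "p_distance")
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 4))
    a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
    expect_equal(d[1, 2], mean(a != b))
    dg <- msa_distance(msa, "group_dissimilarity")
    expect_equal(dg[1, 2], 1 - group_similarity(rows[1], rows[2]) / 100)
  }
})

test_that("three-taxon neighbor joining has the closed-form solution", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining is exact on additive distances", {
  skip_if_not_installed("phangorn")
  set.seed(503)
  for (trial in 1:100) {
    n <- sample(5:10, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    d <- stats::cophenetic(true_tree)
    ord <- sort(rownames(d))
    rec <- neighbor_joining(d[ord, ord])
    expect_equal(phangorn::RF.dist(ape::unroot(rec), ape::unroot(true_tree)),
                 0)
    dd <- stats::cophenetic(rec)[rownames(d), colnames(d)]
    expect_lt(max(abs(dd - d)), 1e-9)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(504)
  tr <- ape::rtree(8, rooted = FALSE)
  d <- stats::cophenetic(tr)
  mine <- neighbor_joining(d)
  ref <- ape::nj(d)
  expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
})

test_that("ultrametric four-leaf input matches UPGMA topology", {
  # perfectly clock-like distances: ((A,B),(C,D))
  d <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  upgma <- ape::as.phylo(stats::hclust(stats::as.dist(d), "average"))
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(upgma)), 0)
})

test_that("negative NJ branch lengths are clamped, preserving pair sums", {
  # a deliberately non-additive matrix that produces a negative estimate
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 2, 2,
                6, 2, 0, 1,
                6, 2, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick output round-trips and sanitizes labels", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_equal(readLines(f), "(A:1.000000,B:1.000000,C:3.000000);")
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(sum(back$edge.length), sum(tr$edge.length), tolerance = 1e-6)
  tr$tip.label <- c("Asterias rubens", "sp b", "C")
  write_newick(tr, f)
  expect_true(grepl("Asterias_rubens", readLines(f)))
})

test_that("duplicating a sequence never lowers the MSA's self-consistency", {
  set.seed(505)
  seqs <- lapply(1:4, function(i) protein_record(paste0("s", i),
                                                 rand_protein(30)))
  base <- progressive_msa(seqs)
  dup <- progressive_msa(c(seqs, list(protein_record("s1b",
                                                     seqs[[1]]$sequence))))
  # the duplicated sequence aligns gap-identically to its twin
  r1 <- dup$rows[dup$ids == "s1"]
  r2 <- dup$rows[dup$ids == "s1b"]
  expect_equal(r1, r2)
})
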