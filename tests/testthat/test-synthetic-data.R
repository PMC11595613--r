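test_that("configuration is validated", {
  expect_error(sim_config(n_cys = 7), "8 or 10")
  expect_error(sim_config(lu_length_range = c(50, 90)))
  expect_error(sim_config(species_divergences = c(a = 0.95)), "0.9")
})

test_that("generators are byte-deterministic for a fixed seed", {
  cfg <- sim_config(seed = 9, n_lu_proteins = 3, n_decoys = 5)
  s1 <- simulate_lu_proteome(cfg)
  s2 <- simulate_lu_proteome(cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$proteins, f1); write_fasta(s2$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
  anc <- protein_record("a", lu_seed_alignment(sim_config(seed = 100))$rows[1])
  expect_identical(simulate_homolog_transcripts(cfg, anc),
                   simulate_homolog_transcripts(cfg, anc))
  expect_identical(simulate_dose_response(cfg), simulate_dose_response(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # and a different seed changes the draws
  expect_false(identical(simulate_lu_proteome(sim_config(seed = 10,
                                                         n_lu_proteins = 3,
                                                         n_decoys = 5)), s1))
})

test_that("planted LU domains sit on the shared cysteine scaffold", {
  cfg <- sim_config(seed = 13, n_lu_proteins = 8, n_decoys = 4)
  sim <- simulate_lu_proteome(cfg)
  sc <- sim$scaffold
  expect_equal(nrow(sim$truth), 8)
  for (k in seq_len(8)) {
    dom <- substr(sim$proteins[[k]]$sequence, sim$truth$start[k] + 1,
                  sim$truth$end[k])
    ch <- strsplit(dom, "")[[1]]
    expect_length(ch, sc$length)
    expect_equal(which(ch == "C"), sc$cys)      # exactly n_cys, at offsets
  }
  # all records satisfy consumer invariants
  for (p in sim$proteins) expect_s3_class(p, "protein_record")
  # decoys do not reproduce the scaffold anywhere
  for (p in sim$proteins[9:12]) {
    ch <- strsplit(p$sequence, "")[[1]]
    hits <- vapply(0:(length(ch) - sc$length), function(off)
      all(ch[off + sc$cys] == "C"), TRUE)
    expect_false(any(hits))
  }
  # seed alignments share the same scaffold across generator seeds
  al1 <- lu_seed_alignment(sim_config(seed = 100), n = 4)
  al2 <- lu_seed_alignment(sim_config(seed = 200), n = 4)
  expect_equal(nchar(al1$rows[1]), sc$length)
  expect_false(identical(al1$rows, al2$rows))
})

test_that("zero-divergence homolog transcripts decode to the ancestor", {
  cfg <- sim_config(seed = 14, species_divergences = c(same_sim = 0),
                    truncated_species = c(trunc_sim = 0))
  anc <- protein_record("anc", lu_seed_alignment(sim_config(seed = 100))$rows[1])
  sim <- simulate_homolog_transcripts(cfg, anc)
  expect_equal(sim$truth$realized_similarity_pct[1], 100)
  hits <- translated_search(anc, sim$transcripts)
  full <- hits[hits$species == "same_sim", ]
  expect_equal(full$query_coverage, 1.0)
  expect_equal(full$group_similarity_pct, 100)
  # the truncated species encodes the C-terminal half
  tr <- hits[hits$species == "trunc_sim", ]
  expect_lt(tr$query_coverage, 1)
})

test_that("within-group bias keeps group similarity above plain identity", {
  # at divergence d with 70% within-group substitutions, identity falls
  # roughly as 1 - d while group similarity falls as 1 - 0.3 d, so the two
  # metrics separate measurably
  anc <- protein_record("anc", lu_seed_alignment(sim_config(seed = 100))$rows[1])
  diffs <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 30 + s,
                      species_divergences = c(one_sim = 0.3),
                      truncated_species = c())
    sim <- simulate_homolog_transcripts(cfg, anc)
    hits <- translated_search(anc, sim$transcripts)
    al <- global_align(anc, hits$subject_peptide[1])
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    ok <- ca != "-" & cb != "-"
    ident <- 100 * mean(ca[ok] == cb[ok])
    grp <- 100 * mean(classify_residue(ca[ok]) == classify_residue(cb[ok]))
    grp - ident
  }, 0)
  expect_gt(mean(diffs), 5)
})

test_that("dose-response truth round-trips through the Hill fit", {
  cfg <- sim_config(seed = 15)
  sim <- simulate_dose_response(cfg)
  expect_equal(nrow(sim$curve), 11 * 5)
  expect_equal(length(unique(sim$curve$concentration_M)), 11)
  expect_equal(range(sim$curve$concentration_M), c(1e-10, 1e-5))
  fit <- fit_hill(sim$curve)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["EC50"] - cfg$assay$EC50) / cfg$assay$EC50, 0.3)
  # zero noise satisfies the model exactly
  cfg0 <- sim_config(seed = 15)
  cfg0$assay$noise_sd <- 0
  sim0 <- simulate_dose_response(cfg0)
  a <- cfg0$assay
  mu <- a$A1 * sim0$curve$concentration_M^a$nH /
    (a$EC50^a$nH + sim0$curve$concentration_M^a$nH)
  expect_equal(sim0$curve$od, mu)
})

test_that("qPCR tables encode stable housekeeping and ranked truth", {
  cfg <- sim_config(seed = 16)
  sim <- simulate_qpcr(cfg)
  tab <- sim$table
  expect_equal(sort(unique(tab$gene)),
               sort(c(sim$housekeeping, "lystar5_sim")))
  hk <- tab[tab$gene %in% sim$housekeeping, ]
  # housekeeping Ct is tissue-independent up to noise
  per_tissue <- tapply(hk$ct, hk$tissue, mean)
  expect_lt(diff(range(per_tissue)), 4 * cfg$qpcr$ct_noise_sd)
  # recovered ordering matches programmed truth (8, 4, 0.1, 0.01)
  e <- relative_expression(tab, sim$housekeeping)
  s <- tissue_summary(e)
  expect_equal(s$tissue[order(-s$mean_level)],
               names(sort(sim$truth, decreasing = TRUE)))
  # zero noise recovers level 1 exactly
  cfg0 <- sim_config(seed = 16)
  cfg0$qpcr$ct_noise_sd <- 0
  cfg0$qpcr$levels <- c(t1 = 1, t2 = 1)
  e0 <- relative_expression(simulate_qpcr(cfg0)$table,
                            simulate_qpcr(cfg0)$housekeeping)
  expect_equal(e0$level, rep(1, nrow(e0)))
})
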