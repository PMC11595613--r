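# Orchestration: each run_* function wires the modules into one of the
# study's analyses, writes its outputs into `out_dir`, and records a run
# manifest (parameters, input hashes, package version, timestamp). Outputs
# are staged in a temporary directory and promoted only on success.

.write_manifest <- function(out_dir, subcommand, params, inputs,
                            seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(subcommand = subcommand, parameters = params,
              inputs = as.list(inputs), input_md5 = hashes, seed = seed,
              tool = "lusurvey",
              version = as.character(utils::packageVersion("lusurvey")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              coordinates = "0-based, half-open")
  jsonlite::write_json(obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.staged <- function(out_dir, expr_fun) {
  stage <- tempfile("lusurvey_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  expr_fun(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage, full.names = TRUE))
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  invisible(out_dir)
}

.require_files <- function(...) {
  for (p in c(...))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
}

#' Discover LU domains in a proteome
#'
#' Builds a profile HMM from a seed alignment, scans the proteome, and
#' writes `hits.tsv` (protein_id, start, end, bit_score), the extracted
#' domain sequences `lu_domains.fasta`, the model `profile.json`, and a run
#' manifest.
#'
#' @param proteome_fasta Protein FASTA to scan.
#' @param seed_msa_fasta Aligned FASTA seed alignment of LU domains.
#' @param out_dir Output directory (created if needed).
#' @param bit_threshold Minimum Viterbi bit score (default 15).
#' @param match_gap_fraction,pseudocount Passed to [build_profile()].
#' @return `out_dir`, invisibly.
#' @export
run_discover <- function(proteome_fasta, seed_msa_fasta, out_dir,
                         bit_threshold = 15, match_gap_fraction = 0.5,
                         pseudocount = 1) {
  .require_files(proteome_fasta, seed_msa_fasta)
  proteome <- read_fasta(proteome_fasta, "protein")
  msa <- read_alignment(seed_msa_fasta)
  if (length(msa$ids) < 2L) stop("seed alignment has fewer than 2 sequences")
  hmm <- build_profile(msa, match_gap_fraction, pseudocount)
  hits <- scan_proteins(hmm, proteome, bit_threshold)
  seqs <- stats::setNames(vapply(proteome, `[[`, "", "sequence"),
                          vapply(proteome, `[[`, "", "id"))
  .staged(out_dir, function(stage) {
    utils::write.table(hits[, c("protein_id", "start", "end", "bit_score")],
                       file.path(stage, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    doms <- lapply(seq_len(nrow(hits)), function(k)
      protein_record(sprintf("%s/%d-%d", hits$protein_id[k], hits$start[k],
                             hits$end[k]),
                     substr(seqs[[hits$protein_id[k]]], hits$start[k] + 1L,
                            hits$end[k]),
                     description = sprintf("bits=%.2f", hits$bit_score[k])))
    write_fasta(doms, file.path(stage, "lu_domains.fasta"))
    write_profile_json(hmm, file.path(stage, "profile.json"))
    .write_manifest(stage, "discover",
                    list(bit_threshold = bit_threshold,
                         match_gap_fraction = match_gap_fraction,
                         pseudocount = pseudocount),
                    c(proteome_fasta, seed_msa_fasta))
  })
}

#' All-vs-all similarity analysis
#'
#' Computes the grouped-residue percent-similarity matrix between two LU
#' domain sets (modified BLOSUM62, global alignment) and the display
#' submatrix; writes `matrix.tsv`, `matrix_long.csv`,
#' `selected_submatrix.tsv` and a manifest.
#'
#' @param rows_fasta,cols_fasta Protein FASTA files (e.g. starfish rows,
#'   human columns).
#' @param out_dir Output directory.
#' @param gap Linear gap penalty (default -10).
#' @param cys_score Cys-Cys weight of the modified matrix (default 99).
#' @param threshold Submatrix selection cutoff (default 53, strict).
#' @param force_rows Row ids always kept in the submatrix.
#' @return The similarity matrix, invisibly.
#' @export
run_similarity <- function(rows_fasta, cols_fasta, out_dir, gap = -10,
                           cys_score = 99, threshold = 53,
                           force_rows = character()) {
  .require_files(rows_fasta, cols_fasta)
  rows <- read_fasta(rows_fasta, "protein")
  cols <- read_fasta(cols_fasta, "protein")
  m <- all_vs_all_similarity(rows, cols,
                             matrix = modified_blosum62(cys_score), gap = gap)
  sub <- select_display_submatrix(m, threshold, force_rows)
  .staged(out_dir, function(stage) {
    write_similarity_tsv(m, file.path(stage, "matrix.tsv"),
                         long_csv = file.path(stage, "matrix_long.csv"))
    write_similarity_tsv(sub, file.path(stage, "selected_submatrix.tsv"))
    .write_manifest(stage, "similarity",
                    list(gap = gap, cys_score = cys_score,
                         threshold = threshold,
                         force_rows = force_rows),
                    c(rows_fasta, cols_fasta))
  })
  invisible(m)
}

#' Translated homologue survey
#'
#' Six-frame translates the transcripts, locally aligns each ORF to the
#' query (unmodified BLOSUM62, affine -11/-1), filters hits to 100% query
#' coverage and keeps the best hit per species by grouped-residue
#' similarity. Writes `hits.tsv`, `best_per_species.tsv` and a manifest.
#'
#' @param query_fasta Single-record protein FASTA query.
#' @param transcripts_fasta Nucleotide FASTA of transcripts.
#' @param species_tsv Optional two-column TSV (transcript_id, species); if
#'   `NULL`, species labels must be embedded as `species=` tokens.
#' @param out_dir Output directory.
#' @param min_orf_len Minimum ORF length in residues (default 30).
#' @param coverage_slack Admit coverage `>= 1 - coverage_slack` (default 0).
#' @return data.frame of best-per-species hits, invisibly.
#' @export
run_survey <- function(query_fasta, transcripts_fasta, species_tsv = NULL,
                       out_dir, min_orf_len = 30, coverage_slack = 0) {
  .require_files(query_fasta, transcripts_fasta)
  query <- read_fasta(query_fasta, "protein")[[1]]
  transcripts <- read_fasta(transcripts_fasta, "nucleotide",
                            species_map = species_tsv)
  hits <- translated_search(query, transcripts, min_orf_len = min_orf_len)
  surviving <- filter_full_coverage(hits, slack = coverage_slack)
  best <- best_per_species(surviving)
  .staged(out_dir, function(stage) {
    cols <- c("species", "transcript_id", "frame", "query_coverage",
              "group_similarity_pct", "local_score")
    utils::write.table(hits[, cols], file.path(stage, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(best[, cols], file.path(stage, "best_per_species.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_manifest(stage, "survey",
                    list(min_orf_len = min_orf_len,
                         coverage_slack = coverage_slack,
                         local_gap = c(-11, -1),
                         similarity_matrix = "BLOSUM62+CC99"),
                    c(query_fasta, transcripts_fasta,
                      if (is.character(species_tsv)) species_tsv))
  })
  invisible(best)
}

#' Dendrogram from sequences or an alignment
#'
#' Aligns the input (if not already aligned), computes MSA distances and a
#' neighbor-joining tree; writes `tree.nwk` (labelled as an NJ surrogate for
#' likelihood trees), `distances.tsv` and a manifest.
#'
#' @param fasta Protein FASTA (aligned or unaligned).
#' @param out_dir Output directory.
#' @param aligned `TRUE` if the input is already an alignment.
#' @param mode Distance mode for [msa_distance()].
#' @return The `phylo` tree, invisibly.
#' @export
run_tree <- function(fasta, out_dir, aligned = FALSE,
                     mode = c("p_distance", "group_dissimilarity")) {
  mode <- match.arg(mode)
  .require_files(fasta)
  msa <- if (aligned) read_alignment(fasta)
         else progressive_msa(read_fasta(fasta, "protein"))
  d <- msa_distance(msa, mode)
  tree <- neighbor_joining(d)
  .staged(out_dir, function(stage) {
    write_newick(tree, file.path(stage, "tree.nwk"))
    utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                       file.path(stage, "distances.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_manifest(stage, "tree",
                    list(aligned = aligned, mode = mode,
                         method = "neighbor-joining (distance surrogate)"),
                    fasta)
  })
  invisible(tree)
}

#' Hill fit from a dose-response CSV
#'
#' Reads a CSV with columns `concentration_M`, `od` (and optionally
#' `replicate`), fits the Hill model and writes `hill_fit.json` plus a
#' manifest.
#'
#' @param dose_csv Input CSV path.
#' @param out_dir Output directory.
#' @return The `hill_fit`, invisibly.
#' @export
run_fit_hill <- function(dose_csv, out_dir) {
  .require_files(dose_csv)
  df <- utils::read.csv(dose_csv)
  fit <- fit_hill(df)
  .staged(out_dir, function(stage) {
    obj <- list(A1 = unname(fit$coefficients["A1"]),
                EC50_M = unname(fit$coefficients["EC50"]),
                nH = unname(fit$coefficients["nH"]),
                se_A1 = unname(fit$se["A1"]),
                se_EC50_M = unname(fit$se["EC50"]),
                se_nH = unname(fit$se["nH"]),
                converged = fit$converged, diagnostic = fit$diagnostic,
                residual_ss = fit$residual_ss)
    jsonlite::write_json(obj, file.path(stage, "hill_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(stage, "fit-hill", list(model = "3-parameter Hill"),
                    dose_csv)
  })
  invisible(fit)
}

#' qPCR normalization from a Ct CSV
#'
#' Reads a CSV with columns `sample`, `tissue`, `gene`, `ct`, normalizes to
#' the two housekeeping genes and writes `normalized.tsv`,
#' `tissue_summary.tsv` and a manifest.
#'
#' @param qpcr_csv Input CSV path.
#' @param housekeeping Character vector of the two housekeeping gene ids.
#' @param out_dir Output directory.
#' @param efficiency Amplification efficiency (default 2).
#' @return The `expression_table`, invisibly.
#' @export
run_qpcr <- function(qpcr_csv, housekeeping, out_dir, efficiency = 2) {
  .require_files(qpcr_csv)
  tab <- utils::read.csv(qpcr_csv)
  expr <- relative_expression(tab, housekeeping, efficiency)
  .staged(out_dir, function(stage) {
    utils::write.table(as.data.frame(expr), file.path(stage, "normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tissue_summary(expr),
                       file.path(stage, "tissue_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_manifest(stage, "qpcr",
                    list(housekeeping = housekeeping,
                         efficiency = efficiency,
                         aggregation = "arithmetic mean of housekeeping Ct"),
                    qpcr_csv)
  })
  invisible(expr)
}
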