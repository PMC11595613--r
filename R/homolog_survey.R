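# Translated homologue survey: a desk-scale re-implementation of the
# TBLASTN-over-TSA procedure. Transcripts are six-frame translated, ORFs
# are locally aligned to the protein query with unmodified BLOSUM62 and
# BLAST-like affine gaps, and hits are ranked by the grouped-residue
# similarity statistic (computed on a global alignment with the
# Cys-Cys-upweighted matrix, for consistency with the pairwise comparison
# stage) rather than by raw identity.

#' Search transcripts with a protein query
#'
#' Each transcript is six-frame translated ([six_frame_translate()]); every
#' ORF of at least `min_orf_len` residues is locally aligned to the query
#' ([local_align()], unmodified BLOSUM62, affine -11/-1 by default) and the
#' transcript's best positive-scoring ORF hit is reported with query
#' coverage and grouped-residue similarity (global alignment of the full
#' query against the ORF's locally aligned region, modified BLOSUM62,
#' linear gap).
#'
#' @param query A `protein_record`.
#' @param transcripts List of `nucleotide_record`s with species labels.
#' @param matrix Substitution matrix for the local search
#'   (default [blosum62()]).
#' @param min_orf_len Minimum ORF length in residues (default 30).
#' @param gap_open,gap_extend Affine parameters for the local search.
#' @param sim_matrix,sim_gap Matrix and linear gap for the similarity
#'   statistic (defaults [modified_blosum62()], -10).
#' @return data.frame (class `homolog_hits`): `transcript_id`, `species`,
#'   `frame`, `orf_start`, `subject_peptide`, `q_start`, `q_end`,
#'   `query_coverage`, `group_similarity_pct`, `local_score`.
#' @export
translated_search <- function(query, transcripts, matrix = blosum62(),
                              min_orf_len = 30, gap_open = -11,
                              gap_extend = -1,
                              sim_matrix = modified_blosum62(),
                              sim_gap = -10) {
  if (inherits(transcripts, "seq_record")) transcripts <- list(transcripts)
  if (!length(transcripts)) stop("no transcripts to search")
  qlen <- nchar(query$sequence)
  out <- list()
  for (tr in transcripts) {
    orfs <- six_frame_translate(tr, min_orf_len)
    if (!nrow(orfs)) next
    best <- NULL
    for (k in seq_len(nrow(orfs))) {
      al <- local_align(query, orfs$peptide[k], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
      if (al$score <= 0) next
      if (is.null(best) || al$score > best$al$score)
        best <- list(al = al, orf = orfs[k, ])
    }
    if (is.null(best)) next
    al <- best$al
    subject_region <- substr(best$orf$peptide, al$b_start + 1L, al$b_end)
    sim <- group_similarity(global_align(query$sequence, subject_region,
                                         matrix = sim_matrix, gap = sim_gap))
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = tr$id, species = tr$species,
      frame = best$orf$frame, orf_start = best$orf$start,
      subject_peptide = best$orf$peptide,
      q_start = al$a_start, q_end = al$a_end,
      query_coverage = query_coverage(al$a_start, al$a_end, qlen),
      group_similarity_pct = sim, local_score = al$score,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(transcript_id = character(), species = character(),
               frame = integer(), orf_start = integer(),
               subject_peptide = character(), q_start = integer(),
               q_end = integer(), query_coverage = numeric(),
               group_similarity_pct = numeric(), local_score = numeric(),
               stringsAsFactors = FALSE)
  class(res) <- c("homolog_hits", "data.frame")
  res
}

#' Query coverage of an alignment span
#'
#' @param q_start,q_end 0-based half-open span on the query.
#' @param query_len Query length in residues.
#' @return `(q_end - q_start) / query_len` in `[0, 1]`.
#' @export
query_coverage <- function(q_start, q_end, query_len) {
  if (any(q_start < 0 | q_end <= q_start | q_end > query_len))
    stop("invalid query span: need 0 <= q_start < q_end <= query_len")
  (q_end - q_start) / query_len
}

#' Keep hits with full query coverage
#'
#' With `slack = 0` (the default) only hits whose local alignment spans
#' every query residue survive; a small slack admits near-full coverage for
#' noisy assemblies. Idempotent.
#'
#' @param hits A `homolog_hits` data.frame.
#' @param slack Admit coverage `>= 1 - slack` (default 0).
#' @return The surviving rows.
#' @export
filter_full_coverage <- function(hits, slack = 0) {
  out <- hits[hits$query_coverage >= 1 - slack, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per species
#'
#' One entry per species: the hit maximizing the ranking statistic, ties
#' broken by higher local score, then lexicographically smallest transcript
#' id. Output sorted by descending similarity.
#'
#' @param hits A `homolog_hits` data.frame; every hit needs a species label.
#' @param rank_by `"group_similarity"` (default) or `"local_score"`.
#' @return data.frame of winning hits, one row per species.
#' @export
best_per_species <- function(hits,
                             rank_by = c("group_similarity", "local_score")) {
  rank_by <- match.arg(rank_by)
  if (!nrow(hits)) return(hits)
  if (any(is.na(hits$species) | !nzchar(hits$species)))
    stop("hit without species label: ",
         paste(hits$transcript_id[is.na(hits$species) |
                                    !nzchar(hits$species)], collapse = ", "))
  key <- if (rank_by == "group_similarity") hits$group_similarity_pct
         else hits$local_score
  picked <- lapply(split(seq_len(nrow(hits)), hits$species), function(idx) {
    o <- order(-key[idx], -hits$local_score[idx], hits$transcript_id[idx])
    idx[o[1]]
  })
  out <- hits[unlist(picked), , drop = FALSE]
  out <- out[order(-out$group_similarity_pct, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
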