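#' @importFrom Biostrings readBStringSet DNAString subseq reverseComplement
#' @importFrom Biostrings GENETIC_CODE
NULL

## Residue classification ----------------------------------------------------

.RESIDUE_GROUPS <- list(
  hydrophobic = c("A", "F", "H", "I", "L", "M", "P", "V", "W"),
  cysteine    = "C",
  polar       = c("G", "N", "Q", "S", "T", "Y"),
  positive    = c("K", "R"),
  negative    = c("D", "E"),
  gap         = "-"
)

.AA20 <- sort(unlist(.RESIDUE_GROUPS[setdiff(names(.RESIDUE_GROUPS), "gap")],
                     use.names = FALSE))

# symbol -> group label lookup, built once at load
.GROUP_OF <- {
  g <- rep(names(.RESIDUE_GROUPS), lengths(.RESIDUE_GROUPS))
  names(g) <- unlist(.RESIDUE_GROUPS, use.names = FALSE)
  g
}

#' Residue group scheme
#'
#' The five residue classes plus the gap class used by the grouped-residue
#' similarity statistic: hydrophobic (A,F,H,I,L,M,P,V,W), cysteine (C),
#' polar (G,N,Q,S,T,Y), positively charged (K,R), negatively charged (D,E),
#' and gap (`-`). The six groups partition the 21-symbol alphabet.
#'
#' @return Named list mapping group label to its member symbols.
#' @export
residue_groups <- function() .RESIDUE_GROUPS

#' Classify residues into groups
#'
#' @param symbol Character vector of single symbols (amino-acid letters or
#'   `-`). Ambiguity codes (B, Z, X, U, O, ...) are rejected.
#' @return Character vector of group labels.
#' @examples
#' classify_residue(c("C", "K", "-"))
#' @export
classify_residue <- function(symbol) {
  if (!is.character(symbol) || any(nchar(symbol) != 1L))
    stop("'symbol' must be single characters")
  g <- .GROUP_OF[symbol]
  if (anyNA(g)) {
    bad <- unique(symbol[is.na(g)])
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(g)
}

## Sequence records -----------------------------------------------------------

#' Protein and nucleotide sequence records
#'
#' Lightweight validated containers: a record has an `id` (no whitespace),
#' an optional free-text `description`, a non-empty uppercase `sequence`, and
#' an optional `species` label. Protein sequences are restricted to the 20
#' standard letters; nucleotide sequences to ACGT (U is mapped to T).
#'
#' @param id Record identifier, no whitespace.
#' @param sequence Sequence string; upcased on construction.
#' @param description Free-text description (default `""`).
#' @param species Optional species label.
#' @return An object of class `protein_record` or `nucleotide_record`.
#' @export
protein_record <- function(id, sequence, description = "",
                           species = NA_character_) {
  .check_id(id)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  .check_alphabet(sequence, .AA20, id)
  structure(list(id = id, description = description, sequence = sequence,
                 species = species),
            class = c("protein_record", "seq_record"))
}

#' @rdname protein_record
#' @export
nucleotide_record <- function(id, sequence, description = "",
                              species = NA_character_) {
  .check_id(id)
  sequence <- chartr("u", "t", tolower(sequence))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  .check_alphabet(sequence, c("A", "C", "G", "T"), id)
  structure(list(id = id, description = description, sequence = sequence,
                 species = species),
            class = c("nucleotide_record", "seq_record"))
}

.check_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  if (grepl("\\s", id)) stop("record id contains whitespace: '", id, "'")
}

.check_alphabet <- function(sequence, allowed, id) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad))
    stop("illegal symbol '", chars[bad[1]], "' at position ", bad[1],
         " in record '", id, "'")
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(class(x)[1], " ", x$id,
      if (!is.na(x$species)) paste0(" [", x$species, "]"),
      ": ", nchar(x$sequence), " residues\n", sep = "")
  invisible(x)
}

# ambiguity codes rejected (or skipped) on read; the group scheme covers only
# the 20 standard letters
.AMBIGUOUS_AA <- c("B", "Z", "X", "U", "O", "J")

## FASTA I/O ------------------------------------------------------------------

#' Read a FASTA file into sequence records
#'
#' Headers are split at the first whitespace into id and description.
#' Duplicate ids are an error. Lowercase is upcased; in nucleotide mode U is
#' mapped to T; in protein mode trailing/internal `*` stop symbols are
#' stripped with a warning. A species label is taken from a `species=` token
#' in the description, or from `species_map` (a two-column id/species
#' data.frame or the path to such a TSV), which takes precedence.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param species_map Optional data.frame (id, species) or TSV path.
#' @param skip_ambiguous If `TRUE`, protein records containing ambiguity
#'   codes (B, Z, X, U, O, J) are dropped with a warning instead of erroring.
#' @return List of `protein_record` / `nucleotide_record` objects, input
#'   order preserved.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       species_map = NULL, skip_ambiguous = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("cannot open FASTA file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (!length(set)) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- unname(as.character(set))

  smap <- NULL
  if (!is.null(species_map)) {
    if (is.character(species_map))
      species_map <- utils::read.delim(species_map, header = FALSE,
                                       col.names = c("id", "species"),
                                       stringsAsFactors = FALSE)
    smap <- stats::setNames(as.character(species_map[[2]]),
                            as.character(species_map[[1]]))
  }

  out <- vector("list", length(ids))
  keep <- rep(TRUE, length(ids))
  for (k in seq_along(ids)) {
    sq <- toupper(seqs[k])
    if (alphabet == "protein" && grepl("*", sq, fixed = TRUE)) {
      warning("stripping '*' stop symbol(s) from record '", ids[k], "'")
      sq <- gsub("*", "", sq, fixed = TRUE)
    }
    if (alphabet == "protein" && skip_ambiguous) {
      chars <- strsplit(sq, "", fixed = TRUE)[[1]]
      if (any(chars %in% .AMBIGUOUS_AA)) {
        warning("skipping record '", ids[k],
                "' containing ambiguous residue(s)")
        keep[k] <- FALSE
        next
      }
    }
    sp <- NA_character_
    if (grepl("species=", descs[k], fixed = TRUE))
      sp <- sub("^.*species=(\\S+).*$", "\\1", descs[k])
    if (!is.null(smap) && ids[k] %in% names(smap)) sp <- smap[[ids[k]]]
    out[[k]] <- if (alphabet == "protein")
      protein_record(ids[k], sq, descs[k], sp)
    else
      nucleotide_record(ids[k], sq, descs[k], sp)
  }
  out[keep]
}

#' Write sequence records as FASTA
#'
#' Lines are wrapped at `width` columns. A non-missing species label is
#' emitted as a `species=` token in the description so that
#' `read_fasta(write_fasta(x))` round-trips.
#'
#' @param records List of sequence records.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- r$id
    if (nzchar(r$description)) hdr <- paste(hdr, r$description)
    if (!is.na(r$species) && !grepl("species=", hdr, fixed = TRUE))
      hdr <- paste0(hdr, " species=", r$species)
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$sequence, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

## Six-frame translation ------------------------------------------------------

#' Six-frame translation with ORF splitting
#'
#' Translates all six reading frames under the standard genetic code, splits
#' each frame at stop codons, and reports segments of at least `min_orf_len`
#' residues. Coordinates are 0-based half-open on the forward strand: `start`
#' is the smallest forward-strand nucleotide offset covered by the segment,
#' so the segment occupies `[start, start + 3*nchar(peptide))` regardless of
#' strand.
#'
#' @param record A `nucleotide_record` (or plain sequence string).
#' @param min_orf_len Minimum peptide length to report (default 30).
#' @return data.frame with columns `frame` (+1..+3, -1..-3), `start`,
#'   `peptide`.
#' @export
six_frame_translate <- function(record, min_orf_len = 30) {
  seq <- if (inherits(record, "seq_record")) record$sequence else
    toupper(chartr("Uu", "Tt", record))
  L <- nchar(seq)
  if (L < 3) stop("sequence shorter than one codon")
  fwd <- seq
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  res <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) next
      pep <- .translate_codons(substr(s, f + 1L, f + 3L * ncod))
      # split at stops; k = 0-based aa offset of each segment within frame
      segs <- .split_at_stops(pep)
      for (sg in segs) {
        if (nchar(sg$pep) < min_orf_len) next
        p <- f + 3L * sg$k                      # offset on translated strand
        start <- if (strand == 1L) p else L - p - 3L * nchar(sg$pep)
        res[[length(res) + 1L]] <-
          data.frame(frame = strand * (f + 1L), start = start,
                     peptide = sg$pep, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(frame = integer(), start = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

.CODON_TABLE <- Biostrings::GENETIC_CODE  # standard code, table 1

.translate_codons <- function(nt) {
  codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  paste(.CODON_TABLE[codons], collapse = "")
}

.split_at_stops <- function(pep) {
  parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
  out <- list()
  k <- 0L
  for (p in parts) {
    if (nzchar(p)) out[[length(out) + 1L]] <- list(pep = p, k = k)
    k <- k + nchar(p) + 1L
  }
  out
}

## Hydropathy scanner ---------------------------------------------------------

# Kyte-Doolittle hydropathy index
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Candidate transmembrane segments by sliding-window hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window; maximal runs of
#' window start positions whose mean is at least `threshold` are merged and
#' reported as the union of the contributing windows. A lightweight heuristic
#' for flagging candidate membrane-spanning stretches; not a trained
#' topology predictor.
#'
#' @param record A `protein_record` or sequence string.
#' @param window Odd window length (default 19).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @return data.frame with 0-based half-open `start`, `end` columns.
#' @export
hydropathy_segments <- function(record, window = 19, threshold = 1.6) {
  seq <- if (inherits(record, "seq_record")) record$sequence else toupper(record)
  L <- nchar(seq)
  if (window %% 2 == 0) stop("window must be odd")
  if (window > L) stop("window (", window, ") larger than sequence (", L, ")")
  h <- unname(.KD[strsplit(seq, "", fixed = TRUE)[[1]]])
  cs <- c(0, cumsum(h))
  n_win <- L - window + 1L
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:n_win]) / window
  hit <- means >= threshold
  if (!any(hit))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(start = starts[idx] - 1L,             # 0-based window start
             end = ends[idx] - 1L + window)        # half-open union of windows
}
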