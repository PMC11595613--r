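---
title: "Methods: surveying LU-domain proteins with lusurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying LU-domain proteins with lusurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lusurvey)
```

# Scope and models

`lusurvey` implements the computational stages of a cross-taxon survey of
LU-domain (Ly6/uPAR, "three-finger") proteins: profile-HMM domain
discovery in a proteome, a grouped-residue similarity comparison of LU
domains between two species' repertoires, a translated homologue survey
over transcript assemblies, distance-based dendrograms, and the two
quantitative assay computations that such studies lean on (Hill-equation
ELISA fits, dual-housekeeping qPCR normalization). This vignette explains
each model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not
establish. All coordinates in outputs are 0-based, half-open.

# Grouped-residue similarity

The central comparison statistic treats amino acids as members of six
classes: hydrophobic (A,F,H,I,L,M,P,V,W), cysteine (C), polar
(G,N,Q,S,T,Y), positively charged (K,R), negatively charged (D,E), and the
gap symbol. Two aligned symbols "coincide" when they share a class;
similarity is the percentage of coinciding columns among **all** columns
of a pairwise global alignment. The gap symbol is deliberately its own
class: a gap-versus-residue column counts against similarity, so the
denominator is the full alignment length. Ambiguity codes (B, Z, X, U, O,
J) are rejected — silently mapping them to a class would fabricate
coincidences — though `read_fasta(..., skip_ambiguous = TRUE)` can drop
whole records with a warning.

The alignment behind the statistic is Needleman–Wunsch under a modified
BLOSUM62 in which the single Cys–Cys entry is raised from 9 to 99. LU
domains carry 8–10 cysteines whose pairing defines the fold; the upweight
makes any alignment that pairs scaffold cysteines dominate any alternative
placement, effectively anchoring the alignment on the disulfide scaffold
before the loops are reconciled.

**Gap model.** The linear penalty of −10 per gap symbol, with terminal
gaps penalized, is the package default. Published descriptions of this
statistic typically omit the gap parameters; −10 matches the common
default of general-purpose global aligners, and both the penalty and an
affine alternative are exposed as arguments so sensitivity to this choice
can be measured directly.

**Ties.** Co-optimal alignments can disagree in group similarity. The
traceback is pinned (substitution, then gap in the second sequence, then
gap in the first) and the number of ties met on the optimal path is
recorded on the alignment object, so tie-sensitive values are at least
flagged.

**Rounding.** Values are stored unrounded; comparisons against printed
integer percentages use round-half-away-from-zero.

**Display submatrix.** For heatmap display of an all-vs-all matrix, rows
and columns whose maximum similarity exceeds 53% (strictly) are kept, and
named reference rows are appended even when they fail the cutoff. If no
column passes, all columns are retained (with a message) so forced rows
remain displayable.

# Profile HMM discovery

The discovery stage is a didactic, self-contained profile HMM — not a
clone of any published HMM suite. Architecture: one match/insert/delete
state triplet per seed-alignment column whose gap fraction is below 0.5
(columns at or above the cutoff become inserts; insert columns before the
first match column are treated as flank), Laplace pseudocounts (+1 by
default) on emissions and transitions, a uniform 1/20 background
(BLOSUM62-marginal frequencies available via an argument), and free
background-emitting flanks so the model is local in the sequence but
global in the model. Scores are log-odds bits computed entirely in log
space; at desk-scale lengths no rescaling is needed.

Scanning extracts non-overlapping envelopes greedily: the best Viterbi hit
above the bit threshold is taken, then the flanks left and right of its
envelope are re-scanned recursively. The envelope is the span of sequence
positions emitted by non-flank states on the Viterbi path.

**Threshold.** There is no E-value calibration; a bit-score threshold
(default 15) plays that role. The default was calibrated once on decoys
from a generator seed independent of the seeds used by the validation
suite, and sits far from both sides of the empirical score distribution:
on the default synthetic proteome, planted domains score ≥ 37 bits and
composition-matched decoys stay below 0 bits.

# Translated homologue survey

Transcripts are translated in all six frames under the standard genetic
code, split at stop codons, and ORFs of ≥ 30 residues are locally aligned
to the query with **unmodified** BLOSUM62 and BLAST-like affine gaps
(−11/−1; a run of length *k* costs `gap_open + k·gap_extend`). The
Cys–Cys upweight is intentionally absent here: the local search emulates a
BLAST-style screen, and only the subsequent similarity statistic uses the
modified matrix, computed on a global alignment of the full query against
the ORF's locally aligned region. This keeps survey percentages on the
same scale as the pairwise repertoire comparison; ranking by raw local
score is available via `best_per_species(..., rank_by = "local_score")`.

Hits require a positive local score; there are no E-values at this scale.
The 100%-coverage filter is exact by default: the local alignment must
span every query residue. Because Smith–Waterman trims terminal columns
that score negatively, genuinely homologous but diverged sequences can
fail the filter by a residue or two — the same behavior that makes real
TBLASTN surveys discard a sizeable fraction of true homologues. A
`coverage_slack` argument admits near-full coverage where that is too
strict. Ties in best-per-species selection resolve by local score, then
lexicographic transcript id.

# Alignment, distances, and trees

The progressive aligner is a desk-scale surrogate for production MSA
tools: guide order from average-linkage clustering of 3-mer count cosine
distances, profile–profile Needleman–Wunsch merges under the mean-of-pairs
column score, "once a gap, always a gap". The dendrogram stage is
Saitou–Nei neighbor joining over MSA distances (p-distance over columns
where neither row is gapped, or group dissimilarity
`1 − similarity/100`). Likelihood tree search is deliberately out of
scope: in this workflow trees are descriptive summaries of similarity
structure, not vehicles for support values, and NJ is exact on additive
inputs — the validation suite verifies exact recovery (topology and branch
lengths to 1e-9) of 100 random 5–10-leaf additive matrices. Pair selection
ties break lexicographically; a negative branch-length estimate is clamped
to zero with the deficit moved to its sibling so the pair's summed length
is preserved; output is unrooted with a trifurcating root, branch lengths
written to 6 decimals.

# Assay statistics

**Hill fits.** ELISA curves are fitted with the three-parameter Hill form
`y = A1·c^nH/(EC50^nH + c^nH)` — zero baseline, because blank-well O.D. is
subtracted before fitting. Fitting is Levenberg–Marquardt least squares
with a small multi-start: `A1` from the largest per-concentration mean,
`EC50` from the concentration nearest half-maximum, and `nH` ∈
{0.5, 1, 2}; the converged start with the lowest residual sum of squares
wins. Standard errors come from the fit covariance. A fit is declared
non-converged when every start fails, when the response is flat ("no dose
dependence"), or when the fitted EC50 leaves the tested concentration
range by more than 10-fold — an EC50 outside the sampled range is an
extrapolation, not a measurement. Units are molar throughout; reports
convert to nM.

**qPCR.** Relative expression is `E^−ΔCt` with ΔCt measured against the
arithmetic mean Ct of two housekeeping genes (equivalently, the geometric
mean of their expression). Efficiency `E` defaults to 2 (perfect
doubling), exposed as an argument since real efficiencies run slightly
lower. Tissue summaries report mean ± SEM. Downstream inferential
statistics (ANOVA and relatives) are left to general-purpose packages;
the normalized per-sample table is the interface.

# Synthetic data: what it emulates, and what it does not

Generators are pure functions of a `sim_config`; a fixed seed gives
byte-identical output (`withr::with_seed` isolates them from ambient RNG
state).

* **Proteomes.** Each planted protein is a signal-peptide-like N-terminus
  (M + 8–12 hydrophobic residues), one LU domain, and optionally a
  GPI-like C-tail. The domain architecture — length (drawn once from
  60–90), cysteine offsets (spacing ≥ 3), and a per-position residue-class
  profile — is fixed by a separate `scaffold_seed`, so independently
  seeded proteomes share one architecture the way real LU domains share
  theirs, and HMM match states align across planted instances.
  Non-cysteine positions follow their profile class with probability
  0.85. Decoys are composition-matched shuffles, re-drawn in the rare
  case a shuffle reproduces the full cysteine scaffold.
* **Transcript panels.** Species-labelled transcripts encode the ancestor
  mutated at a per-site probability, with 70% of substitutions staying
  within the residue class — the knob that separates group similarity from
  plain identity measurably (at divergence *d*, identity falls roughly as
  1 − *d* but group similarity as 1 − 0.3 *d*). Mutants are back-translated
  with random synonymous codons, wrapped in random UTRs, and placed on a
  random strand. The default panel spans divergences 0.02–0.40 across ten
  species plus two deliberately truncated species (C-terminal half only)
  for the coverage filter. Truth tables record programmed divergence and
  the realized similarity of each encoded peptide.
* **Assays.** Dose-response truth defaults to the coelomocyte-like
  operating point (A1 = 1.97, EC50 = 54.5 nM, nH = 0.71, noise sd 0.05,
  5 replicates at 11 log-spaced concentrations over 1e-10–1e-5 M); qPCR
  truth uses four tissues at levels 8, 4, 0.1 and 0.01 with two stable
  housekeeping genes (Ct noise sd 0.2, 5 samples per tissue), mirroring a
  system where expression concentrates in coelomocytes and coelomic
  epithelium and is nearly absent elsewhere.

The generators have **no indel process** (beyond optional truncation), no
rate heterogeneity across sites, and no compositional drift between
species. Passing recovery tests therefore demonstrates correctness of the
implementations and calibration of thresholds under clean conditions; it
does not establish sensitivity on real proteomes, where domain boundaries
blur, insert states carry real load, and assemblies contain frameshifts.
Likewise, the planted-domain benchmark (20 LU proteins, 80 decoys,
perfect recovery at 15 bits) bounds the method's behavior on data
generated from its own model family, which is the strongest claim
synthetic validation can make.

# Problem sizes and determinism

The validation suite runs at sizes chosen to exercise every code path
while staying exhaustively checkable: brute-force alignment oracles at
sequence lengths ≤ 6, HMM path enumeration at ≤ 3 match states and
sequences ≤ 5, 100-tree NJ recovery at 5–10 leaves, 200-curve Hill
calibration runs, and a 100-protein discovery benchmark. Deterministic
stages (alignment, scoring, HMM, NJ) never consume random numbers; only
the generators and the stochastic recovery tests take seeds. Checks
against the deposited LU-domain sets of the motivating survey (51
starfish × 57 human domains, headline pairs 67/63/58/45%) require those
third-party FASTA files to be supplied locally, as documented in the
README; all other validation is self-contained.
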