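## Pairwise nucleotide alignment and identity.
##
## All alignments in the package use one scoring scheme: match +1,
## mismatch -1, affine gaps costing 2 + L for a gap of length L
## (opening penalty 2, extension penalty 1 per gapped base). N never
## matches anything, including another N.

.DNA_BASES <- c("A", "C", "G", "T")

#' Substitution matrix used throughout the package
#' @noRd
.sub_matrix <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", "N"] <- -1  # N is an unknown base, never a match
  function() m
})

.GAP_OPEN <- 2
.GAP_EXT <- 1

#' Identity of an aligned string pair: matching columns / all columns
#'
#' Gap columns count as aligned, non-matching; N columns never match.
#' @noRd
.aligned_identity <- function(p, s) {
  pv <- strsplit(p, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  sum(pv == sv & pv %in% .DNA_BASES) / length(pv)
}

#' Global identity between two nucleotide sequences
#'
#' Computes the optimal Needleman-Wunsch global alignment (match +1,
#' mismatch -1, gap of length L costs 2 + L, end gaps penalised) and
#' returns the fraction of matching columns over all aligned columns.
#' Gap columns count as aligned, non-matching columns, so the value lies
#' in `[0, 1]` and is symmetric in its arguments.
#'
#' @param a,b Nucleotide sequences over the alphabet A, C, G, T, N.
#' @return A single numeric identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGT")  # 1
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  check_dna(a, "sequence a")
  check_dna(b, "sequence b")
  .identity_one_vs_many(a, b)[1L]
}

#' Global identities of one query against many targets (vectorised)
#'
#' Fast path: aligned columns (including end gaps) are
#' `len_p + len_s - nmatch - nmismatch`, since base-base columns are
#' exactly the match/mismatch columns. When any sequence carries an N the
#' gapped strings are compared instead, so N-N columns never count as
#' matches.
#' @noRd
.identity_one_vs_many <- function(query, targets) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(targets), query, type = "global",
    substitutionMatrix = .sub_matrix(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  if (!grepl("N", query, fixed = TRUE) &&
      !any(grepl("N", targets, fixed = TRUE))) {
    nm <- Biostrings::nmatch(aln)
    cols <- nchar(targets) + nchar(query) - nm - Biostrings::nmismatch(aln)
    return(nm / cols)
  }
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(p), function(i) .aligned_identity(p[i], s[i]), numeric(1))
}

#' Best local alignment of a query against a subject
#'
#' Smith-Waterman local alignment under the package scoring scheme.
#' Identity is computed over the aligned (local) columns only; coverage is
#' the fraction of the query included in the alignment.
#'
#' @param query,subject Nucleotide sequences.
#' @return A list with `score`, `identity`, `aligned_columns`,
#'   `query_coverage`.
#' @export
local_alignment <- function(query, subject) {
  check_dna(query, "query")
  check_dna(subject, "subject")
  aln <- Biostrings::pairwiseAlignment(
    query, subject, type = "local", substitutionMatrix = .sub_matrix(),
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  ncol_aln <- nchar(p)
  id <- if (ncol_aln > 0) .aligned_identity(p, s) else 0
  q_used <- sum(strsplit(p, "")[[1]] != "-")
  list(score = Biostrings::score(aln),
       identity = id,
       aligned_columns = ncol_aln,
       query_coverage = q_used / nchar(query))
}

#' Integer-encode all k-mers of a sequence (A=0,C=1,G=2,T=3); k <= 15
#'
#' Positions containing N are dropped.
#' @noRd
.kmer_codes <- function(seq, k) {
  v <- match(strsplit(seq, "")[[1]], .DNA_BASES) - 1L
  n <- length(v)
  if (n < k) return(integer(0))
  num <- rep(0, n - k + 1L)
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    vj <- v[j:(n - k + j)]
    ok <- ok & !is.na(vj)
    num <- num * 4 + ifelse(is.na(vj), 0, vj)
  }
  unique(num[ok])
}
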