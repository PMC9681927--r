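## Thin wrappers around Biostrings' affine-gap aligner with the scoring
## scheme used throughout the package: DNA match +2 / mismatch -3,
## gap open 5 / extend 2 (BLAST-like defaults); protein alignments use
## BLOSUM62. Identity is matches / alignment columns, gap columns included.

dna_score_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      s <- matrix(-3, 5, 5, dimnames = list(bases, bases))
      diag(s) <- 2
      s["N", ] <- -1
      s[, "N"] <- -1
      m <<- s
    }
    m
  }
})

aln_identity <- function(q_aln, r_aln) {
  q <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(r_aln, "", fixed = TRUE)[[1]]
  100 * sum(q == r & q != "-") / length(q)
}

#' Pairwise DNA alignment (affine gaps)
#'
#' @param query,reference DNA strings.
#' @param type `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @param gap_open,gap_ext gap penalties (positive costs).
#' @return list with `q_aln`, `r_aln` (equal-length aligned strings, gap
#'   character `-`), `score`, `identity` (percent, gap columns counted),
#'   and for local alignments `q_start`, `q_end`, `r_start`, `r_end`
#'   (0-based half-open coordinates of the aligned spans).
#' @keywords internal
align_dna <- function(query, reference, type = "global", gap_open = 5,
                      gap_ext = 2) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = type, substitutionMatrix = dna_score_matrix(),
    gapOpening = gap_open, gapExtension = gap_ext)
  q_aln <- as.character(Biostrings::alignedPattern(al))
  r_aln <- as.character(Biostrings::alignedSubject(al))
  out <- list(q_aln = q_aln, r_aln = r_aln, score = Biostrings::score(al),
              identity = aln_identity(q_aln, r_aln))
  if (type == "local") {
    pat <- al@pattern
    sub <- al@subject
    out$q_start <- Biostrings::start(pat@range) - 1L
    out$q_end <- Biostrings::end(pat@range)
    out$r_start <- Biostrings::start(sub@range) - 1L
    out$r_end <- Biostrings::end(sub@range)
  }
  out
}

## local protein alignment score against BLOSUM62 (frame selection,
## peptide identity reports)
align_protein <- function(query, reference, type = "local") {
  q <- gsub("\\*", "X", query)
  r <- gsub("\\*", "X", reference)
  if (!nzchar(q) || !nzchar(r)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(r), type = type,
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  list(q_aln = as.character(Biostrings::alignedPattern(al)),
       r_aln = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al),
       identity = aln_identity(as.character(Biostrings::alignedPattern(al)),
                               as.character(Biostrings::alignedSubject(al))))
}
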