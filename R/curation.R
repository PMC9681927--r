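## Assembly curation: ORF annotation, length filtering, representative
## selection per (assembly component, orthogroup) group, and assembly
## completeness statistics (Nxx, ultra-conserved-ortholog capture).

#' Build a contig table
#'
#' The contig table is the working unit of the curation stage: one row per
#' assembled contig with its assembly component (locus) id and optional
#' orthogroup assignment.
#'
#' @param seqs named character vector of contig sequences.
#' @param components named character vector mapping contig id to assembly
#'   component id; by default the prefix of the contig id up to the last
#'   `_cN` suffix (Trinity-style `compX_cY_seqZ` ids map to `compX_cY`).
#' @param orthogroups optional data.frame from [read_orthogroups()].
#' @return data.frame with columns `id`, `sequence`, `length`, `component`,
#'   `orthogroup` (NA when unassigned).
#' @export
contig_table <- function(seqs, components = NULL, orthogroups = NULL) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  comp <- if (is.null(components)) {
    sub("_(seq|c)[0-9]+$", "", ids)
  } else {
    unname(components[ids])
  }
  if (anyNA(comp) || any(!nzchar(comp))) stop("missing component id")
  og <- rep(NA_character_, length(ids))
  if (!is.null(orthogroups)) {
    m <- match(ids, orthogroups$contig_id)
    og <- orthogroups$orthogroup_id[m]
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             component = comp, orthogroup = og,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Longest open reading frame over all six frames
#'
#' An ORF is an ATG followed by an in-frame stop codon within the contig;
#' ORFs running off the contig end are not counted. The length includes the
#' stop codon. Coordinates are reported on the forward contig (0-based
#' half-open), with frame +1..+3 for the forward strand and -1..-3 for the
#' reverse strand.
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return list with `start`, `end`, `frame`, `length`, or `NULL` when the
#'   contig has no complete ORF.
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("non-DNA alphabet in contig")
  L <- nchar(seq)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n3 <- L %/% 3L
    for (off in 0:2) {
      n <- (L - off) %/% 3L
      if (n < 2L) next
      st <- seq(off + 1L, by = 3L, length.out = n)
      codons <- substring(s, st, st + 2L)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% STOP_CODONS
      if (!any(is_atg) || !any(is_stop)) next
      stop_idx <- which(is_stop)
      for (a in which(is_atg)) {
        nxt <- stop_idx[stop_idx >= a]
        if (length(nxt) == 0L) break
        len <- (nxt[1] - a + 1L) * 3L
        if (is.null(best) || len > best$length) {
          s0 <- st[a] - 1L           # 0-based on this strand
          e0 <- s0 + len
          if (strand == "+") {
            best <- list(start = s0, end = e0, frame = off + 1L, length = len)
          } else {
            best <- list(start = L - e0, end = L - s0, frame = -(off + 1L),
                         length = len)
          }
        }
      }
    }
  }
  best
}

#' Annotate contigs with their longest ORF
#'
#' @param contigs contig table from [contig_table()].
#' @return the table with added columns `orf_start`, `orf_end`, `orf_frame`,
#'   `orf_len` (NA where no ORF).
#' @export
annotate_orfs <- function(contigs) {
  orfs <- lapply(contigs$sequence, find_longest_orf)
  pick <- function(f) vapply(orfs, function(o)
    if (is.null(o)) NA_integer_ else as.integer(o[[f]]), integer(1))
  contigs$orf_start <- pick("start")
  contigs$orf_end <- pick("end")
  contigs$orf_frame <- pick("frame")
  contigs$orf_len <- pick("length")
  contigs
}

#' Filter contigs by ORF length
#'
#' Keeps contigs whose longest ORF is strictly greater than `min_orf_bp`
#' (contigs without any ORF are dropped). Row order is preserved.
#'
#' @param contigs ORF-annotated contig table.
#' @param min_orf_bp minimum ORF length, exclusive (default 200).
#' @return filtered contig table.
#' @export
filter_orf <- function(contigs, min_orf_bp = 200L) {
  if (!"orf_len" %in% names(contigs)) stop("run annotate_orfs() first")
  keep <- !is.na(contigs$orf_len) & contigs$orf_len > min_orf_bp
  contigs[keep, , drop = FALSE]
}

#' Select one representative contig per (component, orthogroup) group
#'
#' Within each assembly component, contigs sharing an orthogroup form one
#' group and the longest contig is kept; ties are broken by the
#' lexicographically smallest id. Contigs without an orthogroup assignment
#' are grouped by component alone, so they survive curation but contribute
#' one representative per component.
#'
#' @param contigs contig table.
#' @return contig table of representatives, in input order.
#' @export
select_representatives <- function(contigs) {
  key <- paste(contigs$component,
               ifelse(is.na(contigs$orthogroup), "<unassigned>",
                      contigs$orthogroup), sep = "\r")
  ord <- order(key, -contigs$length, contigs$id)
  first <- !duplicated(key[ord])
  keep_idx <- sort(ord[first])
  contigs[keep_idx, , drop = FALSE]
}

#' Nxx length of a set of contig lengths
#'
#' The length `L` such that contigs of length `>= L` together contain at
#' least `xx`% of all assembled bases.
#'
#' @param lengths integer vector of contig lengths.
#' @param xx percentage threshold (e.g. 50 for N50).
#' @return Nxx length in bp.
#' @export
nxx <- function(lengths, xx) {
  stopifnot(length(lengths) > 0, xx > 0, xx <= 100)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= xx / 100 * sum(as.numeric(s)))[1]]
}

#' Assembly summary statistics
#'
#' @param contigs contig table (typically of representatives).
#' @param assigned_only restrict to contigs with an orthogroup assignment
#'   (mirrors reporting on the assigned subset of an assembly).
#' @return list with `n_contigs`, `n_assigned`, `N25`, `N50`, `mean_len`,
#'   `min_len`, `max_len`.
#' @export
assembly_stats <- function(contigs, assigned_only = FALSE) {
  if (assigned_only) {
    contigs <- contigs[!is.na(contigs$orthogroup), , drop = FALSE]
  }
  if (nrow(contigs) == 0L) stop("no contigs to summarise")
  len <- contigs$length
  list(n_contigs = nrow(contigs),
       n_assigned = sum(!is.na(contigs$orthogroup)),
       N25 = nxx(len, 25), N50 = nxx(len, 50),
       mean_len = mean(len), min_len = min(len), max_len = max(len))
}

#' Ultra-conserved-ortholog capture rate
#'
#' The fraction of a benchmark set of single-copy orthogroups present in the
#' transcriptome, a standard proxy for assembly completeness.
#'
#' @param orthogroups_present character vector of orthogroup ids observed in
#'   the assembly.
#' @param uco_ids character vector of benchmark orthogroup ids.
#' @return list with `total`, `captured`, `rate` (fraction) and `percent`
#'   (percentage truncated to one decimal, the reporting convention used
#'   for capture-rate tables).
#' @export
uco_capture <- function(orthogroups_present, uco_ids) {
  if (length(uco_ids) == 0L) stop("empty UCO id list")
  captured <- sum(uco_ids %in% orthogroups_present)
  rate <- captured / length(uco_ids)
  list(total = length(uco_ids), captured = captured, rate = rate,
       percent = floor(1000 * rate) / 10)
}

#' Run the full curation stage
#'
#' ORF annotation, ORF-length filtering and representative selection in one
#' call; curation is idempotent.
#'
#' @param contigs contig table.
#' @param min_orf_bp ORF filter threshold (default 200, exclusive).
#' @return curated contig table.
#' @export
curate <- function(contigs, min_orf_bp = 200L) {
  if (!"orf_len" %in% names(contigs)) contigs <- annotate_orfs(contigs)
  select_representatives(filter_orf(contigs, min_orf_bp))
}
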