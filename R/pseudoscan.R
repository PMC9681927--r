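## Pseudogenization scan: compare a (reconstructed) CDS against a conserved
## reference ortholog and call frameshift indels, premature stop codons and
## retained introns, then classify the gene's status.

#' Global pairwise alignment of a query CDS against a reference CDS
#'
#' Affine-gap Needleman-Wunsch with the package's DNA scoring (match +2,
#' mismatch -3, gap extend 2). The gap-open penalty defaults to 20 --
#' deliberately higher than in local contig mapping -- so that one long
#' indel (a retained intron, say) stays one gap run instead of being
#' interrupted at every chance 4-base match; event calling needs the
#' parsimonious representation. Traceback is deterministic.
#'
#' @param query_cds,reference_cds DNA strings; lengths within 5x of each
#'   other.
#' @param gap_open gap-open penalty (default 20).
#' @return a `pairwise_alignment`: list with `q_aln`, `r_aln` (equal-length
#'   aligned strings), `score`, `identity` (percent of columns that match,
#'   gap columns included).
#' @export
global_align <- function(query_cds, reference_cds, gap_open = 20) {
  if (!nzchar(query_cds) || !nzchar(reference_cds)) stop("empty sequence")
  if (nchar(query_cds) > 5 * nchar(reference_cds) ||
      nchar(reference_cds) > 5 * nchar(query_cds)) {
    stop("sequence lengths differ by more than 5x")
  }
  al <- align_dna(query_cds, reference_cds, type = "global",
                  gap_open = gap_open)
  structure(al, class = "pairwise_alignment")
}

## reference CDS coordinate (0-based) of the last reference base at or
## before each alignment column; -1 before the first reference base
ref_coord_map <- function(r_chars) {
  cumsum(r_chars != "-") - 1L
}

#' Detect insertion and deletion events from a pairwise alignment
#'
#' Each maximal gap run becomes one event: a gap run in the reference row
#' is an insertion in the query, a gap run in the query row a deletion.
#' `ref_pos` is the 0-based reference CDS coordinate of the base preceding
#' the run; `frame_offset = length %% 3` (0 marks an in-frame event).
#'
#' @param alignment a `pairwise_alignment` from [global_align()].
#' @return data.frame with columns `kind`, `ref_pos`, `length`,
#'   `frame_offset`, `seq` (the inserted/deleted bases), `aln_col`
#'   (1-based alignment column where the run starts); empty when the
#'   alignment has no gaps.
#' @export
detect_indels <- function(alignment) {
  q <- strsplit(alignment$q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(alignment$r_aln, "", fixed = TRUE)[[1]]
  rmap <- ref_coord_map(r)
  events <- list()
  state <- ifelse(r == "-", "insertion", ifelse(q == "-", "deletion", "m"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values)) {
    kind <- runs$values[i]
    if (kind == "m") next
    len <- runs$lengths[i]
    col <- starts[i]
    ref_pos <- if (kind == "insertion") rmap[col] else rmap[col] - 1L
    sq <- if (kind == "insertion")
      paste(q[col:ends[i]], collapse = "") else
      paste(r[col:ends[i]], collapse = "")
    events[[length(events) + 1L]] <-
      data.frame(kind = kind, ref_pos = ref_pos, length = len,
                 frame_offset = len %% 3L, seq = sq, aln_col = col,
                 stringsAsFactors = FALSE)
  }
  if (length(events) == 0L) {
    return(data.frame(kind = character(0), ref_pos = integer(0),
                      length = integer(0), frame_offset = integer(0),
                      seq = character(0), aln_col = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, events)
}

#' Detect a premature stop codon in the query
#'
#' The query reading frame is anchored at the query base aligned to the
#' reference start codon; the first in-frame query stop whose alignment
#' column lies strictly before the column of the reference's terminal stop
#' codon is premature. A stop at the terminal position only returns
#' `NULL`.
#'
#' @param query_cds the (unaligned) query sequence.
#' @param alignment a `pairwise_alignment` of `query_cds` vs the
#'   reference.
#' @return `NULL`, or a list with `kind = "premature_stop"`, `query_pos`
#'   (0-based query coordinate of the stop codon start), `ref_pos`
#'   (0-based reference coordinate at the stop), `aln_col` (1-based
#'   alignment column of the first stop base), `codon`, and
#'   `truncated_fraction` (fraction of the reference protein lost).
#' @export
detect_premature_stop <- function(query_cds, alignment) {
  q <- strsplit(alignment$q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(alignment$r_aln, "", fixed = TRUE)[[1]]
  qmap <- cumsum(q != "-") - 1L       # query coord at each column
  rmap <- ref_coord_map(r)
  ref_len <- max(rmap) + 1L
  ## anchor: query base aligned to reference position 0
  anchor_col <- which(r != "-")[1]
  q_anchor <- qmap[anchor_col]
  if (q[anchor_col] == "-") q_anchor <- q_anchor + 1L  # next query base
  ## column of the reference terminal stop codon (first base)
  term_col <- which(rmap == ref_len - 3L & r != "-")[1]
  ## column of each query coordinate
  qcols <- which(q != "-")
  n_q <- nchar(query_cds)
  n_codons <- (n_q - q_anchor) %/% 3L
  if (n_codons < 1L) return(NULL)
  starts <- q_anchor + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(query_cds, starts + 1L, starts + 3L)
  hits <- which(codons %in% STOP_CODONS)
  if (length(hits) == 0L) {
    return(structure(NULL, no_stop = TRUE))
  }
  qpos <- starts[hits[1]]
  col <- qcols[qpos + 1L]
  if (!is.na(term_col) && col >= term_col) return(NULL)
  ref_pep_len <- ref_len / 3L - 1L
  trunc_frac <- 1 - (hits[1] - 1L) / ref_pep_len
  list(kind = "premature_stop", query_pos = qpos, ref_pos = rmap[col],
       aln_col = col, codon = codons[hits[1]],
       truncated_fraction = max(0, trunc_frac))
}

#' Reclassify insertions at exon junctions as retained introns
#'
#' An insertion becomes a retained intron when its reference position lies
#' within `junction_tol` bp of an annotated exon-exon junction and its
#' length is within `length_tol` (fractional) of that intron's annotated
#' length. GT..AG termini of the inserted sequence are recorded as
#' corroborating evidence but are not required. The junction tolerance
#' must absorb the aligner's gap-placement ambiguity: with a diverged
#' flank the optimal alignment can slide a long gap by around ten bases,
#' so the default window is 12 bp; the +/-5% length match remains the
#' decisive signature.
#'
#' @param alignment a `pairwise_alignment`, or a data.frame of events from
#'   [detect_indels()].
#' @param gene_model reference [gene_model()] supplying exon junctions;
#'   without one the operation is unavailable and insertions stay
#'   insertions.
#' @param junction_tol junction distance tolerance in bp (default 12).
#' @param length_tol fractional length tolerance (default 0.05).
#' @return the event data.frame with matching insertions relabelled
#'   `retained_intron` and columns `intron_index` and `gt_ag` added.
#' @export
detect_retained_intron <- function(alignment, gene_model,
                                   junction_tol = 12L, length_tol = 0.05) {
  events <- if (is.data.frame(alignment)) alignment
            else detect_indels(alignment)
  events$intron_index <- rep(NA_integer_, nrow(events))
  events$gt_ag <- rep(NA, nrow(events))
  if (is.null(gene_model)) {
    stop("retained-intron detection needs a reference gene model")
  }
  junc <- gene_model_junctions(gene_model)
  if (nrow(junc) == 0L || nrow(events) == 0L) return(events)
  ## Even with a high gap-open penalty the aligner occasionally interrupts
  ## a very long insertion where its interior happens to match the exon;
  ## nearby insertion runs are therefore clustered (separated by at most
  ## `merge_cols` aligned columns) and each cluster is tested against the
  ## junctions as one event.
  merge_cols <- 15L
  ins_idx <- which(events$kind == "insertion")
  ins_idx <- ins_idx[order(events$aln_col[ins_idx])]
  clusters <- list()
  cur <- integer(0)
  last_end <- -Inf
  for (i in ins_idx) {
    if (length(cur) > 0L &&
        events$aln_col[i] - last_end > merge_cols) {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- integer(0)
    }
    cur <- c(cur, i)
    last_end <- events$aln_col[i] + events$length[i]
  }
  if (length(cur) > 0L) clusters[[length(clusters) + 1L]] <- cur
  drop <- integer(0)
  for (cl in clusters) {
    total <- sum(events$length[cl])
    pos <- events$ref_pos[cl[1]]
    ## insertion sits after ref_pos; junction cds_pos is the first base of
    ## the downstream exon, so a retained intron has ref_pos ~ cds_pos - 1
    d <- abs(junc$cds_pos - 1L - pos)
    j <- which.min(d)
    if (d[j] <= junction_tol &&
        abs(total - junc$length[j]) <= length_tol * junc$length[j]) {
      k <- cl[1]
      events$kind[k] <- "retained_intron"
      events$length[k] <- total
      events$frame_offset[k] <- total %% 3L
      events$seq[k] <- paste(events$seq[cl], collapse = "")
      events$intron_index[k] <- junc$intron[j]
      events$gt_ag[k] <- startsWith(events$seq[k], "GT") &&
        endsWith(events$seq[k], "AG")
      drop <- c(drop, cl[-1])
    }
  }
  if (length(drop) > 0L) events <- events[-drop, , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Scan a query CDS against a reference ortholog for pseudogenization
#' events
#'
#' Runs [global_align()], [detect_indels()], retained-intron
#' reclassification (when a gene model is supplied) and
#' [detect_premature_stop()], optionally marks events as read-supported,
#' and classifies the gene.
#'
#' @param query_cds query CDS.
#' @param reference_cds reference ortholog CDS.
#' @param gene_model optional reference [gene_model()] for retained-intron
#'   calls.
#' @param reads optional read pool; events spanned by at least
#'   `min_read_support` reads carrying the variant get `read_support =
#'   TRUE` (left `NA` when no reads are supplied).
#' @param min_read_support reads required for support (default 2).
#' @param flank bases of query context either side of an event used for
#'   read support (default 15).
#' @return list with `alignment`, `events` (data.frame incl. any
#'   premature stop), `status` (from [classify()]), `identity`.
#' @export
scan_pseudogene <- function(query_cds, reference_cds, gene_model = NULL,
                            reads = NULL, min_read_support = 2L,
                            flank = 15L) {
  al <- global_align(query_cds, reference_cds)
  events <- detect_indels(al)
  if (!is.null(gene_model)) {
    events <- detect_retained_intron(events, gene_model)
  } else {
    events$intron_index <- rep(NA_integer_, nrow(events))
    events$gt_ag <- rep(NA, nrow(events))
  }
  events$read_support <- rep(NA, nrow(events))
  if (!is.null(reads) && nrow(events) > 0L) {
    pool <- c(unname(reads), revcomp(unname(reads)))
    qmapcols <- strsplit(al$q_aln, "", fixed = TRUE)[[1]]
    qmap <- cumsum(qmapcols != "-") - 1L
    for (i in seq_len(nrow(events))) {
      qpos <- qmap[events$aln_col[i]]   # query coord at run start
      lo <- max(0L, qpos - flank)
      hi <- min(nchar(query_cds),
                qpos + flank +
                  if (events$kind[i] == "deletion") 0L else events$length[i])
      probe <- substring(query_cds, lo + 1L, hi)
      events$read_support[i] <-
        sum(grepl(probe, pool, fixed = TRUE)) >= min_read_support
    }
  }
  ps <- detect_premature_stop(query_cds, al)
  events_all <- events
  if (!is.null(ps)) {
    events_all <- rbind(events,
                        data.frame(kind = "premature_stop",
                                   ref_pos = ps$ref_pos, length = 3L,
                                   frame_offset = 0L, seq = ps$codon,
                                   aln_col = ps$aln_col,
                                   intron_index = NA_integer_, gt_ag = NA,
                                   read_support = NA,
                                   stringsAsFactors = FALSE))
    attr(events_all, "truncated_fraction") <- ps$truncated_fraction
  }
  status <- classify(events_all)
  list(alignment = al, events = events_all, status = status,
       identity = al$identity)
}

#' Classify a gene's status from its detected events
#'
#' A frameshift indel (non-zero frame offset) followed by a premature stop
#' that truncates at least `truncated_fraction_threshold` of the reference
#' protein makes a `frameshift_pseudogene`; a retained intron (with no
#' frameshift call) gives `retained_intron`; a premature stop alone gives
#' `truncated`; only in-frame indels give `in_frame_variant`; no events at
#' all gives `conserved`. The label is a pure function of the event set —
#' event order never matters.
#'
#' @param events event data.frame (as produced by [scan_pseudogene()]; an
#'   optional `truncated_fraction` attribute accompanies a premature
#'   stop).
#' @param truncated_fraction_threshold minimum truncated fraction of the
#'   reference protein for a pseudogene call (default 0.05).
#' @return list with `label`, `events`, `truncated_fraction`.
#' @export
classify <- function(events, truncated_fraction_threshold = 0.05) {
  tf <- attr(events, "truncated_fraction")
  if (is.null(tf)) tf <- NA_real_
  indels <- events[events$kind %in% c("insertion", "deletion"), ,
                   drop = FALSE]
  stops <- events[events$kind == "premature_stop", , drop = FALSE]
  retained <- events[events$kind == "retained_intron", , drop = FALSE]
  frameshift <- indels[indels$frame_offset != 0L, , drop = FALSE]
  label <- if (nrow(frameshift) > 0L && nrow(stops) > 0L &&
               any(outer(stops$ref_pos, frameshift$ref_pos, `>=`)) &&
               (is.na(tf) || tf >= truncated_fraction_threshold)) {
    "frameshift_pseudogene"
  } else if (nrow(retained) > 0L) {
    "retained_intron"
  } else if (nrow(stops) > 0L &&
             (is.na(tf) || tf >= truncated_fraction_threshold)) {
    "truncated"
  } else if (nrow(indels) > 0L) {
    "in_frame_variant"
  } else {
    "conserved"
  }
  list(label = label, events = events, truncated_fraction = tf)
}
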