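## Ortholog-guided full-length CDS reconstruction: map fragmented contigs
## onto a conserved reference CDS, stitch them in reference order, fill the
## remaining gaps by iterative exact-match ("grep"-style) read extension,
## and recover unannotated genes from genomic scaffolds by translated
## search.

## recursive colinear chain of local alignments between one oriented
## contig and the reference (a contig carrying a long insertion -- e.g. a
## retained intron -- maps as two blocks flanking it)
chain_contig <- function(seqq, ref, q_lo, q_hi, r_lo, r_hi, min_score) {
  if (q_hi - q_lo < 25L || r_hi - r_lo < 25L) return(list())
  al <- align_dna(substring(seqq, q_lo + 1L, q_hi),
                  substring(ref, r_lo + 1L, r_hi), type = "local")
  if (al$score < min_score) return(list())
  blk <- list(score = al$score, identity = al$identity,
              q_start = q_lo + al$q_start, q_end = q_lo + al$q_end,
              r_start = r_lo + al$r_start, r_end = r_lo + al$r_end,
              q_aln = al$q_aln, r_aln = al$r_aln)
  c(chain_contig(seqq, ref, q_lo, blk$q_start, r_lo, blk$r_start,
                 min_score),
    list(blk),
    chain_contig(seqq, ref, blk$q_end, q_hi, blk$r_end, r_hi, min_score))
}

#' Map assembled contigs onto a reference ortholog CDS
#'
#' Each contig is aligned against the reference on both strands as a
#' colinear chain of local alignments, so a contig interrupted by a long
#' insertion (a retained intron, say) yields one block per flank rather
#' than losing half of itself. Reverse-complement hits are reoriented.
#' Contigs whose best chain scores below `min_score` are dropped (an
#' unrelated contig yields no block).
#'
#' @param contigs named character vector of contig sequences.
#' @param reference_cds reference CDS (transcription orientation).
#' @param min_score minimum local alignment score per block (default 60,
#'   i.e. a 30-bp exact match).
#' @return list of alignment blocks, sorted by reference start; each block
#'   has `contig_id`, `strand`, `score`, `identity`, `q_start`, `q_end`,
#'   `r_start`, `r_end` (0-based half-open, query coordinates on the
#'   oriented contig), `q_aln`, `r_aln`, `q_seq` (the oriented contig).
#' @export
map_contigs <- function(contigs, reference_cds, min_score = 60) {
  blocks <- list()
  for (id in names(contigs)) {
    chains <- lapply(c("+", "-"), function(strand) {
      oriented <- if (strand == "-") revcomp(contigs[[id]])
                  else contigs[[id]]
      list(strand = strand, oriented = oriented,
           chain = chain_contig(oriented, reference_cds, 0L,
                                nchar(oriented), 0L,
                                nchar(reference_cds), min_score))
    })
    totals <- vapply(chains, function(ch)
      sum(vapply(ch$chain, `[[`, numeric(1), "score"), 0), numeric(1))
    best <- chains[[which.max(totals)]]
    for (blk in best$chain) {
      blocks[[length(blocks) + 1L]] <-
        c(list(contig_id = id, strand = best$strand,
               q_seq = best$oriented), blk)
    }
  }
  blocks[order(vapply(blocks, `[[`, numeric(1), "r_start"))]
}

## Expand a block into per-reference-position cells: cell[i] holds the
## contig bases attached to reference position r_start + i - 1 (the aligned
## base, "" for a deletion, plus any insertion bases that follow it).
block_cells <- function(block) {
  q <- strsplit(block$q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(block$r_aln, "", fixed = TRUE)[[1]]
  n_ref <- block$r_end - block$r_start
  cells <- character(n_ref)
  pos <- 0L
  for (i in seq_along(q)) {
    if (r[i] != "-") {
      pos <- pos + 1L
      cells[pos] <- if (q[i] == "-") "" else q[i]
    } else if (pos >= 1L) {
      cells[pos] <- paste0(cells[pos], q[i])
    }
  }
  cells
}

#' Stitch mapped contigs into a reference-ordered transcript scaffold
#'
#' Contig bases are placed at their reference-projected positions
#' (insertions relative to the reference stay attached to the preceding
#' reference base, so planted indels survive stitching). Reference spans no
#' contig covers become runs of `N`. Where two contigs overlap and
#' disagree at a position, the base from the block with higher alignment
#' identity wins; an identity tie yields `N`. Overlapping contigs that
#' disagree over more than 20% of their shared span raise a conflict
#' error.
#'
#' @param blocks alignment blocks from [map_contigs()].
#' @param reference_cds the reference CDS the blocks were mapped to.
#' @param reference_id identifier recorded on the scaffold.
#' @return a `scaffolded_transcript`: list with `reference_id`, `sequence`,
#'   `provenance` (one tag per base: `contig:<id>`, `read_extended:<i>` or
#'   `gap`), `gaps` (data.frame `ref_start`, `ref_end`, 0-based half-open
#'   reference coordinates), and `ref_len`.
#' @export
stitch <- function(blocks, reference_cds, reference_id = "reference") {
  L <- nchar(reference_cds)
  content <- rep(NA_character_, L)
  source_id <- rep(NA_character_, L)
  source_identity <- rep(-Inf, L)
  covered_by <- vector("list", L)
  for (b in blocks) {
    cells <- block_cells(b)
    idx <- seq.int(b$r_start + 1L, b$r_end)
    for (j in seq_along(idx)) {
      i <- idx[j]
      covered_by[[i]] <- c(covered_by[[i]],
                           stats::setNames(list(cells[j]), b$contig_id))
      if (is.na(content[i])) {
        content[i] <- cells[j]
        source_id[i] <- b$contig_id
        source_identity[i] <- b$identity
      } else if (!identical(content[i], cells[j])) {
        if (b$identity > source_identity[i]) {
          content[i] <- cells[j]
          source_id[i] <- b$contig_id
          source_identity[i] <- b$identity
        } else if (b$identity == source_identity[i]) {
          content[i] <- "N"
          source_id[i] <- b$contig_id
        }
      }
    }
  }
  ## bridge same-contig block pairs: contig bases between two colinear
  ## blocks of one contig (e.g. a retained intron the aligner jumped) are
  ## attached as an insertion at the upstream block's last reference
  ## position, provided the blocks (nearly) abut on the reference
  by_contig <- split(seq_along(blocks),
                     vapply(blocks, `[[`, character(1), "contig_id"))
  for (idx in by_contig) {
    if (length(idx) < 2L) next
    idx <- idx[order(vapply(blocks[idx], `[[`, numeric(1), "q_start"))]
    for (k in seq_len(length(idx) - 1L)) {
      b1 <- blocks[[idx[k]]]
      b2 <- blocks[[idx[k + 1L]]]
      q_gap <- b2$q_start - b1$q_end
      r_gap <- b2$r_start - b1$r_end
      if (q_gap > 0L && r_gap >= 0L && r_gap <= 5L && b1$r_end >= 1L) {
        ins <- substring(b1$q_seq, b1$q_end + 1L, b2$q_start)
        i <- b1$r_end                    # cell of ref position r_end - 1
        if (!is.na(content[i])) {
          content[i] <- paste0(content[i], ins)
        }
      }
    }
  }
  ## terminal soft-clip rescue: the local aligner trims diverged contig
  ## ends; at the transcript termini read coverage is too thin to refill
  ## them, so clipped bases are projected one-to-one onto the flanking
  ## reference positions -- but only at the termini, only into positions no
  ## aligned block covers, capped at 40 bp, and only when they agree with
  ## the reference well enough (>= 40% matches) to be a substitution run
  ## rather than foreign sequence (e.g. a clipped-through intron).
  if (length(blocks) > 0L) {
    rescue <- function(ref_pos0, chars, contig_id) {
      # ref_pos0: 0-based ref position of chars[1]
      refc <- strsplit(substring(reference_cds, ref_pos0 + 1L,
                                 ref_pos0 + length(chars)), "",
                       fixed = TRUE)[[1]]
      if (mean(chars == refc) < 0.4) return(invisible(NULL))
      for (k in seq_along(chars)) {
        i <- ref_pos0 + k
        if (is.na(content[i])) {
          content[i] <<- chars[k]
          source_id[i] <<- contig_id
          source_identity[i] <<- 0
        }
      }
    }
    b1 <- blocks[[which.min(vapply(blocks, `[[`, numeric(1), "r_start"))]]
    n <- min(b1$q_start, b1$r_start, 40L)
    if (n > 0L) {
      rescue(b1$r_start - n,
             strsplit(substring(b1$q_seq, b1$q_start - n + 1L,
                                b1$q_start), "", fixed = TRUE)[[1]],
             b1$contig_id)
    }
    b2 <- blocks[[which.max(vapply(blocks, `[[`, numeric(1), "r_end"))]]
    n <- min(nchar(b2$q_seq) - b2$q_end, L - b2$r_end, 40L)
    if (n > 0L) {
      rescue(b2$r_end,
             strsplit(substring(b2$q_seq, b2$q_end + 1L, b2$q_end + n),
                      "", fixed = TRUE)[[1]],
             b2$contig_id)
    }
  }
  ## pairwise conflict check over shared spans
  ids <- vapply(blocks, `[[`, character(1), "contig_id")
  all_cells <- lapply(blocks, block_cells)
  for (a in seq_along(blocks)) {
    for (b in seq_along(blocks)) {
      if (b <= a) next
      sa <- blocks[[a]]$r_start; ea <- blocks[[a]]$r_end
      sb <- blocks[[b]]$r_start; eb <- blocks[[b]]$r_end
      lo <- max(sa, sb)
      hi <- min(ea, eb)
      if (hi - lo < 10L) next
      ca <- all_cells[[a]][(lo - sa + 1L):(hi - sa)]
      cb <- all_cells[[b]][(lo - sb + 1L):(hi - sb)]
      dis <- which(ca != cb)
      if (length(dis) > 0.2 * (hi - lo)) {
        stop("contigs ", ids[a], " and ", ids[b],
             " disagree over >20% of their overlap (reference positions ",
             paste(utils::head(lo + dis - 1L, 10L), collapse = ", "),
             if (length(dis) > 10L) ", ..." else "", ")")
      }
    }
  }
  uncovered <- is.na(content)
  content[uncovered] <- "N"
  pieces <- content
  prov_tag <- ifelse(uncovered, "gap", paste0("contig:", source_id))
  prov <- rep(prov_tag, nchar(pieces))
  sequence <- paste(pieces, collapse = "")
  runs <- rle(uncovered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gap_runs <- which(runs$values)
  gaps <- data.frame(ref_start = starts[gap_runs] - 1L,
                     ref_end = ends[gap_runs])
  structure(list(reference_id = reference_id, sequence = sequence,
                 provenance = prov, gaps = gaps, ref_len = L),
            class = "scaffolded_transcript")
}

#' @export
print.scaffolded_transcript <- function(x, ...) {
  cat(sprintf("scaffolded_transcript vs %s: %d bp, %d gap(s) (%d N)\n",
              x$reference_id, nchar(x$sequence), nrow(x$gaps),
              sum(x$provenance == "gap")))
  invisible(x)
}

## Majority-consensus extension from an exact seed match in the read pool.
## direction "right": consensus of read suffixes after the seed;
## "left": consensus of read prefixes before it, built outward.
consensus_extension <- function(seed, reads, min_support, direction = "right") {
  hits <- reads[grepl(seed, reads, fixed = TRUE)]
  if (length(hits) < min_support) return("")
  pos <- regexpr(seed, hits, fixed = TRUE)
  tails <- if (direction == "right") {
    substring(hits, pos + nchar(seed))
  } else {
    vapply(seq_along(hits), function(i) {
      s <- substring(hits[i], 1L, pos[i] - 1L)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1))
  }
  tails <- tails[nzchar(tails)]
  if (length(tails) < min_support) return("")
  out <- character(0)
  for (j in seq_len(max(nchar(tails)))) {
    bases <- substring(tails[nchar(tails) >= j], j, j)
    tab <- sort(table(bases), decreasing = TRUE)
    if (tab[1] < min_support) break
    if (length(tab) > 1L && tab[2] == tab[1]) break   # consensus tie halts
    out <- c(out, names(tab)[1])
  }
  s <- paste(out, collapse = "")
  if (direction == "left") {
    s <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }
  s
}

## attempt to close one gap; ctx_left/ctx_right may be "" at transcript ends
fill_one_gap <- function(ctx_left, ctx_right, run_len, reads, seed_len,
                         min_read_support, max_iterations, both_flanks) {
  left_ext <- character(0)   # per-base vector, iteration tag parallel
  left_it <- integer(0)
  right_ext <- character(0)
  right_it <- integer(0)
  closed <- FALSE
  fill <- NULL
  fill_it <- NULL
  try_close <- function() {
    Lfull <- paste0(ctx_left, paste(left_ext, collapse = ""))
    Rfull <- paste0(paste(right_ext, collapse = ""), ctx_right)
    nL <- nchar(Lfull)
    if (!nzchar(ctx_left) || !nzchar(ctx_right)) {
      ## terminal gap: one flank only; close once run_len bases recovered
      if (!nzchar(ctx_right)) {
        if (length(left_ext) >= run_len) {
          return(list(fill = left_ext[seq_len(run_len)],
                      it = left_it[seq_len(run_len)]))
        }
      } else {
        if (length(right_ext) >= run_len) {
          k <- length(right_ext)
          return(list(fill = right_ext[(k - run_len + 1L):k],
                      it = right_it[(k - run_len + 1L):k]))
        }
      }
      return(NULL)
    }
    if (length(left_ext) + length(right_ext) == 0L) return(NULL)
    if (nL < seed_len) return(NULL)
    probe <- substring(Lfull, nL - seed_len + 1L, nL)
    if (grepl("N", probe, fixed = TRUE)) return(NULL)
    p <- regexpr(probe, Rfull, fixed = TRUE)[1]
    if (p < 1L) return(NULL)
    ## converging extensions must agree over their whole overlap
    k <- min(p - 1L, nL - seed_len)
    if (k > 0L &&
        substring(Rfull, p - k, p - 1L) !=
        substring(Lfull, nL - seed_len - k + 1L, nL - seed_len)) {
      return(NULL)
    }
    merged <- paste0(Lfull, substring(Rfull, p + seed_len))
    fill_len <- nchar(merged) - nchar(ctx_left) - nchar(ctx_right)
    if (fill_len < 0L) return(NULL)
    if (fill_len == 0L) return(list(fill = character(0), it = integer(0)))
    f <- strsplit(substring(merged, nchar(ctx_left) + 1L,
                            nchar(ctx_left) + fill_len), "",
                  fixed = TRUE)[[1]]
    ## iteration tags: left part from left_it, remainder from the right side
    nl <- min(length(left_ext), fill_len)
    its <- c(left_it[seq_len(nl)],
             rep(max(c(left_it, right_it, 1L)), fill_len - nl))
    list(fill = f, it = its)
  }
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    progressed <- FALSE
    if (nzchar(ctx_left)) {
      Lfull <- paste0(ctx_left, paste(left_ext, collapse = ""))
      nL <- nchar(Lfull)
      if (nL >= seed_len) {
        seed <- substring(Lfull, nL - seed_len + 1L, nL)
        if (!grepl("N", seed, fixed = TRUE)) {
          ext <- consensus_extension(seed, reads, min_read_support, "right")
          if (nzchar(ext)) {
            eb <- strsplit(ext, "", fixed = TRUE)[[1]]
            left_ext <- c(left_ext, eb)
            left_it <- c(left_it, rep(it, length(eb)))
            progressed <- TRUE
          }
        }
      }
    }
    iterations <- it
    res <- try_close()
    if (!is.null(res)) {
      closed <- TRUE; fill <- res$fill; fill_it <- res$it
      break
    }
    if (both_flanks && nzchar(ctx_right)) {
      Rfull <- paste0(paste(right_ext, collapse = ""), ctx_right)
      if (nchar(Rfull) >= seed_len) {
        seed <- substring(Rfull, 1L, seed_len)
        if (!grepl("N", seed, fixed = TRUE)) {
          ext <- consensus_extension(seed, reads, min_read_support, "left")
          if (nzchar(ext)) {
            eb <- strsplit(ext, "", fixed = TRUE)[[1]]
            right_ext <- c(eb, right_ext)
            right_it <- c(rep(it, length(eb)), right_it)
            progressed <- TRUE
          }
        }
      }
      res <- try_close()
      if (!is.null(res)) {
        closed <- TRUE; fill <- res$fill; fill_it <- res$it
        break
      }
    }
    if (!progressed) break
  }
  list(closed = closed, fill = fill, fill_it = fill_it,
       iterations = iterations,
       bases_added = if (closed) length(fill)
                     else length(left_ext) + length(right_ext))
}

#' Fill scaffold gaps by iterative exact-match read extension
#'
#' The "grep"-style gap filler: per gap and per iteration, the terminal
#' `seed_len` bases of the left (then right) flank are used as an exact-
#' match seed into the read pool; matching reads are extended inward by
#' strict-majority consensus wherever at least `min_read_support` reads
#' agree (a support tie halts that gap — ambiguity is reported, never
#' guessed). A gap closes when the converging extensions overlap exactly
#' over at least `seed_len` bases; gaps at the transcript ends close when
#' the single flank has recovered the full gap length. Non-gap bases are
#' never modified.
#'
#' @param scaffold a `scaffolded_transcript` from [stitch()].
#' @param reads character vector of reads (e.g. both mates pooled).
#' @param seed_len exact-match seed length (default 25).
#' @param min_read_support minimum agreeing reads per consensus base
#'   (default 2).
#' @param max_iterations maximum extension iterations per gap (default 10).
#' @param both_strands also search the reverse complement of every read
#'   (default `TRUE`).
#' @param both_flanks extend inward from both flanks (default `TRUE`);
#'   `FALSE` restricts to left-to-right extension.
#' @return the scaffold with filled gaps and a `fill_report` attribute /
#'   element: data.frame with one row per gap (`ref_start`, `ref_end`,
#'   `closed`, `iterations`, `bases_added`).
#' @export
grep_extend <- function(scaffold, reads, seed_len = 25L,
                        min_read_support = 2L, max_iterations = 10L,
                        both_strands = TRUE, both_flanks = TRUE) {
  stopifnot(inherits(scaffold, "scaffolded_transcript"),
            seed_len >= 8L, min_read_support >= 1L)
  pool <- unname(reads)
  if (both_strands) pool <- c(pool, revcomp(pool))
  chars <- strsplit(scaffold$sequence, "", fixed = TRUE)[[1]]
  prov <- scaffold$provenance
  is_gap <- prov == "gap"
  runs <- rle(is_gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gi <- which(runs$values)
  report <- scaffold$gaps
  if (nrow(report) == 0L) {
    scaffold$fill_report <- cbind(report, closed = logical(0),
                                  iterations = integer(0),
                                  bases_added = integer(0))
    return(scaffold)
  }
  report$closed <- FALSE
  report$iterations <- 0L
  report$bases_added <- 0L
  ## process gaps right-to-left so earlier coordinates stay valid
  for (ri in rev(seq_along(gi))) {
    g <- gi[ri]
    s <- starts[g]; e <- ends[g]
    left_all <- if (s > 1L) paste(chars[1:(s - 1L)], collapse = "") else ""
    right_all <- if (e < length(chars))
      paste(chars[(e + 1L):length(chars)], collapse = "") else ""
    ## flank context: trimmed at the nearest N so seeds stay exact
    trim_left <- sub(".*N", "", left_all)
    trim_right <- sub("N.*", "", right_all)
    ctx_left <- substring(trim_left, max(1L, nchar(trim_left) - 299L))
    ctx_right <- substring(trim_right, 1L, 300L)
    res <- fill_one_gap(ctx_left, ctx_right, e - s + 1L, pool, seed_len,
                        min_read_support, max_iterations, both_flanks)
    report$iterations[ri] <- res$iterations
    report$bases_added[ri] <- res$bases_added
    if (res$closed) {
      report$closed[ri] <- TRUE
      chars <- c(if (s > 1L) chars[1:(s - 1L)], res$fill,
                 if (e < length(chars)) chars[(e + 1L):length(chars)])
      prov <- c(if (s > 1L) prov[1:(s - 1L)],
                paste0("read_extended:", res$fill_it),
                if (e < length(prov)) prov[(e + 1L):length(prov)])
    }
  }
  scaffold$sequence <- paste(chars, collapse = "")
  scaffold$provenance <- prov
  scaffold$gaps <- scaffold$gaps[!report$closed, , drop = FALSE]
  scaffold$fill_report <- report
  scaffold
}

#' Finalize a reconstructed CDS against its reference
#'
#' The reconstructed sequence is globally aligned to the reference CDS and
#' trimmed to the span matching the reference start codon through terminal
#' stop (internal insertions are kept, so planted events survive). The
#' translation and global identities versus the reference CDS and peptide
#' are reported; a missing ATG or remaining gaps flag the result as
#' partial rather than silently trimming further.
#'
#' @param x a `scaffolded_transcript` or a plain sequence string.
#' @param reference_cds reference CDS.
#' @return list with `cds`, `peptide` (up to the first stop), `full_translation`,
#'   `identity_cds`, `identity_pep`, `premature_stop`, `partial`,
#'   `has_start`, `ref_peptide`.
#' @export
finalize <- function(x, reference_cds) {
  seq <- if (inherits(x, "scaffolded_transcript")) x$sequence else x
  partial <- grepl("N", seq, fixed = TRUE)
  al <- align_dna(seq, reference_cds, type = "global", gap_open = 20)
  q <- strsplit(al$q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(al$r_aln, "", fixed = TRUE)[[1]]
  ref_cols <- which(r != "-")
  first_col <- ref_cols[1]
  last_col <- ref_cols[length(ref_cols)]
  keep <- q[first_col:last_col]
  cds <- paste(keep[keep != "-"], collapse = "")
  has_start <- startsWith(cds, "ATG")
  if (!has_start) partial <- TRUE
  full_tr <- translate_cds(cds)
  stop_at <- regexpr("*", full_tr, fixed = TRUE)[1]
  n_aa <- nchar(full_tr)
  premature <- stop_at > 0L && stop_at < n_aa
  peptide <- if (stop_at > 0L) substring(full_tr, 1L, stop_at - 1L)
             else full_tr
  ref_pep <- sub("\\*$", "", translate_cds(reference_cds))
  trim_al <- align_dna(cds, reference_cds, type = "global", gap_open = 20)
  id_pep <- if (nzchar(peptide))
    align_protein(peptide, ref_pep, type = "global")$identity else 0
  list(cds = cds, peptide = peptide, full_translation = full_tr,
       identity_cds = trim_al$identity, identity_pep = id_pep,
       premature_stop = premature, partial = partial,
       has_start = has_start, ref_peptide = ref_pep)
}

## recursive colinear chaining of local alignments (exon discovery)
chain_blocks <- function(query, scaf, q_lo, q_hi, s_lo, s_hi, min_score) {
  if (q_hi - q_lo < 20L || s_hi - s_lo < 20L) return(list())
  al <- align_dna(substring(query, q_lo + 1L, q_hi),
                  substring(scaf, s_lo + 1L, s_hi), type = "local")
  if (al$score < min_score) return(list())
  segs <- Filter(function(s) s$score >= 20, decompose_block(al, q_lo, s_lo))
  if (length(segs) == 0L) return(list())
  first <- segs[[1L]]
  last <- segs[[length(segs)]]
  c(chain_blocks(query, scaf, q_lo, first$q_start, s_lo, first$s_start,
                 min_score),
    segs,
    chain_blocks(query, scaf, last$q_end, q_hi, last$s_end, s_hi,
                 min_score))
}

## Split one local alignment into exon-like segments at genome-only gap
## runs of at least `min_intron` bp (the affine aligner happily jumps a
## short intron with a single deletion gap; each side of such a gap is its
## own candidate exon). Segment scores use the package scoring scheme.
decompose_block <- function(al, q_lo, s_lo, min_intron = 20L) {
  q <- strsplit(al$q_aln, "", fixed = TRUE)[[1]]
  r <- strsplit(al$r_aln, "", fixed = TRUE)[[1]]
  qpos <- q_lo + al$q_start
  spos <- s_lo + al$r_start
  segs <- list()
  cur <- NULL
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (q[i] == "-") {
      j <- i
      while (j <= n && q[j] == "-") j <- j + 1L
      runlen <- j - i
      if (runlen >= min_intron) {
        if (!is.null(cur)) { segs[[length(segs) + 1L]] <- cur; cur <- NULL }
      } else if (!is.null(cur)) {
        cur$score <- cur$score - 5 - 2 * runlen
      }
      spos <- spos + runlen
      i <- j
    } else if (r[i] == "-") {
      j <- i
      while (j <= n && r[j] == "-") j <- j + 1L
      if (!is.null(cur)) cur$score <- cur$score - 5 - 2 * (j - i)
      qpos <- qpos + (j - i)
      i <- j
    } else {
      if (is.null(cur)) {
        cur <- list(q_start = qpos, s_start = spos, score = 0)
      }
      cur$score <- cur$score + if (q[i] == r[i]) 2 else -3
      qpos <- qpos + 1L
      spos <- spos + 1L
      cur$q_end <- qpos
      cur$s_end <- spos
      i <- i + 1L
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
  segs
}

#' Recover an unannotated gene locus from genomic scaffolds
#'
#' A translated-search-style recovery: the query CDS is chained against
#' every scaffold on both strands as colinear local alignments (candidate
#' exons), interior exon boundaries are snapped to the nearest GT..AG
#' intron dinucleotides within `snap_window` bp, and the coding frame is
#' chosen as the six-frame translation of the spliced exons that best
#' aligns to the query peptide.
#'
#' @param query_cds query coding sequence.
#' @param genome named character vector of scaffolds.
#' @param query_peptide optional query peptide (defaults to the translated
#'   query CDS).
#' @param min_block_score minimum per-exon local alignment score.
#' @param min_total_score report not-found below this total score
#'   (distinguishes true absence from a poor hit).
#' @param snap_window splice-site snap window in bp (default 10).
#' @return list with `found`; when found also `scaffold`, `strand`,
#'   `exons` (data.frame of 0-based half-open forward-scaffold intervals,
#'   rows in transcription order), `cds`, `frame`, `score`, `identity`.
#' @export
genome_recover <- function(query_cds, genome, query_peptide = NULL,
                           min_block_score = 60, min_total_score = 100,
                           snap_window = 10L) {
  if (is.null(query_peptide)) {
    query_peptide <- sub("\\*$", "", translate_cds(query_cds))
  }
  best <- NULL
  for (scaf_id in names(genome)) {
    for (strand in c("+", "-")) {
      scaf <- if (strand == "+") genome[[scaf_id]]
              else revcomp(genome[[scaf_id]])
      blocks <- chain_blocks(query_cds, scaf, 0L, nchar(query_cds), 0L,
                             nchar(scaf), min_block_score)
      if (length(blocks) == 0L) next
      total <- sum(vapply(blocks, `[[`, numeric(1), "score"))
      if (is.null(best) || total > best$total) {
        best <- list(scaf_id = scaf_id, strand = strand, scaf = scaf,
                     blocks = blocks, total = total)
      }
    }
  }
  if (is.null(best) || best$total < min_total_score) {
    return(list(found = FALSE))
  }
  blocks <- best$blocks[order(vapply(best$blocks, `[[`, numeric(1),
                                     "q_start"))]
  scaf <- best$scaf
  ## Snap interior boundaries to GT..AG. The two ends of one intron are
  ## snapped jointly under the query-contiguity constraint (shifting the
  ## donor by d shifts the acceptor by d minus any query overlap/gap
  ## between the segments), so exon bases that the aligner parked at the
  ## wrong end of the intron return to their exon.
  win <- seq(-snap_window, snap_window)
  win <- win[order(abs(win))]
  if (length(blocks) > 1L) {
    for (i in seq_len(length(blocks) - 1L)) {
      e1 <- blocks[[i]]$s_end        # 0-based: intron starts here
      s2 <- blocks[[i + 1L]]$s_start # 0-based: intron ends just before
      o <- blocks[[i + 1L]]$q_start - blocks[[i]]$q_end
      snapped <- FALSE
      for (d1 in win) {
        d2 <- d1 - o
        if (abs(d2) > snap_window) next
        if (substring(scaf, e1 + d1 + 1L, e1 + d1 + 2L) == "GT" &&
            substring(scaf, s2 + d2 - 1L, s2 + d2) == "AG" &&
            s2 + d2 > e1 + d1 + 4L) {
          blocks[[i]]$s_end <- e1 + d1
          blocks[[i + 1L]]$s_start <- s2 + d2
          snapped <- TRUE
          break
        }
      }
      if (!snapped) {
        ## fall back to independent snapping of each end
        for (d1 in win) {
          if (substring(scaf, e1 + d1 + 1L, e1 + d1 + 2L) == "GT") {
            blocks[[i]]$s_end <- e1 + d1
            break
          }
        }
        for (d2 in win) {
          if (substring(scaf, s2 + d2 - 1L, s2 + d2) == "AG") {
            blocks[[i + 1L]]$s_start <- s2 + d2
            break
          }
        }
      }
    }
  }
  exon_seqs <- vapply(blocks, function(b)
    substring(scaf, b$s_start + 1L, b$s_end), character(1))
  cds <- paste(exon_seqs, collapse = "")
  ## six-frame translation: pick the frame that best matches the peptide
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  scores <- vapply(frames, function(f) {
    s <- if (f > 0) cds else revcomp(cds)
    tr <- translate_cds(substring(s, abs(f)))
    if (nchar(tr) < 5L) return(-Inf)
    align_protein(tr, query_peptide)$score
  }, numeric(1))
  frame <- frames[which.max(scores)]
  ## report exon intervals on the forward scaffold, transcription order
  slen <- nchar(genome[[best$scaf_id]])
  exons <- do.call(rbind, lapply(blocks, function(b) {
    if (best$strand == "+") data.frame(start = b$s_start, end = b$s_end)
    else data.frame(start = slen - b$s_end, end = slen - b$s_start)
  }))
  idal <- align_dna(cds, query_cds, type = "global")
  list(found = TRUE, scaffold = best$scaf_id, strand = best$strand,
       exons = exons, cds = cds, frame = frame, score = best$total,
       identity = idal$identity)
}
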