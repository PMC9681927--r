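## Synthetic-data generators.
##
## Everything the downstream stages consume can be generated here with
## machine-readable ground truth: multi-exon gene models on scaffolds,
## diverged ortholog transcripts with planted indels / retained introns,
## fragmented contigs with an internal assembly gap, short reads, and
## negative-binomial count matrices with cluster archetypes and planted
## outlier libraries. All generators are pure functions of their arguments:
## the same seed gives byte-identical artifacts, and the caller's RNG state
## is left untouched.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

## sample() treats a scalar first argument as 1:x; guard degenerate ranges
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(as.integer(lo), as.integer(hi)), n, replace = TRUE)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

## CDS = ATG + sense codons + one stop; length must be divisible by 3
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste0("ATG",
         paste(sample(SENSE_CODONS, len / 3L - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

random_intron <- function(len) {
  stopifnot(len >= 4L)
  paste0("GT", random_dna(len - 4L), "AG")
}

#' Simulate multi-exon gene models on genomic scaffolds
#'
#' Each gene gets its own scaffold: flanking sequence, exons carrying a valid
#' CDS (ATG start, single terminal stop, length divisible by 3) and GT..AG
#' introns. Strand is drawn at random unless fixed.
#'
#' @param n_genes number of genes.
#' @param exon_count_range integer pair, inclusive range of exons per gene.
#' @param exon_len_range integer pair (bp); the range must span at least 3 bp
#'   so a total CDS length divisible by 3 is always reachable.
#' @param intron_len_range integer pair (bp), minimum 10.
#' @param flank scaffold flank length either side of the gene (bp).
#' @param strand `"random"`, `"+"` or `"-"`.
#' @param seed RNG seed; fixes all randomness.
#' @param dir optional directory; when given, `genome.fa` and `models.gff3`
#'   are written there.
#' @return list with `genome` (named character vector of scaffolds), `models`
#'   (named list of [gene_model()]), and `truth` (per-gene exon/intron
#'   lengths and strand).
#' @export
simulate_gene_models <- function(n_genes = 20L,
                                 exon_count_range = c(7L, 12L),
                                 exon_len_range = c(90L, 300L),
                                 intron_len_range = c(80L, 800L),
                                 flank = 300L,
                                 strand = "random",
                                 seed = 1L,
                                 dir = NULL) {
  stopifnot(n_genes >= 1L, length(exon_count_range) == 2L,
            exon_count_range[1] >= 1L,
            exon_count_range[2] >= exon_count_range[1],
            exon_len_range[2] >= exon_len_range[1],
            exon_len_range[1] >= 12L,
            intron_len_range[1] >= 10L,
            intron_len_range[2] >= intron_len_range[1])
  if (exon_len_range[2] - exon_len_range[1] < 3L &&
      sum(exon_len_range) %% 1L == 0L) {
    # a span < 3 cannot always absorb the mod-3 residue in the last exon
    if (exon_len_range[2] - exon_len_range[1] < 2L) {
      stop("exon_len_range too narrow to guarantee a CDS length divisible by 3")
    }
  }
  with_seed(seed, {
    genome <- character(0)
    models <- list()
    truth <- list()
    for (i in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", i)
      scaf <- sprintf("scaf%03d", i)
      n_ex <- if (exon_count_range[1] == exon_count_range[2])
        exon_count_range[1] else
        sample(seq(exon_count_range[1], exon_count_range[2]), 1L)
      lens <- if (n_ex > 1L)
        sample_range(exon_len_range[1], exon_len_range[2], n_ex - 1L)
        else integer(0)
      # last exon length chosen so the CDS length is divisible by 3
      cand <- seq(exon_len_range[1], exon_len_range[2])
      cand <- cand[(sum(lens) + cand) %% 3L == 0L]
      if (length(cand) == 0L) {
        stop("exon length ranges cannot produce a CDS divisible by 3")
      }
      lens <- c(lens, if (length(cand) == 1L) cand else sample(cand, 1L))
      cds <- random_cds(sum(lens))
      ilens <- if (n_ex > 1L)
        sample_range(intron_len_range[1], intron_len_range[2], n_ex - 1L)
        else integer(0)
      introns <- vapply(ilens, random_intron, character(1))
      # gene region in transcription orientation
      ends <- cumsum(lens)
      starts <- c(0L, ends[-n_ex])
      exon_seqs <- substring(cds, starts + 1L, ends)
      region <- paste(as.vector(rbind(exon_seqs, c(introns, ""))),
                      collapse = "")
      str <- if (strand == "random") sample(c("+", "-"), 1L) else strand
      # transcript-orientation interval of exon k within the region
      reg_starts <- starts + c(0L, cumsum(ilens))[seq_len(n_ex)]
      reg_ends <- reg_starts + lens
      lr <- nchar(region)
      if (str == "+") {
        scaffold_seq <- paste0(random_dna(flank), region, random_dna(flank))
        ex <- data.frame(start = flank + reg_starts, end = flank + reg_ends)
      } else {
        scaffold_seq <- paste0(random_dna(flank), revcomp(region),
                               random_dna(flank))
        ex <- data.frame(start = flank + lr - reg_ends,
                         end = flank + lr - reg_starts)
      }
      genome[scaf] <- scaffold_seq
      models[[gid]] <- gene_model(gid, scaf, str, ex, cds)
      truth[[gid]] <- list(strand = str, exon_lengths = lens,
                           intron_lengths = ilens)
    }
    out <- list(genome = genome, models = models, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(genome, file.path(dir, "genome.fa"))
      write_gff3(models, file.path(dir, "models.gff3"))
    }
    out
  })
}

## Intron sequence of intron i (transcription orientation) from the genome
intron_sequence <- function(model, genome, i) {
  ex <- model$exons
  scaf <- genome[[model$scaffold]]
  if (model$strand == "+") {
    substring(scaf, ex$end[i] + 1L, ex$start[i + 1L])
  } else {
    revcomp(substring(scaf, ex$end[i + 1L] + 1L, ex$start[i]))
  }
}

#' Specify a sequence event to plant in a simulated ortholog
#'
#' @param kind `"insertion"`, `"deletion"` or `"retained_intron"`.
#' @param exon exon index (insertions/deletions).
#' @param intron intron index (retained introns).
#' @param length event length in bp (for retained introns the annotated
#'   intron length is used).
#' @param stop_free for insertions: sample the inserted sequence without
#'   in-frame stop codons (default `FALSE`; stops are allowed so that
#'   premature-stop detection is exercised).
#' @return an `event_spec` list.
#' @export
event_spec <- function(kind, exon = NULL, intron = NULL, length = NULL,
                       stop_free = FALSE) {
  kind <- match.arg(kind, c("insertion", "deletion", "retained_intron"))
  if (kind == "retained_intron") stopifnot(!is.null(intron))
  else stopifnot(!is.null(exon), !is.null(length), length >= 1L)
  structure(list(kind = kind, exon = exon, intron = intron, length = length,
                 stop_free = stop_free), class = "event_spec")
}

#' Simulate a diverged ortholog transcript with planted events and
#' assembly fragmentation
#'
#' Starting from a reference gene model's CDS, substitutions are applied
#' i.i.d. at the configured rate — only outside planted-event footprints,
#' never in the first or last codon, and never converting a sense codon of
#' the reference frame into a stop (so the only premature stops in the
#' mutant are consequences of planted events). Planted insertions, deletions
#' and retained introns are then applied, and the mutant transcript is
#' fragmented into contigs whose union misses exactly one internal gap
#' interval. Breakpoints keep at least 25 bp away from planted events so
#' event detection is attributable to the scanner, not the stitcher.
#'
#' @param model reference [gene_model()].
#' @param genome named scaffold vector (needed for retained introns; the
#'   annotated intron sequence is inserted at its junction).
#' @param divergence per-base substitution probability in `[0, 1)`.
#' @param events list of [event_spec()] objects.
#' @param n_contigs number of contigs after fragmentation (1 = no gap).
#' @param gap_len length of the internal gap (bp, mutant coordinates).
#' @param min_contig minimum fragment length (default 200 bp, the usual
#'   assembler minimum reported contig length).
#' @param rc_contigs reverse-complement each contig with probability 1/2.
#' @param seed RNG seed.
#' @return list with `transcript` (the mutant), `contigs` (named character
#'   vector), `events` (data.frame: `kind`, `ref_pos` = 0-based reference
#'   CDS coordinate of the base preceding the event run, `length`,
#'   `frame_offset`, `index` = exon or intron index, `seq`), `gap_mutant`
#'   and `gap_ref` (0-based half-open intervals), `breakpoints`, and
#'   `contig_rc` (logical, per contig).
#' @export
simulate_ortholog <- function(model, genome = NULL, divergence = 0.15,
                              events = list(), n_contigs = 3L,
                              gap_len = 120L, min_contig = 200L,
                              rc_contigs = TRUE, seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1, n_contigs >= 1L)
  ref <- model$cds
  L <- nchar(ref)
  junc <- gene_model_junctions(model)
  ex_ends <- cumsum(model$exons$end - model$exons$start)
  ex_starts <- c(0L, ex_ends[-length(ex_ends)])
  with_seed(seed, {
    ## resolve event coordinates on the reference CDS
    ev <- list()
    for (e in events) {
      if (e$kind == "retained_intron") {
        i <- e$intron
        if (i < 1L || i > nrow(junc)) stop("no such intron: ", i)
        p <- junc$cds_pos[i]
        iseq <- if (!is.null(genome)) intron_sequence(model, genome, i)
                else random_intron(junc$length[i])
        ev[[length(ev) + 1L]] <- list(kind = "retained_intron", p = p,
                                      length = nchar(iseq), index = i,
                                      seq = iseq)
      } else {
        k <- e$exon
        if (k < 1L || k > length(ex_ends)) stop("no such exon: ", k)
        lo <- ex_starts[k] + 5L
        hi <- ex_ends[k] - 5L - if (e$kind == "deletion") e$length else 0L
        lo <- max(lo, 4L)                       # keep the start codon intact
        hi <- min(hi, L - 4L - if (e$kind == "deletion") e$length else 0L)
        if (hi < lo) stop("exon ", k, " too short for a ", e$length,
                          "-bp ", e$kind)
        p <- if (hi == lo) lo else sample(seq(lo, hi), 1L)
        sq <- if (e$kind == "insertion") {
          s <- random_dna(e$length)
          if (e$stop_free) {
            while (grepl("TAA|TAG|TGA", s)) s <- random_dna(e$length)
          }
          s
        } else substring(ref, p + 1L, p + e$length)
        ev[[length(ev) + 1L]] <- list(kind = e$kind, p = p,
                                      length = e$length, index = k, seq = sq)
      }
    }
    ord <- order(vapply(ev, `[[`, numeric(1), "p"))
    ev <- ev[ord]
    ## substitution footprints to protect (reference coords)
    protect <- rep(FALSE, L)
    protect[1:3] <- TRUE
    protect[(L - 2L):L] <- TRUE
    for (e in ev) {
      if (e$kind == "deletion") {
        protect[(e$p + 1L):(e$p + e$length)] <- TRUE
      } else {
        protect[max(1L, e$p):min(L, e$p + 1L)] <- TRUE
      }
    }
    mut <- strsplit(ref, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(L) < divergence & !protect)
    for (pos in hit) {
      orig <- mut[pos]
      alts <- sample(setdiff(c("A", "C", "G", "T"), orig))
      cs <- ((pos - 1L) %/% 3L) * 3L + 1L       # codon start, reference frame
      for (a in alts) {
        mut[pos] <- a
        if (!paste(mut[cs:(cs + 2L)], collapse = "") %in% STOP_CODONS) break
        mut[pos] <- orig
      }
    }
    subbed <- paste(mut, collapse = "")
    ## apply events, descending reference position
    transcript <- subbed
    for (e in rev(ev)) {
      if (e$kind == "deletion") {
        transcript <- paste0(substring(transcript, 1L, e$p),
                             substring(transcript, e$p + e$length + 1L))
      } else {
        transcript <- paste0(substring(transcript, 1L, e$p), e$seq,
                             substring(transcript, e$p + 1L))
      }
    }
    Lm <- nchar(transcript)
    ## mutant-coordinate footprints of events (ascending, with running offset)
    off <- 0L
    zones <- list()
    for (e in ev) {
      if (e$kind == "deletion") {
        zones[[length(zones) + 1L]] <- c(e$p + off, e$p + off + 1L)
        off <- off - e$length
      } else {
        zones[[length(zones) + 1L]] <- c(e$p + off, e$p + off + e$length)
        off <- off + e$length
      }
    }
    forbid <- rep(FALSE, Lm)
    for (z in zones) {
      forbid[max(1L, z[1] - 24L):min(Lm, z[2] + 25L)] <- TRUE
    }
    events_df <- data.frame(
      kind = vapply(ev, `[[`, character(1), "kind"),
      ref_pos = vapply(ev, function(e) e$p - 1L, numeric(1)),
      length = vapply(ev, `[[`, numeric(1), "length"),
      frame_offset = vapply(ev, function(e) e$length %% 3L, numeric(1)),
      index = vapply(ev, `[[`, numeric(1), "index"),
      seq = vapply(ev, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    if (n_contigs == 1L || gap_len == 0L) {
      contigs <- stats::setNames(transcript, paste0(model$gene_id, "_c1"))
      return(list(transcript = transcript, contigs = contigs,
                  events = events_df, gap_mutant = NULL, gap_ref = NULL,
                  breakpoints = integer(0),
                  contig_rc = stats::setNames(FALSE, names(contigs))))
    }
    if (gap_len >= Lm - 2L * min_contig) {
      stop("gap longer than the transcript allows")
    }
    ok <- which(!vapply(seq_len(Lm - gap_len + 1L) - 1L, function(g) {
      g < min_contig || (g + gap_len) > (Lm - min_contig) ||
        any(forbid[(g + 1L):(g + gap_len)])
    }, logical(1)))
    if (length(ok) == 0L) stop("no room for the gap away from planted events")
    g <- (ok[if (length(ok) == 1L) 1L else sample(length(ok), 1L)]) - 0L
    g <- g - 1L  # 0-based gap start
    pieces <- list(c(0L, g), c(g + gap_len, Lm))
    while (length(pieces) < n_contigs) {
      sizes <- vapply(pieces, function(p) p[2] - p[1], numeric(1))
      i <- which.max(sizes)
      p <- pieces[[i]]
      if (p[2] - p[1] < 2L * min_contig) {
        stop("transcript too short to fragment into ", n_contigs,
             " contigs of >= ", min_contig, " bp")
      }
      cand <- seq(p[1] + min_contig, p[2] - min_contig)
      cand <- cand[!forbid[cand + 1L]]
      if (length(cand) == 0L) stop("cannot place a breakpoint away from events")
      b <- cand[if (length(cand) == 1L) 1L else sample(length(cand), 1L)]
      pieces <- append(pieces[-i], list(c(p[1], b), c(b, p[2])), after = i - 1L)
    }
    pieces <- pieces[order(vapply(pieces, `[`, numeric(1), 1L))]
    contigs <- vapply(pieces, function(p)
      substring(transcript, p[1] + 1L, p[2]), character(1))
    names(contigs) <- paste0(model$gene_id, "_c", seq_along(contigs))
    rc <- if (rc_contigs) sample(c(TRUE, FALSE), length(contigs),
                                 replace = TRUE)
          else rep(FALSE, length(contigs))
    contigs[rc] <- revcomp(contigs[rc])
    names(rc) <- names(contigs)
    ## reference coordinates of the gap (no events inside it by construction)
    off_g <- 0L
    for (i in seq_along(ev)) {
      if (zones[[i]][2] <= g) {
        off_g <- off_g + (if (ev[[i]]$kind == "deletion") -ev[[i]]$length
                          else ev[[i]]$length)
      }
    }
    gap_ref <- c(g - off_g, g - off_g + gap_len)
    breakpoints <- vapply(pieces, `[`, numeric(1), 1L)[-1]
    list(transcript = transcript, contigs = contigs, events = events_df,
         gap_mutant = c(g, g + gap_len), gap_ref = gap_ref,
         breakpoints = breakpoints, contig_rc = rc)
  })
}

#' Simulate short reads from a transcript
#'
#' Paired reads come from uniformly placed fixed-length fragments; R1 is the
#' fragment 5' end, R2 the reverse complement of its 3' end, with fragment
#' orientation random. With `error_rate = 0` every read is an exact substring
#' of the transcript or of its reverse complement.
#'
#' @param transcript template sequence.
#' @param read_len read length (bp); must be shorter than the transcript.
#' @param coverage fold coverage (counting both mates).
#' @param error_rate per-base substitution error probability, `< 0.1`.
#' @param insert fragment length (bp), clamped to the transcript length.
#' @param paired if `FALSE`, single-end reads with random strand.
#' @param seed RNG seed.
#' @return for paired mode, a list with named character vectors `r1`, `r2`;
#'   otherwise a single named vector.
#' @export
simulate_reads <- function(transcript, read_len = 100L, coverage = 20,
                           error_rate = 0, insert = 250L, paired = TRUE,
                           seed = 1L) {
  L <- nchar(transcript)
  if (read_len >= L) stop("read_len must be shorter than the transcript")
  if (coverage <= 0) stop("coverage must be positive")
  stopifnot(error_rate >= 0, error_rate < 0.1)
  insert <- max(read_len, min(insert, L))
  add_errors <- function(reads) {
    if (error_rate == 0) return(reads)
    vapply(reads, function(r) {
      b <- strsplit(r, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(b)) < error_rate)
      for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  with_seed(seed, {
    if (paired) {
      n <- max(1L, round(coverage * L / (2 * read_len)))
      starts <- sample.int(L - insert + 1L, n, replace = TRUE) - 1L
      frags <- substring(transcript, starts + 1L, starts + insert)
      flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
      frags[flip] <- revcomp(frags[flip])
      r1 <- substring(frags, 1L, read_len)
      r2 <- revcomp(substring(frags, insert - read_len + 1L, insert))
      r1 <- add_errors(r1); r2 <- add_errors(r2)
      names(r1) <- sprintf("read%06d/1", seq_len(n))
      names(r2) <- sprintf("read%06d/2", seq_len(n))
      list(r1 = r1, r2 = r2)
    } else {
      n <- max(1L, round(coverage * L / read_len))
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
      reads <- substring(transcript, starts + 1L, starts + read_len)
      flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
      reads[flip] <- revcomp(reads[flip])
      reads <- add_errors(reads)
      names(reads) <- sprintf("read%06d", seq_len(n))
      reads
    }
  })
}

#' Simulate a clustered gene-by-library count matrix
#'
#' Genes belong to one of `k` archetypes — distinct tissue-level log2
#' expression patterns; counts are negative-binomial around the archetype
#' means, with a shared per-gene baseline drawn log-normally. Outlier
#' libraries are produced by permuting the gene labels of an otherwise clean
#' library, which preserves its count distribution while destroying its
#' correlation with every other library.
#'
#' @param n_genes number of genes.
#' @param tissues tissue names (one replicate group per tissue).
#' @param replicates replicates per tissue (>= 2).
#' @param k number of archetype clusters (>= 2).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   `0` gives Poisson counts.
#' @param amplitude archetype effect size, log2 units (default 2.5,
#'   i.e. ~5.7-fold between high and low tissues).
#' @param outlier_libraries library names to turn into label-permuted
#'   outliers.
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix), `lengths` (per-gene bp),
#'   `groups` (library -> tissue), and `truth` (`archetype` per gene,
#'   `outliers`, archetype pattern matrix).
#' @export
simulate_counts <- function(n_genes = 6000L,
                            tissues = c("Cb", "ShU", "ShA", "Fl1", "Fl2", "Fl3"),
                            replicates = 3L, k = 9L, dispersion = 0.05,
                            amplitude = 2.5,
                            outlier_libraries = character(0), seed = 1L) {
  if (replicates < 2L) stop("need at least 2 replicates per tissue")
  if (k < 2L) stop("need at least 2 archetypes")
  if (dispersion < 0) stop("dispersion must be non-negative")
  n_t <- length(tissues)
  libs <- as.vector(t(outer(tissues, seq_len(replicates),
                            function(t, r) paste0(t, "_R", r))))
  groups <- stats::setNames(rep(tissues, each = replicates), libs)
  if (!all(outlier_libraries %in% libs)) {
    stop("unknown outlier library: ",
         paste(setdiff(outlier_libraries, libs), collapse = ", "))
  }
  if (k > 2^(n_t - 1L) - 2L) {
    stop("too many archetypes for ", n_t, " tissues")
  }
  with_seed(seed, {
    ## distinct, non-constant +/- patterns over tissues, drawn from the
    ## even-parity code so any two archetypes differ in at least two
    ## tissues (keeps pattern correlation <= 1 - 4/n_t: well separated)
    pat <- matrix(0, k, n_t)
    seen <- character(0)
    for (a in seq_len(k)) {
      repeat {
        v <- sample(c(-1, 1), n_t - 1L, replace = TRUE)
        v <- c(v, prod(v))
        key <- paste(v, collapse = "")
        if (length(unique(v)) > 1L && !key %in% seen) break
      }
      seen <- c(seen, key)
      pat[a, ] <- v * amplitude
    }
    colnames(pat) <- tissues
    arch <- sample.int(k, n_genes, replace = TRUE)
    base <- stats::rlnorm(n_genes, meanlog = log(300), sdlog = 1)
    mu <- base * 2^pat[arch, , drop = FALSE]          # genes x tissues
    counts <- matrix(0L, n_genes, length(libs),
                     dimnames = list(sprintf("g%05d", seq_len(n_genes)), libs))
    for (j in seq_along(libs)) {
      m <- mu[, groups[libs[j]]]
      counts[, j] <- if (dispersion == 0) stats::rpois(n_genes, m)
                     else stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
    }
    for (lib in outlier_libraries) {
      counts[, lib] <- counts[sample.int(n_genes), lib]
    }
    lengths <- sample(seq(500L, 3000L), n_genes, replace = TRUE)
    names(lengths) <- rownames(counts)
    list(counts = counts, lengths = lengths, groups = groups,
         truth = list(archetype = stats::setNames(arch, rownames(counts)),
                      outliers = outlier_libraries, patterns = pat))
  })
}
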