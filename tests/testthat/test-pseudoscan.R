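test_that("global alignment handles identity and planted gaps", {
  set.seed(100)
  s <- rdna(300)
  al <- global_align(s, s)
  expect_equal(al$identity, 100)
  expect_false(grepl("-", al$q_aln, fixed = TRUE))

  ins <- paste0(substring(s, 1, 150), "ACGTACGT", substring(s, 151))
  al2 <- global_align(ins, s)
  runs <- gregexpr("-+", al2$r_aln)[[1]]
  expect_equal(length(runs), 1)
  expect_equal(attr(runs, "match.length"), 8)
  expect_error(global_align("", s), "empty")
  expect_error(global_align(s, strrep("A", 2000)), "5x")
})

test_that("global alignment score equals a quadratic-space DP oracle", {
  set.seed(101)
  for (i in 1:20) {
    a <- rdna(sample(50:300, 1))
    b <- a
    # mutate b: substitutions plus the occasional small indel
    bb <- strsplit(b, "")[[1]]
    for (j in sample(length(bb), length(bb) %/% 10)) {
      bb[j] <- sample(c("A", "C", "G", "T"), 1)
    }
    b <- paste(bb, collapse = "")
    if (i %% 2 == 0) {
      at <- sample(nchar(b) - 10, 1)
      b <- paste0(substring(b, 1, at), rdna(sample(1:6, 1)),
                  substring(b, at + 1))
    }
    al <- global_align(a, b)
    expect_equal(al$score, nw_score_oracle(a, b))
  }
})

test_that("indel detection reports run positions, lengths and frame
           offsets", {
  set.seed(102)
  ref <- rdna(600)
  ins8 <- paste0(substring(ref, 1, 200), "GATCCGGA", substring(ref, 201))
  ev <- detect_indels(global_align(ins8, ref))
  expect_equal(nrow(ev), 1)
  expect_identical(ev$kind, "insertion")
  expect_equal(ev$length, 8)
  expect_equal(ev$frame_offset, 2)

  del3 <- paste0(substring(ref, 1, 300), substring(ref, 304))
  ev3 <- detect_indels(global_align(del3, ref))
  expect_identical(ev3$kind, "deletion")
  expect_equal(ev3$frame_offset, 0)

  expect_equal(nrow(detect_indels(global_align(ref, ref))), 0)
})

test_that("each planted insertion of length 1..30 yields exactly one event
           with frame offset length mod 3", {
  set.seed(103)
  ref <- rdna(400)
  for (L in 1:30) {
    ins <- paste0(substring(ref, 1, 180), rdna(L), substring(ref, 181))
    ev <- detect_indels(global_align(ins, ref))
    ev <- ev[ev$kind == "insertion", ]
    expect_equal(sum(ev$length), L)
    if (nrow(ev) == 1) {
      expect_equal(ev$frame_offset, L %% 3)
      expect_lt(abs(ev$ref_pos - 179), 6)  # aligner may slide in repeats
    }
  }
})

test_that("premature stops are found where the codon-scan oracle says,
           and terminal stops are not premature", {
  gm <- simulate_gene_models(n_genes = 1, seed = 104)
  m <- gm$models[[1]]
  # substitutions only, no frame disruption: no premature stop
  orth <- simulate_ortholog(m, gm$genome, divergence = 0.1,
                            n_contigs = 1, gap_len = 0, seed = 105)
  al <- global_align(orth$transcript, m$cds)
  expect_null(detect_premature_stop(orth$transcript, al))
  # the reference itself: the terminal stop is not premature
  expect_null(detect_premature_stop(m$cds, global_align(m$cds, m$cds)))

  set.seed(106)
  for (i in 1:30) {
    gm2 <- simulate_gene_models(n_genes = 1, exon_count_range = c(4, 6),
                                seed = 200 + i)
    m2 <- gm2$models[[1]]
    orth2 <- simulate_ortholog(
      m2, gm2$genome, divergence = 0,
      events = list(event_spec("insertion",
                               exon = sample(2:3, 1),
                               length = sample(c(1, 2, 4, 5, 7, 8), 1))),
      n_contigs = 1, gap_len = 0, seed = 300 + i)
    al2 <- global_align(orth2$transcript, m2$cds)
    got <- detect_premature_stop(orth2$transcript, al2)
    want <- stop_scan_oracle(orth2$transcript, 0L)
    if (is.null(got)) {
      # the first in-frame stop must then be the terminal codon region
      expect_true(is.na(want) ||
                    want >= nchar(orth2$transcript) - 3 -
                      orth2$events$length[1])
    } else {
      expect_equal(got$query_pos, want)
      expect_gte(got$truncated_fraction, 0)
      expect_lte(got$truncated_fraction, 1)
    }
  }
})

test_that("insertions at annotated junctions with matching length become
           retained introns", {
  gm <- simulate_gene_models(n_genes = 1, exon_count_range = c(10, 10),
                             intron_len_range = c(695, 695), seed = 107)
  m <- gm$models[[1]]
  orth <- simulate_ortholog(m, gm$genome, divergence = 0.15,
                            events = list(event_spec("retained_intron",
                                                     intron = 8)),
                            n_contigs = 1, gap_len = 0, seed = 108)
  al <- global_align(orth$transcript, m$cds)
  ev <- detect_retained_intron(al, m)
  ri <- ev[ev$kind == "retained_intron", ]
  expect_equal(nrow(ri), 1)
  expect_equal(ri$intron_index, 8)
  expect_equal(ri$length, 695)

  # fully spliced transcript: nothing to reclassify
  spliced <- simulate_ortholog(m, gm$genome, divergence = 0.1,
                               n_contigs = 1, gap_len = 0, seed = 109)
  ev0 <- detect_retained_intron(global_align(spliced$transcript, m$cds), m)
  expect_equal(sum(ev0$kind == "retained_intron"), 0)

  # a mid-exon insertion of unrelated length stays an insertion
  mid <- simulate_ortholog(m, gm$genome, divergence = 0,
                           events = list(event_spec("insertion", exon = 5,
                                                    length = 300)),
                           n_contigs = 1, gap_len = 0, seed = 110)
  evm <- detect_retained_intron(global_align(mid$transcript, m$cds), m)
  expect_identical(evm$kind[evm$length == 300], "insertion")
})

test_that("detected events applied to the reference reconstruct the query
           (event completeness)", {
  gm <- simulate_gene_models(n_genes = 3, exon_count_range = c(8, 10),
                             seed = 111)
  for (m in gm$models) {
    orth <- simulate_ortholog(
      m, gm$genome, divergence = 0,
      events = list(event_spec("insertion", exon = 2, length = 8),
                    event_spec("deletion", exon = 4, length = 5),
                    event_spec("retained_intron", intron = 6)),
      n_contigs = 1, gap_len = 0, seed = 112)
    ev <- detect_indels(global_align(orth$transcript, m$cds))
    rebuilt <- m$cds
    ev <- ev[order(-ev$ref_pos), ]
    for (i in seq_len(nrow(ev))) {
      p <- ev$ref_pos[i] + 1
      if (ev$kind[i] == "deletion") {
        rebuilt <- paste0(substring(rebuilt, 1, p),
                          substring(rebuilt, p + ev$length[i] + 1))
      } else {
        rebuilt <- paste0(substring(rebuilt, 1, p), ev$seq[i],
                          substring(rebuilt, p + 1))
      }
    }
    expect_identical(rebuilt, orth$transcript)
  }
})

test_that("classification follows the event hierarchy and ignores event
           order", {
  no_ev <- detect_indels(global_align("ATGAAATTTTAA", "ATGAAATTTTAA"))
  expect_identical(classify(no_ev)$label, "conserved")

  ev <- data.frame(kind = c("insertion", "premature_stop"),
                   ref_pos = c(100, 300), length = c(8, 3),
                   frame_offset = c(2, 0), seq = c("ACGTACGT", "TAA"),
                   aln_col = c(101, 309), stringsAsFactors = FALSE)
  attr(ev, "truncated_fraction") <- 0.6
  expect_identical(classify(ev)$label, "frameshift_pseudogene")
  ev_rev <- ev[2:1, ]
  attr(ev_rev, "truncated_fraction") <- 0.6
  expect_identical(classify(ev_rev)$label, "frameshift_pseudogene")

  # frameshift but near-terminal stop: not a pseudogene call
  attr(ev, "truncated_fraction") <- 0.01
  expect_false(identical(classify(ev)$label, "frameshift_pseudogene"))

  ri <- data.frame(kind = "retained_intron", ref_pos = 500, length = 693,
                   frame_offset = 0, seq = "GTAG", aln_col = 501,
                   stringsAsFactors = FALSE)
  expect_identical(classify(ri)$label, "retained_intron")

  inframe <- data.frame(kind = "deletion", ref_pos = 50, length = 3,
                        frame_offset = 0, seq = "AAA", aln_col = 51,
                        stringsAsFactors = FALSE)
  expect_identical(classify(inframe)$label, "in_frame_variant")

  stop_only <- data.frame(kind = "premature_stop", ref_pos = 90,
                          length = 3, frame_offset = 0, seq = "TGA",
                          aln_col = 91, stringsAsFactors = FALSE)
  attr(stop_only, "truncated_fraction") <- 0.5
  expect_identical(classify(stop_only)$label, "truncated")
})

test_that("the full scan reproduces a frameshift-pseudogene scenario with
           read support", {
  gm <- simulate_gene_models(n_genes = 1, exon_count_range = c(12, 12),
                             seed = 113)
  m <- gm$models[[1]]
  orth <- simulate_ortholog(m, gm$genome, divergence = 0.15,
                            events = list(event_spec("insertion", exon = 3,
                                                     length = 8),
                                          event_spec("retained_intron",
                                                     intron = 8)),
                            n_contigs = 1, gap_len = 0, seed = 114)
  reads <- simulate_reads(orth$transcript, read_len = 100, coverage = 20,
                          seed = 115)
  scan <- scan_pseudogene(orth$transcript, m$cds, gene_model = m,
                          reads = c(reads$r1, reads$r2))
  expect_identical(scan$status$label, "frameshift_pseudogene")
  kinds <- scan$events$kind
  expect_true("retained_intron" %in% kinds)
  ins <- scan$events[scan$events$kind == "insertion", ]
  expect_equal(ins$length, 8)
  expect_equal(ins$frame_offset, 2)
  expect_true(isTRUE(ins$read_support))
  expect_true("premature_stop" %in% kinds)
})
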