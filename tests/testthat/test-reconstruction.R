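test_that("contig mapping reports exact substrings and strand, and
           ignores unrelated sequence", {
  set.seed(80)
  ref <- rdna(800)
  contigs <- c(mid = substring(ref, 101, 400),
               rc = rc_oracle(substring(ref, 501, 700)),
               junk = rdna(1000))
  blocks <- map_contigs(contigs, ref)
  expect_length(blocks, 2)
  b1 <- blocks[[1]]
  expect_equal(c(b1$r_start, b1$r_end), c(100, 400))
  expect_equal(b1$identity, 100)
  expect_identical(b1$strand, "+")
  expect_identical(blocks[[2]]$strand, "-")
  expect_false(any(vapply(blocks, `[[`, character(1), "contig_id") ==
                     "junk"))
})

test_that("stitching reproduces the reference-order layout with the
           planted hole", {
  set.seed(81)
  ref <- rdna(900)
  frags <- c(f1 = substring(ref, 1, 300),
             f2 = substring(ref, 301, 500),
             f3 = substring(ref, 621, 900))   # 120-bp hole at 500..620
  blocks <- map_contigs(frags, ref)
  scaf <- stitch(blocks, ref)
  expect_equal(nrow(scaf$gaps), 1)
  expect_equal(scaf$gaps$ref_end - scaf$gaps$ref_start, 120)
  expect_equal(scaf$gaps$ref_start, 500)
  expect_identical(gsub("N", "", scaf$sequence),
                   paste0(substring(ref, 1, 500), substring(ref, 621, 900)))
  # full coverage -> no gaps, sequence equals the reference
  full <- stitch(map_contigs(c(a = substring(ref, 1, 500),
                               b = substring(ref, 401, 900)), ref), ref)
  expect_equal(nrow(full$gaps), 0)
  expect_identical(full$sequence, ref)
  # identical overlapping blocks collapse once; input order irrelevant
  bl <- map_contigs(c(a = substring(ref, 1, 500),
                      b = substring(ref, 401, 900)), ref)
  expect_identical(stitch(rev(bl), ref)$sequence, full$sequence)
})

test_that("disagreeing overlaps beyond 20% raise a conflict error", {
  set.seed(82)
  ref <- rdna(600)
  # contig B disagrees with contig A over ~30% of their 200-bp overlap but
  # stays anchored by its exact 200-bp tail
  overlap <- strsplit(substring(ref, 201, 400), "")[[1]]
  hit <- sample(200, 60)
  for (i in hit) overlap[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              overlap[i]), 1)
  contigs <- c(good = substring(ref, 1, 400),
               bad = paste0(paste(overlap, collapse = ""),
                            substring(ref, 401, 600)))
  blocks <- map_contigs(contigs, ref, min_score = 50)
  expect_length(blocks, 2)
  expect_error(stitch(blocks, ref), "disagree")
})

test_that("read gap filling closes a short gap exactly in one iteration
           and leaves unfillable gaps untouched", {
  set.seed(83)
  tx <- rdna(700)
  ref <- tx
  frags <- c(l = substring(tx, 1, 335), r = substring(tx, 366, 700))
  scaf <- stitch(map_contigs(frags, ref), ref)
  expect_equal(nrow(scaf$gaps), 1)
  reads <- simulate_reads(tx, read_len = 100, coverage = 20, seed = 84)
  filled <- grep_extend(scaf, c(reads$r1, reads$r2))
  expect_true(all(filled$fill_report$closed))
  expect_equal(filled$fill_report$iterations, 1)
  expect_identical(filled$sequence, tx)
  # no read carries either flank seed -> unfilled, scaffold unchanged
  unrelated <- setNames(vapply(1:50, function(i) rdna(100), character(1)),
                        paste0("x", 1:50))
  untouched <- grep_extend(scaf, unrelated)
  expect_false(any(untouched$fill_report$closed))
  expect_identical(untouched$sequence, scaf$sequence)
})

test_that("a gap of ~2.5 read-lengths-minus-seed closes in exactly three
           one-sided iterations", {
  set.seed(85)
  tx <- rdna(1400)
  gap_start <- 601
  gap_len <- 180  # = 2.4 x (100 - 25)
  frags <- c(l = substring(tx, 1, gap_start - 1),
             r = substring(tx, gap_start + gap_len, 1400))
  scaf <- stitch(map_contigs(frags, tx), tx)
  expect_equal(scaf$gaps$ref_end - scaf$gaps$ref_start, gap_len)
  reads <- simulate_reads(tx, read_len = 100, coverage = 30, seed = 86)
  filled <- grep_extend(scaf, c(reads$r1, reads$r2), seed_len = 25,
                        both_flanks = FALSE)
  expect_true(filled$fill_report$closed)
  expect_equal(filled$fill_report$iterations, 3)
  expect_identical(filled$sequence, tx)
})

test_that("gap filling never modifies non-gap bases", {
  set.seed(87)
  tx <- rdna(900)
  frags <- c(l = substring(tx, 1, 400), r = substring(tx, 521, 900))
  scaf <- stitch(map_contigs(frags, tx), tx)
  before <- strsplit(scaf$sequence, "")[[1]]
  reads <- simulate_reads(tx, read_len = 100, coverage = 20, seed = 88)
  filled <- grep_extend(scaf, c(reads$r1, reads$r2))
  after <- strsplit(filled$sequence, "")[[1]]
  non_gap <- scaf$provenance != "gap"
  expect_identical(after[filled$provenance != "gap" &
                           startsWith(filled$provenance, "contig")],
                   before[non_gap])
})

test_that("finalize trims to the reference frame and reports identity", {
  gm <- simulate_gene_models(n_genes = 1, seed = 90)
  m <- gm$models[[1]]
  fin <- finalize(m$cds, m$cds)
  expect_equal(fin$identity_cds, 100)
  expect_identical(fin$peptide, m$peptide)
  expect_false(fin$premature_stop)
  # a premature stop is flagged, not silently trimmed
  mut <- paste0(substring(m$cds, 1, 90), "TAA", substring(m$cds, 94))
  fin2 <- finalize(mut, m$cds)
  expect_true(fin2$premature_stop)
  expect_identical(fin2$cds, mut)
  expect_equal(nchar(fin2$peptide), 30)
})

test_that("fragmented diverged orthologs reconstruct base-perfectly end
           to end", {
  gm <- simulate_gene_models(n_genes = 5, seed = 91)
  for (gid in names(gm$models)) {
    m <- gm$models[[gid]]
    orth <- simulate_ortholog(m, gm$genome, divergence = 0.27,
                              n_contigs = 3, gap_len = 120, seed = 92)
    reads <- simulate_reads(orth$transcript, read_len = 100, coverage = 20,
                            seed = 93)
    blocks <- map_contigs(orth$contigs, m$cds)
    scaf <- grep_extend(stitch(blocks, m$cds), c(reads$r1, reads$r2))
    fin <- finalize(scaf, m$cds)
    expect_identical(fin$cds, orth$transcript)
    expect_gt(fin$identity_cds, 65)
    expect_lt(fin$identity_cds, 80)
  }
})

test_that("genomic recovery finds planted gene loci exactly", {
  gm <- simulate_gene_models(n_genes = 2, exon_count_range = c(3, 3),
                             exon_len_range = c(120, 240),
                             intron_len_range = c(80, 300),
                             strand = "+", seed = 94)
  m <- gm$models[[1]]
  hit <- genome_recover(m$cds, gm$genome)
  expect_true(hit$found)
  expect_identical(hit$scaffold, m$scaffold)
  expect_identical(hit$strand, "+")
  expect_equal(hit$exons, m$exons, ignore_attr = TRUE)
  expect_identical(hit$cds, m$cds)
  expect_equal(hit$identity, 100)
  expect_equal(hit$frame, 1)
})

test_that("genomic recovery handles minus strands, single exons and
           frame selection", {
  gm <- simulate_gene_models(n_genes = 1, exon_count_range = c(2, 2),
                             strand = "-", seed = 95)
  m <- gm$models[[1]]
  hit <- genome_recover(m$cds, gm$genome)
  expect_true(hit$found)
  expect_identical(hit$strand, "-")
  expect_identical(hit$cds, m$cds)
  expect_equal(hit$exons, m$exons, ignore_attr = TRUE)

  # single-exon exact query: one exon, identity 100
  set.seed(96)
  gene <- paste0("ATG", strrep("GCT", 60), "TAA")
  genome1 <- c(chr = paste0(rdna(200), gene, rdna(200)))
  hit1 <- genome_recover(gene, genome1)
  expect_true(hit1$found)
  expect_equal(nrow(hit1$exons), 1)
  expect_equal(hit1$identity, 100)

  # exonic sequence matching the query peptide in frame +2 only
  pep <- "MDEVKNLLSWFHRTGA"
  codons <- c(M = "ATG", D = "GAT", E = "GAA", V = "GTT", K = "AAA",
              N = "AAT", L = "CTT", S = "TCT", W = "TGG", F = "TTT",
              H = "CAT", R = "CGT", T = "ACT", G = "GGT", A = "GCT")
  dna <- paste(codons[strsplit(pep, "")[[1]]], collapse = "")
  shifted <- paste0("C", dna, "GG")
  genome2 <- c(chr = paste0(rdna(150), shifted, rdna(150)))
  hit2 <- genome_recover(shifted, genome2, query_peptide = pep)
  expect_true(hit2$found)
  expect_equal(hit2$frame, 2)

  # absence is reported, not fabricated
  miss <- genome_recover(rdna(300), c(chr = rdna(5000)))
  expect_false(miss$found)
})
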