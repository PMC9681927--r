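## Coordinate conventions
##
## Internally every interval is 0-based half-open [start, end); GFF3 1-based
## inclusive coordinates are converted exactly once, at read/write time.
## All transcript-level analyses operate in transcription orientation; genomic
## intervals keep scaffold orientation plus a strand flag.

#' Convert GFF3 1-based inclusive coordinates to internal 0-based half-open
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return A two-column matrix `start`, `end`, 0-based half-open.
#' @export
gff_to_internal <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  cbind(start = start - 1L, end = as.integer(end))
}

#' Convert internal 0-based half-open coordinates back to GFF3 1-based
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return A two-column matrix `start`, `end`, 1-based inclusive.
#' @export
internal_to_gff <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  cbind(start = as.integer(start + 1L), end = as.integer(end))
}

#' Reverse complement of DNA strings
#'
#' Accepts plain character vectors over the A/C/G/T/N alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Trailing bases that do not fill a codon are ignored; codons containing N
#' translate to `X`. Stops are `*`.
#'
#' @param cds DNA string.
#' @return amino-acid string (including any stops).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

sanitize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%s: %d sequence(s) contain IUPAC ambiguity codes; mapped to N",
                    what, sum(bad)))
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Read a FASTA file
#'
#' @param path FASTA file (optionally gzipped).
#' @param dna if `TRUE` (default) sequences are uppercased and non-ACGTN
#'   characters are mapped to `N` with a warning.
#' @return named character vector of sequences, with per-record header
#'   descriptions in `attr(, "descriptions")`. Record order is preserved.
#' @export
read_fasta <- function(path, dna = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  if (dna) seqs <- sanitize_dna(seqs, basename(path))
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param descriptions optional named character vector appended to headers.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, descriptions = NULL, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    hdr <- if (!is.null(descriptions) && !is.na(descriptions[id]) &&
               nzchar(descriptions[id])) {
      paste0(">", id, " ", descriptions[id])
    } else paste0(">", id)
    writeLines(hdr, con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33; optionally gzipped).
#' @return named character vector of read sequences (uppercased).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write reads to FASTQ
#'
#' All bases receive the same placeholder quality (`I`, Phred 40).
#'
#' @param seqs named character vector of reads.
#' @param path output file; `.gz` suffix writes gzip.
#' @export
write_fastq <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0("@", id), seqs[[id]], "+",
                 strrep("I", nchar(seqs[[id]]))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model holds the ordered exon structure of a reference gene together
#' with its spliced CDS and translated peptide. Exons are stored in
#' transcription order (5' to 3' on the transcript) as 0-based half-open
#' genomic intervals on the forward scaffold strand.
#'
#' @param gene_id gene identifier.
#' @param scaffold scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open genomic coordinates), rows in transcription order.
#' @param cds spliced coding sequence, transcription orientation.
#' @param validate check CDS/exon/peptide invariants (default `TRUE`).
#' @return an object of class `gene_model` with fields `gene_id`, `scaffold`,
#'   `strand`, `exons`, `cds`, `peptide`, and `in_frame` (`FALSE` when the CDS
#'   length is not divisible by 3; such records are flagged, not dropped).
#' @export
gene_model <- function(gene_id, scaffold, strand, exons, cds, validate = TRUE) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[, c("start", "end")]
  in_frame <- nchar(cds) %% 3L == 0L
  if (validate) {
    if (any(exons$end <= exons$start)) stop(gene_id, ": empty exon interval")
    glen <- sum(exons$end - exons$start)
    if (glen != nchar(cds)) {
      stop(gene_id, ": CDS length ", nchar(cds),
           " != total exon length ", glen)
    }
    ord <- if (strand == "+") order(exons$start) else order(-exons$start)
    if (!identical(ord, seq_len(nrow(exons)))) {
      stop(gene_id, ": exons not in transcription order")
    }
    if (!in_frame) {
      warning(gene_id, ": CDS length not divisible by 3; flagged")
    }
  }
  pep <- translate_cds(cds)
  # strip the single terminal stop when present
  if (in_frame && nchar(pep) > 0L && substring(pep, nchar(pep)) == "*") {
    pep <- substring(pep, 1L, nchar(pep) - 1L)
  }
  structure(list(gene_id = gene_id, scaffold = scaffold, strand = strand,
                 exons = exons, cds = cds, peptide = pep,
                 in_frame = in_frame),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s(%s)  %d exon(s), CDS %d bp, peptide %d aa%s\n",
              x$gene_id, x$scaffold, x$strand, nrow(x$exons), nchar(x$cds),
              nchar(x$peptide), if (x$in_frame) "" else "  [out of frame]"))
  invisible(x)
}

#' CDS coordinates of exon-exon junctions and intron lengths of a gene model
#'
#' @param model a `gene_model`.
#' @return data.frame with one row per intron: `intron` (1-based index),
#'   `cds_pos` (0-based CDS coordinate of the first base of the downstream
#'   exon, i.e. the junction), `length` (intron length in bp).
#' @export
gene_model_junctions <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(intron = integer(0), cds_pos = integer(0),
                      length = integer(0)))
  }
  lens <- ex$end - ex$start
  if (model$strand == "+") {
    intron_len <- ex$start[-1L] - ex$end[-n]
  } else {
    intron_len <- ex$start[-n] - ex$end[-1L]
  }
  data.frame(intron = seq_len(n - 1L),
             cds_pos = cumsum(lens)[-n],
             length = as.integer(intron_len))
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Exon features (grouped by `Parent` transcript, falling back to CDS features
#' when no exon rows are present) are spliced into a CDS in transcription
#' order; minus-strand exons are reverse-complemented. A CDS whose length is
#' not divisible by 3 is flagged (`in_frame = FALSE`) with a warning, not
#' dropped.
#'
#' @param gff_path GFF3 file.
#' @param genome_fasta_path genome FASTA with the scaffolds named in the GFF.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(gff_path, genome_fasta_path) {
  genome <- read_fasta(genome_fasta_path)
  gr <- rtracklayer::import(gff_path)
  feat <- as.data.frame(gr)
  types <- as.character(feat$type)
  use <- types == "exon"
  if (!any(use)) use <- types == "CDS"
  if (!any(use)) stop("no exon or CDS features in ", gff_path)
  feat <- feat[use, ]
  parent <- vapply(feat$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  parent <- sub("^transcript:", "", parent)
  models <- list()
  for (tx in unique(parent)) {
    rows <- feat[parent == tx, ]
    scaf <- as.character(rows$seqnames[1])
    if (!scaf %in% names(genome)) {
      stop("exon of ", tx, " references missing scaffold ", scaf)
    }
    strand <- as.character(rows$strand[1])
    if (!strand %in% c("+", "-")) strand <- "+"
    iv <- gff_to_internal(rows$start, rows$end)
    ord <- if (strand == "+") order(iv[, "start"]) else order(-iv[, "start"])
    iv <- iv[ord, , drop = FALSE]
    pieces <- substring(genome[[scaf]], iv[, "start"] + 1L, iv[, "end"])
    if (strand == "-") pieces <- revcomp(pieces)
    cds <- paste(pieces, collapse = "")
    gid <- sub("^(mRNA|transcript)[:.]", "", tx)
    models[[gid]] <- gene_model(gid, scaf, strand,
                                data.frame(start = iv[, "start"],
                                           end = iv[, "end"]),
                                cds)
  }
  models
}

#' Write gene models to GFF3
#'
#' @param models list of [gene_model()] objects.
#' @param path output GFF3 file.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    g <- internal_to_gff(min(m$exons$start), max(m$exons$end))
    writeLines(sprintf("%s\torthofill\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
                       m$scaffold, g[1, "start"], g[1, "end"], m$strand,
                       m$gene_id), con)
    writeLines(sprintf("%s\torthofill\tmRNA\t%d\t%d\t.\t%s\t.\tID=mRNA:%s;Parent=gene:%s",
                       m$scaffold, g[1, "start"], g[1, "end"], m$strand,
                       m$gene_id, m$gene_id), con)
    iv <- internal_to_gff(m$exons$start, m$exons$end)
    for (i in seq_len(nrow(iv))) {
      writeLines(sprintf("%s\torthofill\texon\t%d\t%d\t.\t%s\t.\tID=exon:%s.%d;Parent=mRNA:%s",
                         m$scaffold, iv[i, "start"], iv[i, "end"], m$strand,
                         m$gene_id, i, m$gene_id), con)
    }
  }
  invisible(path)
}

#' Read a gene-by-library count matrix from TSV
#'
#' First column gene id, remaining columns one per library, non-negative
#' integer counts.
#'
#' @param path TSV file with a header line.
#' @return integer matrix, genes in rows (rownames), libraries in columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[1])) stop("missing header in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_hdr <- length(fields[[1]])
  if (ncol_hdr < 2L) stop("missing header in ", path)
  nf <- lengths(fields)
  # header may omit the gene-id column name
  body_ok <- nf[-1] %in% c(ncol_hdr, ncol_hdr + 1L)
  if (length(unique(nf[-1])) > 1L || !all(body_ok)) {
    stop("ragged row at line ", which(!body_ok | nf[-1] != nf[2])[1] + 1L,
         " in ", path)
  }
  libs <- fields[[1]]
  if (nf[2] == ncol_hdr) libs <- libs[-1]
  rows <- fields[-1]
  genes <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(f) f[-1], character(length(libs))))
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = length(genes)))
  if (anyNA(num)) stop("non-numeric count in ", path)
  if (any(num < 0)) stop("negative count in ", path)
  if (any(num != round(num))) stop("non-integer count in ", path)
  mat <- matrix(as.integer(num), nrow = length(genes),
                dimnames = list(genes, libs))
  mat
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix with gene rownames and library colnames.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column orthogroup assignment table
#'
#' @param path TSV with columns `contig_id`, `orthogroup_id` (header optional
#'   but recommended).
#' @return data.frame with columns `contig_id`, `orthogroup_id`.
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("orthogroup table needs two columns: ", path)
  stats::setNames(df[, 1:2], c("contig_id", "orthogroup_id"))
}

#' Read a qPCR CT table
#'
#' Long format: one row per well with columns `sample`, `gene`, `ct`
#' (technical replicate rows share sample and gene).
#'
#' @param path TSV file.
#' @return data.frame with columns `sample`, `gene`, `ct` (numeric).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("CT table needs columns sample, gene, ct: ", path)
  }
  df$ct <- as.numeric(df$ct)
  df[, need]
}
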