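## Quantification, clustering, replicate QC, differential expression
## (lightweight NB stand-in), hypergeometric enrichment and qPCR
## quantification.

#' FPKM normalization
#'
#' `fpkm(g, l) = counts(g, l) * 1e9 / (length(g) * total(l))` where
#' `total(l)` is the library's total mapped count. Corrects for transcript
#' length and sequencing depth.
#'
#' @param counts integer matrix, genes x libraries.
#' @param lengths per-gene effective length in bp (named or in row order).
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths) {
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("library with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  sweep(sweep(counts * 1e9, 1, lengths, "/"), 2, totals, "/")
}

#' log2(FPKM + 1) transform
#'
#' The pseudocount keeps zeros finite and the matrix non-negative.
#'
#' @param fpkm_mat FPKM matrix from [fpkm()].
#' @return log2-scale matrix.
#' @export
log2_fpkm <- function(fpkm_mat) log2(fpkm_mat + 1)

#' Remove genes with low mean count
#'
#' Keeps genes whose mean raw count across all libraries is at least
#' `min_mean` (i.e. removes genes with mean count below it).
#'
#' @param counts integer matrix.
#' @param min_mean threshold (default 1).
#' @return filtered count matrix.
#' @export
filter_low <- function(counts, min_mean = 1) {
  counts[rowMeans(counts) >= min_mean, , drop = FALSE]
}

#' Select the most variable genes by median absolute deviation
#'
#' MAD is unscaled (no 1.4826 consistency constant): only the ranking
#' matters. Ties are broken by gene id so the selection is deterministic.
#'
#' @param mat expression matrix (typically log2 FPKM), genes in rows.
#' @param top_n number of genes to keep (default 4000).
#' @return character vector of selected gene ids, MAD-descending.
#' @export
mad_select <- function(mat, top_n = 4000L) {
  m <- apply(mat, 1, stats::mad, constant = 1)
  if (top_n > nrow(mat)) {
    warning("top_n exceeds gene count; returning all genes")
    top_n <- nrow(mat)
  }
  ord <- order(-m, rownames(mat))
  rownames(mat)[ord][seq_len(top_n)]
}

#' Correlation distance matrix
#'
#' `d(i, j) = 1 - Pearson r(i, j)` between profiles; scale-free, range
#' `[0, 2]`.
#'
#' @param mat numeric matrix.
#' @param margin 1 to compare rows (genes), 2 to compare columns
#'   (libraries).
#' @return a `dist` object.
#' @export
correlation_distance <- function(mat, margin = 1L) {
  x <- if (margin == 1L) t(mat) else mat
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(x))
}

#' Complete-linkage hierarchical clustering with a k-cluster cut
#'
#' @param d distance object or matrix (e.g. from
#'   [correlation_distance()]).
#' @param k number of clusters.
#' @param linkage linkage method (default `"complete"`).
#' @return list with `assignments` (named integer vector of labels 1..k),
#'   `tree` (the `hclust` object), and `sizes` (cluster sizes).
#' @export
hcluster_cut <- function(d, k, linkage = "complete") {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1L || k > n) stop("k must be between 1 and the number of profiles")
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  list(assignments = cl, tree = tree, sizes = table(cl))
}

## For every leaf: does the smallest merge-tree cluster containing it and a
## same-group partner stay within the replicate-group size? (Merge nodes are
## visited bottom-up; the first node joining a leaf with a mate is the
## smallest such cluster.)
cocluster_ok <- function(tree, groups, group_sizes) {
  merge <- tree$merge
  n <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  ok <- rep(FALSE, n)
  done <- rep(FALSE, n)
  for (i in seq_len(nrow(merge))) {
    members[[i]] <- c(if (merge[i, 1] < 0) -merge[i, 1] else members[[merge[i, 1]]],
                      if (merge[i, 2] < 0) -merge[i, 2] else members[[merge[i, 2]]])
    mem <- members[[i]]
    for (leaf in mem[!done[mem]]) {
      mates <- mem[groups[mem] == groups[leaf]]
      if (length(mates) > 1L) {
        done[leaf] <- TRUE
        ok[leaf] <- length(mem) <= group_sizes[[groups[leaf]]]
      }
    }
  }
  ok
}

#' Bootstrap co-clustering replicate QC
#'
#' Replicate libraries of one sample are expected to group with each other.
#' For each bootstrap resample of genes, libraries are clustered by
#' correlation distance with complete linkage; a library scores a success
#' when the smallest cluster containing it and at least one same-group
#' replicate is no larger than its replicate group. The support of a
#' library is its success fraction over bootstraps; libraries below
#' `min_support` are flagged for removal.
#'
#' @param mat expression matrix (log2 FPKM recommended; raw counts
#'   accepted), genes x libraries.
#' @param groups named character vector, library -> replicate group.
#' @param n_boot number of bootstrap resamples (>= 100 recommended).
#' @param min_support flag threshold on the support fraction (default 0.5).
#' @param seed RNG seed.
#' @return data.frame with columns `library`, `group`, `support`,
#'   `flagged`.
#' @export
bootstrap_replicate_qc <- function(mat, groups, n_boot = 1000L,
                                   min_support = 0.5, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be positive")
  libs <- colnames(mat)
  stopifnot(all(libs %in% names(groups)))
  groups <- groups[libs]
  gsz <- table(groups)
  if (any(gsz < 2L)) {
    stop("replicate group(s) of size 1: ",
         paste(names(gsz)[gsz < 2L], collapse = ", "))
  }
  ng <- nrow(mat)
  succ <- stats::setNames(numeric(length(libs)), libs)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ng, ng, replace = TRUE)
      bm <- mat[idx, , drop = FALSE]
      sds <- apply(bm, 2, stats::sd)
      if (any(sds == 0)) next
      tree <- stats::hclust(stats::as.dist(1 - stats::cor(bm)),
                            method = "complete")
      succ <- succ + cocluster_ok(tree, unname(groups), gsz)
    }
  })
  support <- succ / n_boot
  data.frame(library = libs, group = unname(groups),
             support = unname(support),
             flagged = unname(support < min_support),
             row.names = NULL, stringsAsFactors = FALSE)
}

## median-of-ratios size factors (reference = geometric mean over libraries)
size_factors <- function(counts) {
  logs <- log(counts)
  logs[!is.finite(logs)] <- NA
  ref <- rowMeans(logs)
  sf <- apply(logs, 2, function(lc) exp(stats::median(lc - ref, na.rm = TRUE)))
  if (anyNA(sf) || any(!is.finite(sf))) {
    stop("cannot estimate size factors (no gene expressed everywhere?)")
  }
  sf
}

#' Negative-binomial differential expression between two groups
#'
#' A lightweight two-group test: median-of-ratios size factors,
#' method-of-moments NB dispersion pooled across the two groups and
#' moderated toward the median dispersion of expressed genes (prior
#' weight `prior_df`, in the spirit of limma/edgeR shrinkage -- raw
#' 2-residual-df dispersion estimates are far too noisy to calibrate a
#' Wald test), and a Wald test on the log2 fold change of normalized
#' means referred to a t distribution with residual + prior degrees of
#' freedom. P-values are BH-adjusted. Genes with zero counts in both
#' groups get `log2fc = 0`, `p = 1`.
#'
#' @param counts integer matrix, genes x libraries.
#' @param group_a,group_b column names (or indices) of the two groups;
#'   at least 2 libraries each.
#' @param prior_df prior weight of the common dispersion (default 12).
#' @return data.frame with columns `gene`, `base_mean`, `log2fc`, `p`,
#'   `padj`.
#' @export
de_test <- function(counts, group_a, group_b, prior_df = 12) {
  a <- counts[, group_a, drop = FALSE]
  b <- counts[, group_b, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  if (nA < 2L || nB < 2L) stop("need >= 2 libraries per group")
  sf <- size_factors(cbind(a, b))
  qa <- sweep(a, 2, sf[seq_len(nA)], "/")
  qb <- sweep(b, 2, sf[nA + seq_len(nB)], "/")
  mA <- rowMeans(qa); mB <- rowMeans(qb)
  vA <- apply(qa, 1, stats::var); vB <- apply(qb, 1, stats::var)
  ## pooled method-of-moments dispersion: var = mu + disp * mu^2
  pool_num <- (nA - 1L) * (vA - mA) + (nB - 1L) * (vB - mB)
  pool_den <- (nA - 1L) * mA^2 + (nB - 1L) * mB^2
  disp <- pmax(0, ifelse(pool_den > 0, pool_num / pool_den, 0))
  res_df <- nA + nB - 2L
  expressed <- (mA + mB) / 2 >= 5
  common <- if (any(expressed)) stats::median(disp[expressed]) else 0
  disp <- (res_df * disp + prior_df * common) / (res_df + prior_df)
  log2fc <- log2(mB + 0.5) - log2(mA + 0.5)
  ## delta-method variance of log2 of a group mean of NB counts
  varA <- ifelse(mA > 0, (mA + disp * mA^2) / nA, 0)
  varB <- ifelse(mB > 0, (mB + disp * mB^2) / nB, 0)
  se2 <- (varA / (mA + 0.5)^2 + varB / (mB + 0.5)^2) / log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(z), df = res_df + prior_df)
  both_zero <- rowSums(a) == 0 & rowSums(b) == 0
  log2fc[both_zero] <- 0
  p[both_zero] <- 1
  data.frame(gene = rownames(counts), base_mean = (mA + mB) / 2,
             log2fc = log2fc, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply p-value and fold-change cutoffs to a DE result
#'
#' Keeps genes with `p < p_cutoff` and `|log2fc| >= log2(fc_cutoff)`.
#'
#' @param de data.frame from [de_test()].
#' @param p_cutoff raw p-value cutoff (default 0.01).
#' @param fc_cutoff fold-change cutoff (default 2, i.e. `|log2fc| >= 1`).
#' @param use_adjusted threshold on `padj` instead of `p`.
#' @return character vector of significant gene ids.
#' @export
apply_thresholds <- function(de, p_cutoff = 0.01, fc_cutoff = 2,
                             use_adjusted = FALSE) {
  pv <- if (use_adjusted) de$padj else de$p
  de$gene[pv < p_cutoff & abs(de$log2fc) >= log2(fc_cutoff)]
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least `k` of the term's `K` background genes in a set of size `n` drawn
#' from a background of size `N`; BH adjustment across terms.
#'
#' @param gene_set character vector, a subset of `background`.
#' @param term_genes named list, term -> character vector of annotated
#'   background genes.
#' @param background character vector of all genes in the universe.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `padj`,
#'   ordered by p.
#' @export
enrich <- function(gene_set, term_genes, background) {
  if (length(background) == 0L) stop("empty background")
  if (!all(gene_set %in% background)) {
    stop("gene_set contains genes outside the background")
  }
  N <- length(background)
  n <- length(gene_set)
  res <- lapply(names(term_genes), function(term) {
    ann <- intersect(term_genes[[term]], background)
    K <- length(ann)
    k <- length(intersect(gene_set, ann))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Relative qPCR expression by the 2^-dCT method
#'
#' Technical-replicate CT values are averaged per sample and gene first;
#' dCT is the target's mean CT minus the mean CT of the reference genes in
#' the same sample, and relative expression is `2^-dCT`.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (replicate
#'   wells as extra rows).
#' @param reference_genes character vector of reference gene names; every
#'   sample must carry CT values for each of them.
#' @return data.frame with columns `sample`, `gene`, `mean_ct`, `delta_ct`,
#'   `rel_expr` (reference genes excluded from the output rows).
#' @export
delta_ct <- function(ct, reference_genes) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)),
            length(reference_genes) >= 1L)
  agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  out <- NULL
  for (s in unique(agg$sample)) {
    sub <- agg[agg$sample == s, ]
    refs <- sub$ct[match(reference_genes, sub$gene)]
    if (anyNA(refs)) {
      stop("sample ", s, " is missing reference gene CT: ",
           paste(reference_genes[is.na(refs)], collapse = ", "))
    }
    ref_mean <- mean(refs)
    targ <- sub[!sub$gene %in% reference_genes, , drop = FALSE]
    if (nrow(targ) == 0L) next
    d <- targ$ct - ref_mean
    out <- rbind(out, data.frame(sample = s, gene = targ$gene,
                                 mean_ct = targ$ct, delta_ct = d,
                                 rel_expr = 2^(-d),
                                 stringsAsFactors = FALSE))
  }
  out
}
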