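test_that("FPKM matches its formula and invariances", {
  counts <- matrix(c(10L, 0L), 2, 1,
                   dimnames = list(c("g1", "g2"), "L1"))
  counts["g2", 1] <- 999990L  # library total 1e6
  out <- fpkm(counts, c(g1 = 1000, g2 = 500))
  expect_equal(out["g1", "L1"], 10)
  counts["g1", 1] <- 0L
  expect_equal(fpkm(counts, c(g1 = 1000, g2 = 500))["g1", 1], 0)

  set.seed(70)
  m <- matrix(rpois(80, 100), 20, 4,
              dimnames = list(paste0("g", 1:20), paste0("L", 1:4)))
  lens <- setNames(sample(200:2000, 20), rownames(m))
  f <- fpkm(m, lens)
  # cell-by-cell independent recomputation
  for (i in sample(20, 5)) {
    for (j in 1:4) {
      expect_equal(f[i, j], m[i, j] * 1e9 / (lens[[i]] * sum(m[, j])))
    }
  }
  # depth invariance and the FPKM sum identity
  expect_equal(fpkm(m * 3L, lens), f)
  expect_equal(unname(colSums(f * lens) / 1e9), rep(1, 4))

  m0 <- m; m0[, 2] <- 0L
  expect_error(fpkm(m0, lens), "L2")
})

test_that("low-expression filtering removes genes with mean count below 1", {
  counts <- rbind(g1 = c(0L, 1L),   # mean 0.5: removed
                  g2 = c(1L, 1L),   # mean 1.0: kept (boundary)
                  g3 = c(2L, 2L))   # mean 2.0: kept
  colnames(counts) <- c("A", "B")
  kept <- filter_low(counts, 1)
  expect_setequal(rownames(kept), c("g2", "g3"))
  expect_equal(nrow(filter_low(matrix(0L, 3, 2), 1)), 0)
  expect_equal(filter_low(counts, 0), counts)
})

test_that("MAD selection ranks by unscaled MAD with deterministic ties", {
  m <- rbind(flat = rep(5, 5), wavy = c(1, 2, 3, 4, 5))
  expect_identical(mad_select(m, 1), "wavy")
  expect_equal(unname(apply(m, 1, mad, constant = 1)[["wavy"]]), 1)
  expect_setequal(mad_select(m, 2), rownames(m))
  expect_warning(sel <- mad_select(m, 5), "top_n")
  expect_length(sel, 2)
})

test_that("correlation distance has the right fixed points", {
  x <- c(1, 3, 2, 5, 4)
  m <- rbind(a = x, b = 2 * x + 7, c = -x)
  d <- as.matrix(correlation_distance(m))
  expect_equal(d["a", "b"], 0)        # positive affine invariance
  expect_equal(d["a", "c"], 2)
  # construct a pair with known correlation 0.5 by Gram-Schmidt mixing
  set.seed(71)
  u <- scale(rnorm(50))[, 1]
  v <- rnorm(50)
  v <- scale(v - u * sum(u * v) / sum(u * u))[, 1]
  y <- 0.5 * u + sqrt(1 - 0.25) * v
  d2 <- as.matrix(correlation_distance(rbind(p = u, q = y)))
  expect_equal(d2["p", "q"], 0.5, tolerance = 1e-12)
  expect_error(correlation_distance(rbind(a = x, k = rep(1, 5))), "k")
})

test_that("hierarchical clustering recovers planted archetypes", {
  set.seed(72)
  arch <- rbind(c(0, 0, 5, 5, 0, 0), c(5, 0, 0, 0, 0, 5))
  mat <- do.call(rbind, lapply(1:40, function(i) {
    a <- (i %% 2) + 1
    arch[a, ] + rnorm(6, sd = 0.1)
  }))
  rownames(mat) <- paste0("g", 1:40)
  cl <- hcluster_cut(correlation_distance(mat), k = 2)
  truth <- rep(1:2, 20)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, truth), 1)
  one <- hcluster_cut(correlation_distance(mat), k = 1)
  expect_equal(unname(unique(one$assignments)), 1L)
  expect_error(hcluster_cut(correlation_distance(mat), k = 41), "k")
})

test_that("bootstrap QC flags exactly a planted label-permuted outlier", {
  cnt <- simulate_counts(n_genes = 1200, tissues = c("A", "B", "C", "D"),
                         replicates = 3, k = 4,
                         outlier_libraries = "B_R2", seed = 73)
  lg <- log2_fpkm(fpkm(cnt$counts, cnt$lengths))
  qc <- bootstrap_replicate_qc(lg, cnt$groups, n_boot = 300, seed = 74)
  expect_identical(qc$library[qc$flagged], "B_R2")
  expect_true(all(qc$support[!qc$flagged] > 0.9))

  clean <- simulate_counts(n_genes = 1200, tissues = c("A", "B", "C", "D"),
                           replicates = 3, k = 4, seed = 75)
  lg2 <- log2_fpkm(fpkm(clean$counts, clean$lengths))
  qc2 <- bootstrap_replicate_qc(lg2, clean$groups, n_boot = 300, seed = 76)
  expect_false(any(qc2$flagged))
  expect_error(bootstrap_replicate_qc(lg, cnt$groups, n_boot = 0), "n_boot")
  expect_error(bootstrap_replicate_qc(lg[, 1:4],
                                      cnt$groups[colnames(lg)[1:4]]),
               "size 1")
})

test_that("DE test controls type-I error and recovers planted fold changes", {
  set.seed(77)
  n <- 3000
  mu <- rlnorm(n, log(200), 1)
  null_counts <- sapply(1:6, function(j) rnbinom(n, mu = mu, size = 20))
  dimnames(null_counts) <- list(paste0("g", 1:n), paste0("L", 1:6))
  de0 <- de_test(null_counts, paste0("L", 1:3), paste0("L", 4:6))
  frac <- mean(de0$p < 0.01)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.02)

  mu <- pmax(mu, 100)               # planted changes sit at mean >= 100
  up <- sample(n, 300)
  muB <- mu; muB[up] <- mu[up] * 4
  counts <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu, size = 20)),
                  sapply(1:3, function(j) rnbinom(n, mu = muB, size = 20)))
  dimnames(counts) <- list(paste0("g", 1:n), paste0("L", 1:6))
  de <- de_test(counts, paste0("L", 1:3), paste0("L", 4:6))
  sig <- apply_thresholds(de, 0.01, 2)
  expect_gte(mean(paste0("g", up) %in% sig), 0.9)

  dup <- cbind(counts[, 1:3], counts[, 1:3])
  colnames(dup) <- paste0("L", 1:6)
  de_same <- de_test(dup, paste0("L", 1:3), paste0("L", 4:6))
  expect_true(all(de_same$log2fc == 0))
})

test_that("hypergeometric enrichment equals exact enumeration for all
           universes up to N = 12", {
  for (N in 2:12) {
    genes <- paste0("g", seq_len(N))
    for (K in 1:N) {
      for (n in 1:N) {
        k_max <- min(K, n)
        for (k in 0:k_max) {
          if (n - k > N - K) next
          term <- list(t1 = genes[seq_len(K)])
          gene_set <- c(genes[seq_len(k)],
                        if (n - k > 0) genes[K + seq_len(n - k)])
          res <- enrich(gene_set, term, genes)
          expect_equal(res$p, hyper_oracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment degenerate cases behave", {
  genes <- paste0("g", 1:10)
  res <- enrich(genes[1:4], list(all = genes), genes)
  expect_equal(res$p, 1)
  res0 <- enrich(genes[6:9], list(t = genes[1:5]), genes)
  expect_lt(abs(res0$p - 1), 1e-12)  # k = 0: upper tail includes everything
  hit <- enrich(genes[1:4], list(t = genes[1:5]), genes)
  expect_equal(hit$p, 5 / 210, tolerance = 1e-12)
  expect_error(enrich(genes[1:2], list(t = genes), character(0)), "background")
})

test_that("2^-dCT quantification matches hand arithmetic", {
  ct <- data.frame(sample = rep("s1", 4),
                   gene = c("t1", "t2", "PP2A", "UBC18"),
                   ct = c(26, 24, 25, 27))
  out <- delta_ct(ct, c("PP2A", "UBC18"))
  expect_equal(out$rel_expr[out$gene == "t1"], 1)   # equals reference mean
  expect_equal(out$rel_expr[out$gene == "t2"], 4)   # dCT = -2
  ct2 <- rbind(ct, data.frame(sample = "s1", gene = "t1", ct = 24))
  out2 <- delta_ct(ct2, c("PP2A", "UBC18"))         # triplicates averaged
  expect_equal(out2$rel_expr[out2$gene == "t1"], 2)
  ct3 <- ct[ct$gene != "UBC18", ]
  expect_error(delta_ct(ct3, c("PP2A", "UBC18")), "s1")
})
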