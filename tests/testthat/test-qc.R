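test_that("HWE exact test matches hand-enumerated probabilities", {
  expect_equal(hwe_exact_test(2, 0, 2), 6 / 70)
  expect_equal(hwe_exact_test(0, 4, 0), 22 / 70)
  expect_equal(hwe_exact_test(5, 0, 0), 1)    # monomorphic: no test
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE exact test equals exhaustive enumeration for all 2n <= 30", {
  for (n in 1:15) {
    for (n_AA in 0:n) {
      for (n_Aa in 0:(n - n_AA)) {
        n_aa <- n - n_AA - n_Aa
        expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                     oracle_hwe(n_AA, n_Aa, n_aa), tolerance = 1e-12)
      }
    }
  }
})

test_that("variant QC removes low call rate and recovers Wahlund deviants", {
  set.seed(42)
  n <- 100
  # group A fixed ancestral-hom, group B fixed derived-hom at variant 1:
  # pooled HWE fails, within-group HWE is perfect (Wahlund recovery case)
  hapA <- cbind(rep(0L, n), matrix(rbinom(n * 4, 1, 0.5), n))
  hapB <- cbind(rep(1L, n), matrix(rbinom(n * 4, 1, 0.5), n))
  hap <- rbind(hapA, hapB)
  panel <- make_panel(hap, groups = rep(c("A", "B"), each = n / 2))
  # variant 2: 96% call rate
  miss <- seq_len(ceiling(0.04 * n))
  panel$haplotypes[2 * miss - 1, 2] <- NA_integer_
  panel$haplotypes[2 * miss, 2] <- NA_integer_

  res <- filter_variants_two_stage(panel)
  rep <- res$report
  expect_equal(unname(rep$removed_variants[["call_rate"]]), 1)
  expect_equal(rep$recovered_variants, 1)
  expect_equal(rep$final_variants,
               rep$initial_variants - sum(rep$removed_variants) +
                 rep$recovered_variants)
  expect_equal(n_variants(res$panel), 4L)     # lost only the call-rate one
})

test_that("clean HWE-consistent panels pass untouched", {
  set.seed(1)
  hap <- matrix(rbinom(200 * 20, 1, 0.4), 200)
  panel <- make_panel(hap, groups = rep(c("A", "B"), each = 50))
  res <- filter_variants_two_stage(panel)
  expect_equal(sum(res$report$removed_variants), 0)
  expect_equal(n_variants(res$panel), 20L)
})

test_that("pihat identifies duplicates, unrelated pairs and parent-child", {
  set.seed(7)
  L <- 5000
  p <- runif(L, 0.1, 0.9)
  n_ind <- 30
  hap <- matrix(rbinom(2 * n_ind * L, 1, rep(p, each = 2 * n_ind)), 2 * n_ind)
  # sample 2 duplicates sample 1
  hap[3, ] <- hap[1, ]
  hap[4, ] <- hap[2, ]
  # sample 4 is a child of sample 3: one haplotype copied
  hap[7, ] <- hap[5, ]
  panel <- make_panel(hap)
  ph <- relatedness_pihat(panel)
  dup <- ph$pihat[ph$sample_i == "S001" & ph$sample_j == "S002"]
  expect_gt(dup, 0.9)
  pc <- ph$pihat[ph$sample_i == "S003" & ph$sample_j == "S004"]
  expect_gt(pc, 0.45)
  expect_lt(pc, 0.55)
  unrel <- ph$pihat[!(ph$sample_i %in% c("S001", "S002", "S003", "S004")) &
                      !(ph$sample_j %in% c("S001", "S002", "S003", "S004"))]
  expect_lt(max(abs(unrel)), 0.05)
  expect_lt(abs(mean(unrel)), 0.02)
})

test_that("relatedness filtering drops one member per flagged pair", {
  set.seed(8)
  L <- 3000
  p <- runif(L, 0.2, 0.8)
  hap <- matrix(rbinom(12 * L, 1, rep(p, each = 12)), 12)
  hap[3, ] <- hap[1, ]
  hap[4, ] <- hap[2, ]
  panel <- make_panel(hap)
  ph <- relatedness_pihat(panel)
  res <- filter_related_samples(panel, ph)
  expect_length(res$removed, 1)
  expect_true(res$removed %in% c("S001", "S002"))
  expect_equal(n_samples(res$panel), 5L)
})

test_that("monomorphic-only panels are rejected by pihat", {
  hap <- matrix(0L, 8, 50)
  expect_error(relatedness_pihat(make_panel(hap)), "polymorphic")
})

test_that("LD pruning keeps exactly one of a perfectly correlated pair", {
  set.seed(3)
  base <- rbinom(200, 1, 0.5)
  hap <- cbind(base, base, rbinom(200, 1, 0.5))
  panel <- make_panel(hap)
  kept <- ld_prune(panel, window_snps = 10, step_snps = 5)
  expect_equal(kept, c(1L, 3L))
})

test_that("independent SNPs survive pruning; greedy chain rule holds", {
  set.seed(4)
  hap <- matrix(rbinom(400 * 10, 1, 0.5), 400)
  panel <- make_panel(hap)
  expect_equal(ld_prune(panel, window_snps = 10, step_snps = 5), 1:10)

  # chain: r2(A,B) and r2(B,C) high, r2(A,C) low -> keep A and C
  # (B mixes A with an independent signal N; C tracks N, so A and C are
  # nearly independent while both correlate with B)
  a <- rbinom(400, 1, 0.5)
  nn <- rbinom(400, 1, 0.5)
  b <- ifelse(runif(400) < 0.5, a, nn)
  cc <- ifelse(runif(400) < 0.02, 1 - nn, nn)
  panel2 <- make_panel(cbind(a, b, cc))
  r2 <- cor(dosage(panel2))^2
  # premise of the chain example (deterministic under the fixed seed)
  expect_gt(r2[1, 2], 0.2)
  expect_gt(r2[2, 3], 0.2)
  expect_lt(r2[1, 3], 0.2)
  kept <- ld_prune(panel2, window_snps = 10, step_snps = 5, maf_min = 0.05)
  expect_equal(kept, c(1L, 3L))
})

test_that("pruned sets satisfy the within-window r2 guarantee", {
  sim <- sim_small(seed = 12)
  kept <- ld_prune(sim$panel, window_snps = 50, step_snps = 5)
  g <- dosage(sim$panel)
  # brute force: every surviving pair guaranteed to share a window
  # (candidate distance up to window - step)
  maf <- minor_freq(sim$panel)
  cand <- unname(which(maf >= 0.05 & maf > 0))
  pos <- match(kept, cand)
  for (a in seq_along(kept)[-length(kept)]) {
    for (b in (a + 1):length(kept)) {
      if (pos[b] - pos[a] > 45) break
      r2 <- suppressWarnings(cor(g[, kept[a]], g[, kept[b]]))^2
      if (!is.na(r2)) expect_lte(r2, 0.2 + 1e-12)
    }
  }
})

test_that("PCA loadings are orthonormal and scores separate populations", {
  sim <- simulate_panel(sim_config(n_founders = 400, pop_size = 80,
                                   n_generations_burnin = 10,
                                   split_generation = 20,
                                   chrom_length_cM = 30, n_variants = 3000,
                                   seed = 31))
  kept <- ld_prune(sim$panel)
  pca <- pca_top_k(sim$panel, k = 10, variant_idx = kept)
  gram <- crossprod(pca$loadings)
  expect_equal(gram, diag(10), tolerance = 1e-8, ignore_attr = TRUE)
  pc1 <- pca$scores$PC1
  g1 <- sim$panel$samples$group == "pop1"
  # complete separation: the two groups' PC1 ranges do not overlap
  expect_true(max(pc1[g1]) < min(pc1[!g1]) || min(pc1[g1]) > max(pc1[!g1]))
})

test_that("a synthetic contaminant far out on PC1 is removed", {
  set.seed(5)
  hap <- matrix(rbinom(60 * 2000, 1, rep(runif(2000, 0.2, 0.8), each = 60)), 60)
  # contaminant: different founder pool (inverted frequencies)
  hap[59, ] <- rbinom(2000, 1, 0.95)
  hap[60, ] <- rbinom(2000, 1, 0.95)
  panel <- make_panel(hap)
  pca <- pca_top_k(panel, k = 5)
  out <- pc_outlier_filter(pca, n_sd = 3)
  expect_true("S030" %in% out$sample_id)
})

test_that("rank-deficient requests are truncated with a warning", {
  set.seed(6)
  hap <- matrix(rbinom(8 * 100, 1, 0.5), 8)
  panel <- make_panel(hap)
  expect_warning(pca <- pca_top_k(panel, k = 10), "rank")
  expect_lte(ncol(pca$loadings), 4)
})

test_that("qc report arithmetic reconciles with the printed cohort counts", {
  expect_equal(qc_reconcile(622926, 65826, 3033), 560133)
})
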