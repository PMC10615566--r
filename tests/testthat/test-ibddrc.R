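test_that("identical haplotypes yield one full-length perfect segment", {
  set.seed(20)
  L <- 500
  a <- rbinom(L, 1, 0.5)
  hap <- rbind(a, a, rbinom(L, 1, 0.5), rbinom(L, 1, 0.5))
  cM <- seq(0, 10, length.out = L)
  panel <- make_panel(hap, cM = cM)
  seg <- detect_ibd(panel, min_length_cM = 2, pairs = cbind(1, 2))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$quality, 1)
  expect_equal(seg$length_cM, 10, tolerance = 0.05)
})

test_that("a dense mismatch cluster splits a segment in two", {
  set.seed(21)
  L <- 1000
  a <- rbinom(L, 1, 0.5)
  b <- a
  # 5 clustered mismatches mid-chromosome, one marker apart
  bad <- c(498, 500, 502, 504, 506)
  b[bad] <- 1 - b[bad]
  cM <- seq(0, 10, length.out = L)
  panel <- make_panel(rbind(a, b), cM = cM)
  seg <- detect_ibd(panel, min_length_cM = 1, pairs = cbind(1, 2))
  expect_equal(nrow(seg), 2L)
  expect_lt(seg$end_cM[1], cM[min(bad)])
  expect_gt(seg$start_cM[2], cM[max(bad)])
})

test_that("an isolated mismatch is absorbed when density allows", {
  a <- rbinom(800, 1, 0.5)
  b <- a
  b[400] <- 1 - b[400]
  cM <- seq(0, 8, length.out = 800)
  panel <- make_panel(rbind(a, b), cM = cM)
  seg <- detect_ibd(panel, min_length_cM = 2, pairs = cbind(1, 2))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$length_cM, 8, tolerance = 0.05)
  expect_equal(seg$quality, 1 - 1 / 800, tolerance = 1e-9)
})

test_that("unrelated founder haplotypes rarely share long segments", {
  set.seed(22)
  false_pos <- 0
  for (trial in 1:50) {
    p <- runif(1000, 0.05, 0.95)
    hap <- matrix(rbinom(4 * 1000, 1, rep(p, each = 4)), 4)
    panel <- make_panel(hap, cM = seq(0, 10, length.out = 1000))
    seg <- detect_ibd(panel, min_length_cM = 2, pairs = cbind(c(1, 3), c(2, 4)))
    false_pos <- false_pos + (nrow(seg) > 0)
  }
  expect_lte(false_pos / 50, 0.05)
})

test_that("detector recalls simulator ground-truth tracts >= 2 cM", {
  sim <- simulate_panel(sim_config(n_founders = 400, pop_size = 50,
                                   n_generations_burnin = 10,
                                   split_generation = 10, n_variants = 2000,
                                   chrom_length_cM = 20, seed = 55),
                        track_ancestry = TRUE)
  pairs <- t(utils::combn(60, 2))
  truth <- true_ibd_segments(sim$truth, sim$panel, pairs = pairs,
                             min_length_cM = 2)
  got <- detect_ibd(sim$panel, min_length_cM = 1, pairs = pairs)
  hit <- 0
  for (i in seq_len(nrow(truth))) {
    cand <- got[got$hap_i == truth$hap_i[i] & got$hap_j == truth$hap_j[i], ]
    ov <- pmin(cand$end_cM, truth$end_cM[i]) - pmax(cand$start_cM,
                                                    truth$start_cM[i])
    hit <- hit + any(ov >= 0.8 * truth$length_cM[i])
  }
  expect_gte(hit / nrow(truth), 0.8)
})

test_that("segment age follows the 50/length rule", {
  expect_equal(estimate_age(1), 50)
  expect_equal(estimate_age(0.5), 100)
  expect_equal(estimate_age(2.5), 20)
  expect_error(estimate_age(0), "positive")
  expect_error(estimate_age(-1), "positive")
})

test_that("DRC bins follow the quality-sum definition with pair dedup", {
  seg <- tibble::tibble(hap_i = c(1, 1, 2), hap_j = c(2, 3, 3),
                        chrom = "chr1",
                        start_cM = c(0.01, 0.02, 0.01),
                        end_cM = c(0.04, 0.04, 0.04),
                        quality = c(1, 0.8, 0.5),
                        age_hat = c(10, 30, 100))
  b <- drc_bins(seg, n_haplotypes = 10, chrom_length_cM = 0.05)
  expect_equal(b$drc_50[1], (1 + 0.8) / 45)
  expect_equal(b$drc_150[1], (1 + 0.8 + 0.5) / 45)
  expect_gte(b$drc_150[1], b$drc_50[1])

  # the same pair's overlapping segments count once (the better quality)
  seg2 <- tibble::tibble(hap_i = c(1, 1), hap_j = c(2, 2), chrom = "chr1",
                         start_cM = c(0, 0.02), end_cM = c(0.04, 0.05),
                         quality = c(0.9, 0.7), age_hat = c(10, 20))
  b2 <- drc_bins(seg2, n_haplotypes = 4, chrom_length_cM = 0.05)
  expect_equal(b2$drc_50[1], 0.9 / 6)

  empty <- seg[0, ]
  b3 <- drc_bins(empty, n_haplotypes = 4, chrom_length_cM = 0.2)
  expect_true(all(b3$drc_150 == 0))
  expect_error(drc_bins(seg, n_haplotypes = 1), "2 haplotypes")
})

test_that("DRC timescale nesting holds on simulated data", {
  sim <- sim_small(seed = 23)
  seg <- detect_ibd(sim$panel, hap_rows = 1:60)
  b <- drc_bins(seg, n_haplotypes = 60,
                chrom_length_cM = max(sim$panel$variants$cM))
  expect_true(all(b$drc_20 <= b$drc_50 + 1e-12))
  expect_true(all(b$drc_50 <= b$drc_150 + 1e-12))
  expect_true(all(b$drc_150 >= 0 & b$drc_150 <= 1))
})

test_that("Gamma null recovery, outlier exclusion and degenerate input", {
  set.seed(24)
  x <- rgamma(5000, shape = 2, rate = 3)
  null <- fit_gamma_null(x, alpha_exclude = 1e-6)
  expect_equal(null$shape, 2, tolerance = 0.1)
  expect_equal(null$rate, 3, tolerance = 0.15)
  expect_true(null$converged)
  expect_length(null$excluded, 0)
  expect_equal(null$n_iterations, 1)

  # outliers at 50x the mean are excluded; parameters barely move
  x2 <- c(x, rep(50 * mean(x), 10))
  null2 <- fit_gamma_null(x2, alpha_exclude = 1e-6)
  expect_true(all(5001:5010 %in% null2$excluded))
  expect_lt(abs(null2$shape - null$shape) / null$shape, 0.02)
  expect_lt(abs(null2$rate - null$rate) / null$rate, 0.02)

  expect_error(fit_gamma_null(rep(0.5, 200)), "degenerate|identical")
  expect_error(fit_gamma_null(rgamma(50, 2)), "100")
})

test_that("Gamma-null p-values are calibrated survival probabilities", {
  set.seed(25)
  x <- rgamma(2000, 2, 3)
  null <- fit_gamma_null(x, alpha_exclude = 1e-5)
  expect_equal(drc_pvalues(0, null), 1)
  med <- qgamma(0.5, null$shape, null$rate)
  expect_equal(drc_pvalues(med, null), 0.5, tolerance = 1e-9)
  p <- drc_pvalues(x, null)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
})
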