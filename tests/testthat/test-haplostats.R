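test_that("EHH follows the carrier-group combinatorics", {
  # 4 derived carriers split into two groups of 2 at the flanking marker
  hap <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 1, 1), c(1, 1, 1),
               c(0, 0, 0), c(0, 1, 0))
  hap <- hap[, c(2, 1, 3)]  # core in the middle
  panel <- make_panel(hap, cM = c(0, 0.1, 0.2))
  cv <- ehh_curve(panel, 2, "derived")
  expect_equal(cv$ehh[cv$distance_cM == 0], 1)
  expect_equal(cv$ehh[cv$distance_cM < 0], 2 * choose(2, 2) / choose(4, 2))
})

test_that("EHH is 1 at the core and 0 once all carriers are distinct", {
  hap <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  panel <- make_panel(hap, cM = c(0.0, 0.1, 0.2))
  cv <- ehh_curve(panel, 1, "derived")
  expect_equal(cv$ehh[cv$distance_cM == 0], 1)
  expect_equal(cv$ehh[cv$distance_cM == 0.2], 0)
  expect_true(all(diff(cv$ehh[cv$distance_cM >= 0]) <= 1e-12))
})

test_that("fewer than two carriers is an error", {
  hap <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 1))
  panel <- make_panel(hap)
  expect_error(ehh_curve(panel, 1, "derived"), "2 carrier")
})

test_that("EHH equals the brute-force group-enumeration oracle", {
  set.seed(99)
  sim <- simulate_panel(sim_config(n_founders = 60, pop_size = 12,
                                   n_generations_burnin = 8,
                                   split_generation = 4, n_variants = 200,
                                   chrom_length_cM = 15, seed = 77))
  panel <- subset_panel(sim$panel, samples = 1:24)   # 48 haplotypes
  hap <- panel$haplotypes
  p <- colMeans(hap)
  cores <- sample(which(p >= 0.2 & p <= 0.8), 20)
  for (core in cores) {
    for (al in c(1L, 0L)) {
      cv <- ehh_curve(panel, core, if (al == 1) "derived" else "ancestral")
      pos0 <- which(cv$distance_cM == 0)
      midx <- core + (seq_len(nrow(cv)) - pos0)   # curve rows are consecutive markers
      pts <- which(cv$distance_cM != 0)
      for (k in pts) {
        expect_equal(cv$ehh[k], oracle_ehh(hap, core, al, midx[k]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("iHH integration applies the cutoff-crossing trapezoid rule", {
  # EHH == 1 out to 0.2 cM then the chromosome ends: rectangle, edge flag
  c1 <- tibble::tibble(distance_cM = c(0, 0.1, 0.2), ehh = c(1, 1, 1))
  r1 <- integrate_ihh(c1)
  expect_equal(r1$ihh, 0.2)
  expect_true(r1$edge_truncated)

  # per side: trapezoids 0.075 + 0.027, stop at the 0.2 marker (EHH < 0.05)
  c2 <- tibble::tibble(distance_cM = c(-0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3),
                       ehh = c(0.04, 0.04, 0.5, 1, 0.5, 0.04, 0.04))
  r2 <- integrate_ihh(c2)
  expect_equal(r2$ihh, 2 * 0.102)
  expect_false(r2$edge_truncated)

  # first flanking marker already below cutoff: that trapezoid only
  c3 <- tibble::tibble(distance_cM = c(0, 0.1, 0.2), ehh = c(1, 0.01, 0.01))
  r3 <- integrate_ihh(c3)
  expect_equal(r3$ihh, (1 + 0.01) / 2 * 0.1)
})

test_that("scan-path iHH agrees with the curve + integration path", {
  sim <- sim_small(seed = 14)
  panel <- sim$panel
  sc <- ihs_scan(panel, maf_min = 0.05)
  pick <- sc[sample.int(nrow(sc), 15), ]
  for (i in seq_len(nrow(pick))) {
    core <- which(panel$variants$bp == pick$bp[i])
    d <- integrate_ihh(ehh_curve(panel, core, "derived"))
    a <- integrate_ihh(ehh_curve(panel, core, "ancestral"))
    expect_equal(pick$ihh_d[i], d$ihh, tolerance = 1e-10)
    expect_equal(pick$ihh_a[i], a$ihh, tolerance = 1e-10)
  }
})

test_that("raw iHS is the log iHH ratio, antisymmetric under polarity flips", {
  expect_equal(log(0.2 / 0.1), log(2))
  sim <- sim_small(seed = 15)
  sc <- ihs_scan(sim$panel, maf_min = 0.05)
  # global polarity flip negates every raw score
  flipped <- sim$panel
  flipped$haplotypes <- 1L - flipped$haplotypes
  sc2 <- ihs_scan(flipped, maf_min = 0.05)
  expect_equal(sc2$ihs_raw, -sc$ihs_raw, tolerance = 1e-12)
  # iHH_A == iHH_D gives a raw score of exactly zero
  expect_equal(sc$ihs_raw[sc$ihh_a == sc$ihh_d],
               rep(0, sum(sc$ihh_a == sc$ihh_d)))
})

test_that("variants with undetermined ancestral state are excluded", {
  sim <- sim_small(seed = 16)
  sim$panel$variants$ancestral_missing[10:20] <- TRUE
  sc <- ihs_scan(sim$panel, maf_min = 0)
  expect_false(any(sc$bp %in% sim$panel$variants$bp[10:20]))
})

test_that("bin normalisation is an exact z-score within DAF bins", {
  rec <- tibble::tibble(daf = c(0.105, 0.108, 0.102, 0.655),
                        ihs_raw = c(-1, 0, 1, 0.5))
  out <- normalize_ihs(rec)
  expect_equal(out$ihs_norm[1:3], c(-1, 0, 1))
  expect_true(out$norm_undefined[4])   # single record in its bin
  expect_true(is.na(out$ihs_norm[4]))
})

test_that("occupied bins have mean 0 and SD 1 after normalisation", {
  sim <- sim_small(seed = 17)
  sc <- normalize_ihs(ihs_scan(sim$panel))
  bin <- ceiling(sc$daf * 100)
  for (b in unique(bin[!sc$norm_undefined])) {
    z <- sc$ihs_norm[bin == b & !sc$norm_undefined]
    if (length(z) >= 2) {
      expect_lt(abs(mean(z)), 1e-10)
      expect_lt(abs(sd(z) - 1), 1e-10)
    }
  }
})

test_that("iHS p-values are two-sided standard normal", {
  expect_equal(ihs_pvalue(0), 1)
  expect_equal(ihs_pvalue(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(ihs_pvalue(-1.959964), 0.05, tolerance = 1e-6)
  # |z| where p crosses the main-scan genome-wide threshold
  expect_equal(qnorm(3.165e-8, lower.tail = FALSE), 5.41, tolerance = 0.01)
})
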