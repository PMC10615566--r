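#' Hudson's per-SNP F_ST
#'
#' The Hudson estimator in its ratio form: numerator
#' `N = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and
#' denominator `D = p1 (1 - p2) + p2 (1 - p1)`, with `fst = N / D`. Sites
#' monomorphic in the pooled sample have `D = 0` and are flagged
#' `monomorphic` (fst `NA`), never silently dropped.
#'
#' @param p1,p2 derived-allele frequencies in the two populations
#'   (vectors accepted).
#' @param n1,n2 allele sample sizes (numbers of haplotypes), at least 2.
#' @return tibble with `p1`, `n1`, `p2`, `n2`, `N_term`, `D_term`, `fst`,
#'   `monomorphic`.
#' @export
hudson_fst_snp <- function(p1, n1, p2, n2) {
  if (any(c(n1, n2) < 2)) stop("allele sample sizes must be >= 2", call. = FALSE)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  mono <- D == 0
  tibble(p1 = p1, n1 = n1, p2 = p2, n2 = n2,
         N_term = N, D_term = D,
         fst = ifelse(mono, NA_real_, N / D),
         monomorphic = mono)
}

#' Per-variant Hudson F_ST scan between two groups
#'
#' @param panel a [haplotype_panel] with a `group` column.
#' @param group_a,group_b the two subpopulation labels to contrast.
#' @param maf_min pooled minor-allele-frequency floor (default 0.01; set 0 to
#'   keep everything).
#' @return tibble of class `fst_scan`: `chrom`, `bp`, `cM` plus the
#'   [hudson_fst_snp()] columns, monomorphic-in-pool sites excluded and
#'   counted in the `n_excluded` attribute.
#' @export
fst_scan <- function(panel, group_a, group_b, maf_min = 0.01) {
  ra <- .group_hap_rows(panel, group_a)
  rb <- .group_hap_rows(panel, group_b)
  ha <- panel$haplotypes[ra, , drop = FALSE]
  hb <- panel$haplotypes[rb, , drop = FALSE]
  p1 <- colMeans(ha, na.rm = TRUE)
  p2 <- colMeans(hb, na.rm = TRUE)
  n1 <- colSums(!is.na(ha))
  n2 <- colSums(!is.na(hb))
  pool <- colMeans(rbind(ha, hb), na.rm = TRUE)
  pass <- pmin(pool, 1 - pool) >= maf_min & n1 >= 2 & n2 >= 2
  rec <- hudson_fst_snp(p1[pass], n1[pass], p2[pass], n2[pass])
  out <- dplyr::bind_cols(panel$variants[pass, c("chrom", "bp", "cM")], rec)
  keep <- !out$monomorphic
  res <- out[keep, , drop = FALSE]
  structure(res, class = c("fst_scan", class(res)),
            groups = c(group_a, group_b), n_excluded = sum(!keep))
}

#' Weighted mean F_ST with block-jackknife standard error
#'
#' The multi-SNP summary is the ratio of averages `sum(N) / sum(D)`. Its
#' standard error comes from a delete-one-block jackknife over `n_blocks`
#' contiguous variant blocks:
#' `SE = sqrt((B - 1)/B * sum((theta_b - theta_bar)^2))`.
#'
#' @param records tibble with `N_term` and `D_term` columns (e.g. from
#'   [fst_scan()]); `NA` rows are dropped.
#' @param n_blocks number of contiguous jackknife blocks (default 100; if
#'   fewer records are available, one record per block with a warning).
#' @return object of class `fst_mean` with fields `fst`, `se`, `n_records`,
#'   `n_blocks`; `se` is `NA` (flagged) with fewer than 2 blocks.
#' @export
weighted_mean_fst <- function(records, n_blocks = 100) {
  ok <- !is.na(records$N_term) & !is.na(records$D_term) & records$D_term > 0
  N <- records$N_term[ok]
  D <- records$D_term[ok]
  if (!length(N)) stop("no usable records", call. = FALSE)
  est <- sum(N) / sum(D)
  B <- min(n_blocks, length(N))
  if (B < n_blocks) {
    warning("only ", length(N), " records; using ", B, " jackknife blocks",
            call. = FALSE)
  }
  se <- NA_real_
  if (B >= 2) {
    blk <- cut(seq_along(N), breaks = B, labels = FALSE)
    sN <- tapply(N, blk, sum)
    sD <- tapply(D, blk, sum)
    theta <- (sum(N) - sN) / (sum(D) - sD)
    se <- sqrt((B - 1) / B * sum((theta - mean(theta))^2))
  }
  structure(list(fst = est, se = se, n_records = length(N), n_blocks = B),
            class = "fst_mean")
}

#' @export
print.fst_mean <- function(x, ...) {
  cat("<fst_mean> F_ST =", format(x$fst, digits = 4),
      "+/-", format(x$se, digits = 4),
      "(", x$n_records, "SNPs,", x$n_blocks, "jackknife blocks )\n")
  invisible(x)
}

#' @export
tidy.fst_mean <- function(x, ...) {
  tibble(term = "fst", estimate = x$fst, std.error = x$se)
}

#' @export
glance.fst_mean <- function(x, ...) {
  tibble(fst = x$fst, se = x$se, n_records = x$n_records,
         n_blocks = x$n_blocks)
}

#' Pairwise weighted F_ST matrix between subpopulations
#'
#' @param panel a [haplotype_panel] with a `group` column.
#' @param groups labels to compare (default: all groups in the panel).
#' @param maf_min pooled MAF floor per pair.
#' @param n_blocks jackknife blocks for the standard error.
#' @return tibble with `population1`, `population2`, `fst`, `se`.
#' @export
pairwise_fst <- function(panel, groups = NULL, maf_min = 0.01,
                         n_blocks = 100) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  combs <- utils::combn(groups, 2)
  purrr::map_dfr(seq_len(ncol(combs)), function(i) {
    sc <- fst_scan(panel, combs[1, i], combs[2, i], maf_min = maf_min)
    wm <- suppressWarnings(weighted_mean_fst(sc, n_blocks = n_blocks))
    tibble(population1 = combs[1, i], population2 = combs[2, i],
           fst = wm$fst, se = wm$se)
  })
}

#' Approximate one-sided p-values for per-SNP F_ST
#'
#' Per-SNP F_ST behaves like a scaled chi-square with one degree of freedom.
#' The scale is fitted by the method of moments on the positive part of the
#' statistics (`c_hat = mean(max(fst, 0))`, since a chi-square(1) has mean 1)
#' and the one-sided upper-tail p-value is the chi-square survival function
#' at `max(fst, 0) / c_hat`. Non-positive estimates get p = 1. Negative
#' per-SNP values are clipped only inside this fit, never in reported `fst`.
#'
#' @param records tibble with an `fst` column (e.g. an [fst_scan()]).
#' @param df chi-square degrees of freedom for the fit (default 1).
#' @return the records with a `p_fst` column; the fitted scale is in the
#'   `c_hat` attribute.
#' @export
fst_pvalues <- function(records, df = 1) {
  x <- pmax(records$fst, 0)
  x <- x[!is.na(x)]
  if (!length(x) || all(x == 0)) {
    stop("cannot fit the null: no positive F_ST estimates", call. = FALSE)
  }
  c_hat <- mean(x) / df
  records$p_fst <- ifelse(is.na(records$fst), NA_real_,
                          pchisq(pmax(records$fst, 0) / c_hat, df = df,
                                 lower.tail = FALSE))
  attr(records, "c_hat") <- c_hat
  records
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1, upper-tail p.
#'
#' @param count_table 2x2 matrix of non-negative counts with positive
#'   margins.
#' @return tibble with `statistic` and `p.value`.
#' @export
chi2_2x2 <- function(count_table) {
  count_table <- as.matrix(count_table)
  stopifnot(all(dim(count_table) == c(2, 2)))
  if (any(count_table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(count_table) == 0) || any(colSums(count_table) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(count_table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}

#' Haplotype linkage disequilibrium r-squared
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB` estimated from
#' phased haplotype counts.
#'
#' @param panel a [haplotype_panel].
#' @param idx_a,idx_b variant indices.
#' @return r-squared (scalar); error when either site is monomorphic.
#' @export
ld_r2 <- function(panel, idx_a, idx_b) {
  a <- panel$haplotypes[, idx_a]
  b <- panel$haplotypes[, idx_b]
  ok <- !is.na(a) & !is.na(b)
  pA <- mean(a[ok])
  pB <- mean(b[ok])
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic site: r-squared undefined", call. = FALSE)
  }
  pAB <- mean(a[ok] == 1 & b[ok] == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}
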