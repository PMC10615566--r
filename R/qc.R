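#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test: under the conditional distribution of the
#' heterozygote count given the allele counts, the p-value sums the
#' probabilities of all heterozygote counts whose probability does not exceed
#' that of the observed count. Monomorphic input is no test: p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#'   Vectors are accepted and recycled to a common length.
#' @return numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  args <- cbind(n_AA, n_Aa, n_aa)
  vapply(seq_len(nrow(args)), function(i) {
    .hwe_exact_one(args[i, 1], args[i, 2], args[i, 3])
  }, numeric(1))
}

.hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(is.na(c(n_AA, n_Aa, n_aa)))) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("genotype counts must not all be zero", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)          # monomorphic: no test
  # possible heterozygote counts share the parity of nA
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Genotype counts per variant
#' @param panel a [haplotype_panel].
#' @return tibble with `n_AA` (ancestral hom), `n_Aa`, `n_aa` (derived hom)
#'   and `call_rate` per variant.
#' @keywords internal
.genotype_counts <- function(panel) {
  d <- dosage(panel)
  tibble(n_AA = colSums(d == 0, na.rm = TRUE),
         n_Aa = colSums(d == 1, na.rm = TRUE),
         n_aa = colSums(d == 2, na.rm = TRUE),
         call_rate = colMeans(!is.na(d)))
}

#' Variant QC with two-stage Hardy-Weinberg recovery
#'
#' Removes variants with a sample call rate below `call_rate_min` or a pooled
#' HWE exact p below `hwe_alpha`. Deviation from HWE in pooled data can be a
#' mere consequence of population structure (the Wahlund effect), so a variant
#' failing only the pooled HWE test is recovered when it passes HWE at the
#' same level in every subpopulation separately (subgroups with fewer than 2
#' genotyped samples are skipped with a warning).
#'
#' @param panel a [haplotype_panel] with a `group` column in its sample table
#'   (see [set_groups()]).
#' @param call_rate_min minimum variant call rate.
#' @param hwe_alpha HWE exact-test significance level.
#' @return list with `panel` (filtered) and `report` (a `qc_report`).
#' @export
filter_variants_two_stage <- function(panel, call_rate_min = 0.97,
                                      hwe_alpha = 1e-6) {
  if (!"group" %in% names(panel$samples)) {
    stop("panel samples need a group column; see set_groups()", call. = FALSE)
  }
  cnt <- .genotype_counts(panel)
  fail_cr <- cnt$call_rate < call_rate_min
  informative <- (cnt$n_AA + cnt$n_Aa + cnt$n_aa) > 0
  hwe_p <- rep(1, nrow(cnt))
  hwe_p[informative] <- hwe_exact_test(cnt$n_AA[informative],
                                       cnt$n_Aa[informative],
                                       cnt$n_aa[informative])
  fail_hwe <- hwe_p < hwe_alpha
  removed <- fail_cr | fail_hwe

  # stage two: re-test HWE-only failures within each subgroup
  cand <- which(fail_hwe & !fail_cr)
  recovered <- integer(0)
  if (length(cand)) {
    groups <- unique(panel$samples$group)
    pass_all <- rep(TRUE, length(cand))
    for (g in groups) {
      sub <- subset_panel(panel, variants = cand,
                          samples = panel$samples$group == g)
      sc <- .genotype_counts(sub)
      n_typed <- sc$n_AA + sc$n_Aa + sc$n_aa
      if (all(n_typed < 2)) {
        warning("subgroup '", g, "' has < 2 genotyped samples; skipped",
                call. = FALSE)
        next
      }
      ok <- n_typed > 0
      pg <- rep(1, length(cand))
      pg[ok] <- hwe_exact_test(sc$n_AA[ok], sc$n_Aa[ok], sc$n_aa[ok])
      pass_all <- pass_all & pg >= hwe_alpha
    }
    recovered <- cand[pass_all]
  }

  keep <- !removed
  keep[recovered] <- TRUE
  report <- qc_report(
    initial_variants = nrow(cnt),
    removed_variants = c(call_rate = sum(fail_cr),
                         hwe = sum(fail_hwe & !fail_cr)),
    recovered_variants = length(recovered),
    thresholds = list(call_rate_min = call_rate_min, hwe_alpha = hwe_alpha))
  list(panel = subset_panel(panel, variants = keep), report = report)
}

#' QC bookkeeping report
#'
#' @param initial_variants variant count before filtering.
#' @param removed_variants named counts of removed variants by reason.
#' @param recovered_variants variants restored by the subgroup HWE re-test.
#' @param removed_samples named counts of removed samples by reason.
#' @param thresholds list of thresholds used.
#' @return a `qc_report`; `final_variants` always reconciles as
#'   initial - removed + recovered.
#' @export
qc_report <- function(initial_variants, removed_variants = c(),
                      recovered_variants = 0, removed_samples = c(),
                      thresholds = list()) {
  stopifnot(all(removed_variants >= 0), recovered_variants >= 0)
  structure(list(
    initial_variants = initial_variants,
    removed_variants = removed_variants,
    recovered_variants = recovered_variants,
    final_variants = qc_reconcile(initial_variants, sum(removed_variants),
                                  recovered_variants),
    removed_samples = removed_samples,
    thresholds = thresholds), class = "qc_report")
}

#' Reconcile QC variant counts
#'
#' @param initial,removed,recovered variant counts.
#' @return `initial - removed + recovered`.
#' @export
qc_reconcile <- function(initial, removed, recovered) {
  initial - removed + recovered
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  variants:", x$initial_variants, "-", sum(x$removed_variants),
      "+", x$recovered_variants, "=", x$final_variants, "\n")
  if (length(x$removed_variants)) {
    cat("   removed by reason:",
        paste(names(x$removed_variants), x$removed_variants, sep = "=",
              collapse = ", "), "\n")
  }
  if (length(x$removed_samples)) {
    cat("  samples removed:",
        paste(names(x$removed_samples), x$removed_samples, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    stage = c("initial", paste0("removed_", names(x$removed_variants)),
              "recovered", "final"),
    n = c(x$initial_variants, -as.numeric(x$removed_variants),
          x$recovered_variants, x$final_variants))
}

#' Pairwise relatedness (PI_HAT)
#'
#' Method-of-moments IBD estimation from identity-by-state counts with
#' allele-frequency correction (the PLINK `--genome` estimator): per pair,
#' the probabilities of sharing 0/1/2 alleles identical by descent are solved
#' from the observed IBS0/IBS1/IBS2 counts and their allele-frequency
#' expectations, and `pihat = P(IBD=1)/2 + P(IBD=2)`, clipped to the unit interval.
#' Only variants with complete genotypes are used.
#'
#' @param panel a [haplotype_panel].
#' @param variant_idx optional variant subset (typically LD-pruned).
#' @return tibble with `sample_i`, `sample_j`, `pihat`.
#' @export
relatedness_pihat <- function(panel, variant_idx = NULL) {
  g <- dosage(panel)
  if (!is.null(variant_idx)) g <- g[, variant_idx, drop = FALSE]
  g <- g[, colSums(is.na(g)) == 0, drop = FALSE]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no informative (polymorphic) variants", call. = FALSE)
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  V <- ncol(g)

  A0 <- (g == 0) + 0
  A1 <- (g == 1) + 0
  A2 <- (g == 2) + 0
  ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  ibs1 <- V - ibs0 - ibs2

  e00 <- sum(2 * p^2 * q^2)
  e10 <- sum(4 * p^3 * q + 4 * p * q^3)
  e11 <- sum(2 * p * q)
  e20 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e21 <- sum(1 - 2 * p * q)

  P0 <- ibs0 / e00
  P1 <- (ibs1 - P0 * e10) / e11
  P2 <- (ibs2 - P0 * e20 - P1 * e21) / V
  pihat <- pmin(pmax(P1 / 2 + P2, 0), 1)

  ut <- which(upper.tri(pihat), arr.ind = TRUE)
  tibble(sample_i = panel$samples$sample_id[ut[, 1]],
         sample_j = panel$samples$sample_id[ut[, 2]],
         pihat = pihat[ut])
}

#' Remove one member of each closely related pair
#'
#' Flags pairs with `pihat >= pihat_max` and removes samples greedily: the
#' sample involved in the most flagged pairs is dropped first; ties are broken
#' by lower sample call rate, then by input order.
#'
#' @param panel a [haplotype_panel].
#' @param pihat tibble from [relatedness_pihat()].
#' @param pihat_max relatedness threshold (default 0.25, i.e. second degree).
#' @return list with `panel` (related samples removed) and `removed`
#'   (character vector of sample ids, in removal order).
#' @export
filter_related_samples <- function(panel, pihat, pihat_max = 0.25) {
  flagged <- pihat[pihat$pihat >= pihat_max, , drop = FALSE]
  ids <- panel$samples$sample_id
  call_rate <- rowMeans(!is.na(dosage(panel)))
  removed <- character(0)
  pairs <- flagged[, c("sample_i", "sample_j")]
  while (nrow(pairs)) {
    deg <- table(factor(c(pairs$sample_i, pairs$sample_j), levels = ids))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      cr <- call_rate[match(cand, ids)]
      cand <- cand[cr == min(cr)]
    }
    drop_id <- cand[which.min(match(cand, ids))]
    removed <- c(removed, drop_id)
    pairs <- pairs[pairs$sample_i != drop_id & pairs$sample_j != drop_id, ,
                   drop = FALSE]
  }
  list(panel = subset_panel(panel, samples = !(ids %in% removed)),
       removed = removed)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` candidate SNPs, pairs with genotype
#' r-squared above `r2_max` lose their later-indexed member; the window then
#' advances by `step_snps`. Candidates are variants with minor allele
#' frequency at least `maf_min`. Every surviving pair that shares a window
#' (candidate distance up to `window_snps - step_snps`) has r-squared at
#' most `r2_max`; with `step_snps = 1` this covers all within-window pairs.
#'
#' @param panel a [haplotype_panel].
#' @param window_snps,step_snps,r2_max pruning parameters (PLINK-style
#'   `--indep-pairwise` semantics; defaults 100, 10, 0.2).
#' @param maf_min minor-allele-frequency floor for candidates.
#' @return integer vector of retained variant indices (into the panel).
#' @export
ld_prune <- function(panel, window_snps = 100, step_snps = 10,
                     r2_max = 0.2, maf_min = 0.05) {
  g <- dosage(panel)
  maf <- minor_freq(panel)
  cand <- unname(which(maf >= maf_min & maf > 0))
  if (!length(cand)) return(integer(0))
  keep <- rep(TRUE, length(cand))
  starts <- seq(1, length(cand), by = step_snps)
  for (st in starts) {
    win <- st:min(st + window_snps - 1, length(cand))
    win <- win[keep[win]]
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(g[, cand[win]], use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    for (i in seq_along(win)[-length(win)]) {
      if (!keep[win[i]]) next
      worse <- which(r2[i, ] > r2_max)
      worse <- worse[worse > i & keep[win[worse]]]
      if (length(worse)) keep[win[worse]] <- FALSE
    }
    if (min(st + window_snps - 1, length(cand)) == length(cand)) break
  }
  cand[keep]
}

#' PCA of a (pruned) genotype panel
#'
#' Principal components of centred, allele-frequency-standardised genotype
#' dosages (each variant scaled by `sqrt(2 p (1-p))`). Loadings are
#' orthonormal; scores are returned for the top `k` components.
#'
#' @param panel a [haplotype_panel].
#' @param k number of components (default 20).
#' @param variant_idx optional variant subset (typically from [ld_prune()]).
#' @return object of class `panel_pca`: list with `scores` (tibble:
#'   `sample_id`, `PC1` ... `PCk`), `loadings` (variants by k), `sdev`.
#' @export
pca_top_k <- function(panel, k = 20, variant_idx = NULL) {
  g <- dosage(panel)
  if (!is.null(variant_idx)) g <- g[, variant_idx, drop = FALSE]
  g <- g[, colSums(is.na(g)) == 0, drop = FALSE]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    warning("requested ", k, " components but rank is ", rank,
            "; returning ", rank, call. = FALSE)
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = panel$samples$sample_id),
                              as_tibble(scores)),
    loadings = sv$v[, seq_len(k), drop = FALSE],
    sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(g) - 1))),
    class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("<panel_pca> ", nrow(x$scores), " samples, ",
      ncol(x$loadings), " components\n", sep = "")
  invisible(x)
}

#' Flag PC outlier samples
#'
#' Single-pass rule: a sample is removed when its PC1 or PC2 score lies more
#' than `n_sd` standard deviations from that component's mean.
#'
#' @param pca a `panel_pca` (or its `scores` tibble).
#' @param n_sd number of standard deviations (default 3).
#' @return tibble of removed samples with `sample_id` and the offending PC.
#' @export
pc_outlier_filter <- function(pca, n_sd = 3) {
  scores <- if (inherits(pca, "panel_pca")) pca$scores else as_tibble(pca)
  out <- lapply(c("PC1", "PC2"), function(pc) {
    z <- scores[[pc]]
    bad <- abs(z - mean(z)) > n_sd * sd(z)
    tibble(sample_id = scores$sample_id[bad], component = pc)
  })
  bind_rows(out) %>% distinct(.data$sample_id, .keep_all = TRUE)
}
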