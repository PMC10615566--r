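# Small builders and independent brute-force oracles used across tests.

# quick panel from a haplotype matrix (rows = haplotypes, even count)
make_panel <- function(hap, cM = NULL, bp = NULL, groups = NULL,
                       ancestral_missing = NULL) {
  hap <- as.matrix(hap)
  L <- ncol(hap)
  if (is.null(bp)) bp <- seq_len(L) * 1000
  if (is.null(cM)) cM <- bp / 1e6 * 1   # 1 cM / Mb
  n_s <- nrow(hap) / 2
  samples <- tibble::tibble(sample_id = sprintf("S%03d", seq_len(n_s)))
  if (!is.null(groups)) samples$group <- groups
  variants <- tibble::tibble(chrom = "chr1", bp = bp, cM = cM,
                             ref = "A", alt = "G", ancestral_is_ref = TRUE,
                             ancestral_missing = ancestral_missing %||%
                               rep(FALSE, L))
  haplotype_panel(hap, samples, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# EHH by direct group enumeration over pasted haplotype strings
oracle_ehh <- function(hap, core, allele, x) {
  car <- which(hap[, core] == allele)
  n <- length(car)
  rng <- if (x >= core) core:x else x:core
  key <- apply(hap[car, rng, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# exact HWE p by exhaustive enumeration of heterozygote counts
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hs == n_Aa] * (1 + 1e-9)])
}

# naive Hudson estimator and delete-one-block jackknife, written directly
# from the definitions
oracle_hudson <- function(p1, n1, p2, n2) {
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D, fst = N / D)
}

oracle_weighted_fst <- function(N, D, n_blocks) {
  B <- n_blocks
  blk <- cut(seq_along(N), breaks = B, labels = FALSE)
  theta <- vapply(seq_len(B), function(b) {
    sum(N[blk != b]) / sum(D[blk != b])
  }, numeric(1))
  list(fst = sum(N) / sum(D),
       se = sqrt((B - 1) / B * sum((theta - mean(theta))^2)))
}

# a tiny deterministic two-group panel with LD structure, used in QC tests
sim_small <- function(seed = 1, ...) {
  simulate_panel(sim_config(n_founders = 200, pop_size = 60,
                            n_generations_burnin = 15, split_generation = 10,
                            chrom_length_cM = 20, n_variants = 600,
                            seed = seed, ...))
}
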