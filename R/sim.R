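#' Simulation configuration for the two-subpopulation forward model
#'
#' Defines a forward Wright-Fisher simulation of one chromosome: founder
#' haplotypes are drawn site-wise from a neutral frequency spectrum
#' (density proportional to 1/x, truncated to `[1/(2 n_founders), 1]`), a
#' panmictic population of `2 * pop_size` diploids evolves for
#' `n_generations_burnin` generations, then splits into two subpopulations of
#' `pop_size` diploids each that evolve independently for `split_generation`
#' generations apart from symmetric migration. Recombination is Poisson with
#' mean `chrom_length_cM / 100` crossovers per meiosis. An optional selective
#' sweep applies multiplicative fitness `(1 + s)` per derived allele copy at
#' the focal site in the targeted subpopulations from
#' `sweep_start_generation` generations before present onward.
#'
#' @param n_founders number of founder haplotypes (even).
#' @param pop_size diploid individuals per subpopulation.
#' @param n_generations_burnin panmictic generations before the split.
#' @param split_generation generations before present at which the split
#'   occurs; `0` keeps the population panmictic to the end.
#' @param migration_rate per-parent per-generation probability of drawing a
#'   parent from the other subpopulation (0 to 0.5).
#' @param chrom_length_cM genetic length of the simulated chromosome.
#' @param n_variants number of biallelic sites.
#' @param sweep optional list with `focal_variant_index` (1-based),
#'   `selection_coefficient`, `sweep_start_generation`, `target_subpops`
#'   (subset of `1:2`), and optionally `focal_founder_freq` to pin the focal
#'   site's founder derived-allele frequency.
#' @param seed integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 1000, pop_size = 500,
                       n_generations_burnin = 10, split_generation = 3,
                       migration_rate = 0, chrom_length_cM = 50,
                       n_variants = 2000, sweep = NULL, seed = 1) {
  counts <- c(n_founders = n_founders, pop_size = pop_size,
              chrom_length_cM = chrom_length_cM, n_variants = n_variants)
  if (any(counts <= 0)) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (n_generations_burnin < 0 || split_generation < 0) {
    stop("generation counts must be non-negative", call. = FALSE)
  }
  if (n_founders %% 2 != 0) stop("n_founders must be even", call. = FALSE)
  if (migration_rate < 0 || migration_rate > 0.5) {
    stop("migration_rate must be in [0, 0.5]", call. = FALSE)
  }
  if (!is.null(sweep)) {
    need <- c("focal_variant_index", "selection_coefficient",
              "sweep_start_generation", "target_subpops")
    if (!all(need %in% names(sweep))) {
      stop("sweep must supply ", paste(need, collapse = ", "), call. = FALSE)
    }
    if (sweep$selection_coefficient < 0) stop("s must be >= 0", call. = FALSE)
    if (sweep$focal_variant_index < 1 ||
        sweep$focal_variant_index > n_variants) {
      stop("focal_variant_index out of range", call. = FALSE)
    }
    if (!all(sweep$target_subpops %in% 1:2)) {
      stop("target_subpops must be a subset of 1:2", call. = FALSE)
    }
  }
  structure(list(n_founders = as.integer(n_founders),
                 pop_size = as.integer(pop_size),
                 n_generations_burnin = as.integer(n_generations_burnin),
                 split_generation = as.integer(split_generation),
                 migration_rate = migration_rate,
                 chrom_length_cM = chrom_length_cM,
                 n_variants = as.integer(n_variants),
                 sweep = sweep, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a phased two-subpopulation haplotype panel
#'
#' Runs the forward model described in [sim_config()] and returns the final
#' generation as a phased panel (alleles coded ancestral = 0 / derived = 1,
#' groups `"pop1"` and `"pop2"`) together with the simulation ground truth.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param track_ancestry if `TRUE`, founder-haplotype ancestry is propagated
#'   per site and true identity-by-descent tracts (since founding) can be
#'   extracted with [true_ibd_segments()].
#' @return list with elements `panel` (a [haplotype_panel]) and `truth`
#'   (class `sim_truth`: `subpop_labels`, `sweep_site`, `expected_fst`,
#'   `seed`, and the ancestry matrix when tracked).
#' @export
simulate_panel <- function(config, track_ancestry = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_variants
  nf <- config$n_founders

  # variant coordinates: ~1 kb spacing, uniform recombination rate
  bp <- as.integer(seq(1000L, by = 1000L, length.out = L))
  cM <- bp / bp[L] * config$chrom_length_cM

  # founder derived-allele frequencies from the neutral SFS ~ 1/x on [a, 1]
  a <- 1 / (2 * nf)
  p <- a ^ (1 - runif(L))
  if (!is.null(config$sweep) && !is.null(config$sweep$focal_founder_freq)) {
    p[config$sweep$focal_variant_index] <- config$sweep$focal_founder_freq
  }
  # site-major founder matrix: rows = sites, columns = founder haplotypes
  founders <- matrix(rbinom(nf * L, 1L, rep(p, times = nf)), nrow = L)

  sw <- config$sweep
  res <- cpp_forward_sim(
    founders, cM,
    pop_size = config$pop_size,
    n_burnin = config$n_generations_burnin,
    split_gen = config$split_generation,
    migration = config$migration_rate,
    sweep_idx = if (is.null(sw)) -1L else sw$focal_variant_index - 1L,
    s = if (is.null(sw)) 0 else sw$selection_coefficient,
    sweep_start = if (is.null(sw)) 0L else as.integer(sw$sweep_start_generation),
    sweep_pop1 = !is.null(sw) && 1L %in% sw$target_subpops,
    sweep_pop2 = !is.null(sw) && 2L %in% sw$target_subpops,
    track_ancestry = track_ancestry)

  n_dip <- 2L * config$pop_size
  samples <- tibble(
    sample_id = sprintf("S%04d", seq_len(n_dip)),
    group = rep(c("pop1", "pop2"), each = config$pop_size))
  variants <- tibble(chrom = "chr1", bp = bp, cM = cM,
                     ref = "A", alt = "G",
                     ancestral_is_ref = TRUE, ancestral_missing = FALSE)
  panel <- haplotype_panel(t(res$haplotypes), samples, variants)

  # rough analytic differentiation at sampling: F_ST ~ t / (2N) per
  # subpopulation lineage pair, ignoring migration
  t <- config$split_generation
  expected_fst <- 1 - (1 - 1 / (2 * config$pop_size)) ^ t

  truth <- structure(
    list(subpop_labels = samples,
         sweep_site = if (is.null(sw)) NA_integer_ else sw$focal_variant_index,
         expected_fst = expected_fst,
         seed = config$seed,
         ancestry = if (track_ancestry) res$ancestry else NULL),
    class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Ground-truth IBD tracts from a tracked simulation
#'
#' Extracts maximal runs over which two haplotypes inherited the same founder
#' haplotype, i.e. tracts identical by descent since founding.
#'
#' @param truth a `sim_truth` from [simulate_panel()] with
#'   `track_ancestry = TRUE`.
#' @param panel the matching [haplotype_panel] (for cM coordinates).
#' @param pairs optional two-column matrix of haplotype index pairs
#'   (1-based); defaults to all pairs.
#' @param min_length_cM shortest tract to report.
#' @return tibble with `hap_i`, `hap_j`, `start_cM`, `end_cM`, `length_cM`.
#' @export
true_ibd_segments <- function(truth, panel, pairs = NULL,
                              min_length_cM = 1) {
  if (is.null(truth$ancestry)) {
    stop("simulation was not run with track_ancestry = TRUE", call. = FALSE)
  }
  if (is.null(pairs)) {
    nh <- ncol(truth$ancestry)      # ancestry is site-major
    pairs <- t(utils::combn(nh, 2))
  }
  seg <- cpp_shared_ancestry_segments(truth$ancestry, panel$variants$cM,
                                      pairs[, 1] - 1L, pairs[, 2] - 1L,
                                      min_length_cM)
  as_tibble(seg) %>% mutate(length_cM = .data$end_cM - .data$start_cM)
}
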