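#' Simulation conditions for the sweep detection study
#'
#' The fixed study design used by [sweep_power_study()]: a 60-cM chromosome
#' with 9,000 markers, two subpopulations of 600 diploids splitting 120
#' generations ago after a 40-generation expansion from 2,000 founder
#' haplotypes, and (optionally) an additive sweep (`s` per derived copy) in
#' the second subpopulation starting 95 generations before present from a
#' founder frequency of 1%. These sizes keep the sweep footprint a small
#' fraction of the simulated genome while a single study runs in minutes.
#'
#' @param seed integer seed.
#' @param s selection coefficient (0 for the matched neutral condition).
#' @return a [sim_config()].
#' @export
sweep_study_config <- function(seed, s = 0.05) {
  sim_config(
    n_founders = 2000, pop_size = 600, n_generations_burnin = 40,
    split_generation = 120, migration_rate = 0, chrom_length_cM = 60,
    n_variants = 9000,
    sweep = if (s > 0) {
      list(focal_variant_index = 4500, selection_coefficient = s,
           sweep_start_generation = 95, target_subpops = 2,
           focal_founder_freq = 0.01)
    } else NULL,
    seed = seed)
}

#' Neutral iHS reference for the sweep detection study
#'
#' Simulates matched neutral panels, scans the target subpopulation, and
#' returns the pooled scan (used as the bin-statistics reference for
#' [normalize_ihs()]) together with the 99th percentile of the neutral
#' |iHS_norm| distribution.
#'
#' @param seed integer seed.
#' @param n_panels number of neutral panels pooled (default 2).
#' @return list with `reference` (pooled `ihs_scan` records) and `q99`.
#' @export
neutral_ihs_reference <- function(seed, n_panels = 2) {
  ref <- NULL
  zs <- c()
  for (i in seq_len(n_panels)) {
    sim <- simulate_panel(sweep_study_config(seed * 10000L + 9900L + i, s = 0))
    sc <- ihs_scan(sim$panel, group = "pop2")
    ref <- if (is.null(ref)) sc else bind_rows(ref, sc)
    zs <- c(zs, abs(normalize_ihs(sc)$ihs_norm))
  }
  list(reference = ref, q99 = unname(quantile(zs, 0.99, na.rm = TRUE)))
}

# DRC detection on one panel: TRUE when some 0.05-cM bin within 1 cM of the
# focal site is significant at the Bonferroni genome-wide level (the scan
# notion of a discovered locus).
.drc_detect <- function(panel, hap_rows, focal_cM, alpha_exclude = 0.01) {
  seg <- detect_ibd(panel, hap_rows = hap_rows)
  bins <- drc_bins(seg, n_haplotypes = length(hap_rows), timescales = 150,
                   chrom_length_cM = max(panel$variants$cM))
  null <- tryCatch(fit_gamma_null(bins$drc_150, alpha_exclude = alpha_exclude),
                   error = function(e) NULL)
  if (is.null(null)) return(FALSE)
  p <- drc_pvalues(bins$drc_150, null)
  mid <- (bins$start_cM + bins$end_cM) / 2
  near <- abs(mid - focal_cM) <= 1
  isTRUE(min(p[near]) <= 0.05 / length(p))
}

#' Sweep detection power study
#'
#' Runs seeded replicates of the sweep condition in [sweep_study_config()],
#' each accepted when the focal derived-allele frequency at sampling falls in
#' `daf_range` (re-seeding up to `max_tries` times; an unaccepted replicate
#' counts as a non-detection). Per replicate three detections are recorded:
#'
#' * `ihs`: the focal variant's |iHS_norm| (standardised against the neutral
#'   reference bins) exceeds the neutral 99th percentile;
#' * `drc`: some DRC_150 bin within 1 cM of the focal site reaches the
#'   Bonferroni genome-wide significance level, with the scan run on
#'   `n_hap_drc` haplotypes of the swept subpopulation;
#' * `drc_half`: the same with half the haplotypes (down-sampling check).
#'
#' @param seed integer seed for the whole study.
#' @param n_replicates number of sweep replicates (default 20).
#' @param s selection coefficient (default 0.05).
#' @param daf_range acceptance window for the focal DAF at sampling.
#' @param n_hap_drc haplotypes used for the IBD/DRC scan (default 240).
#' @param max_tries re-seeding attempts per replicate (the replicate
#'   counts as a non-detection if the window is never reached).
#' @param reference optional result of [neutral_ihs_reference()] (built from
#'   `seed` when missing).
#' @return tibble with one row per replicate: `replicate`, `accepted`,
#'   `daf`, `z_focal`, `ihs`, `drc`, `drc_half`; the neutral q99 is attached
#'   as attribute `q99`.
#' @export
sweep_power_study <- function(seed, n_replicates = 20, s = 0.05,
                              daf_range = c(0.4, 0.8), n_hap_drc = 240,
                              max_tries = 16, reference = NULL) {
  if (is.null(reference)) reference <- neutral_ihs_reference(seed)
  focal <- 4500L
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- NULL
    daf <- NA_real_
    for (k in seq_len(max_tries)) {
      cand <- simulate_panel(sweep_study_config(seed * 10000L + r * 100L + k,
                                                s = s))
      rows <- .group_hap_rows(cand$panel, "pop2")
      daf_k <- mean(cand$panel$haplotypes[rows, focal])
      if (daf_k >= daf_range[1] && daf_k <= daf_range[2]) {
        sim <- cand
        daf <- daf_k
        break
      }
    }
    if (is.null(sim)) {
      out[[r]] <- tibble(replicate = r, accepted = FALSE, daf = NA_real_,
                         z_focal = NA_real_, ihs = FALSE, drc = FALSE,
                         drc_half = FALSE)
      next
    }
    panel <- sim$panel
    rows <- .group_hap_rows(panel, "pop2")
    sc <- ihs_scan(panel, group = "pop2", variants = focal)
    sc <- normalize_ihs(sc, reference = reference$reference)
    zf <- if (nrow(sc)) abs(sc$ihs_norm[1]) else NA_real_
    focal_cM <- panel$variants$cM[focal]
    out[[r]] <- tibble(
      replicate = r, accepted = TRUE, daf = daf, z_focal = zf,
      ihs = isTRUE(zf > reference$q99),
      drc = .drc_detect(panel, rows[seq_len(n_hap_drc)], focal_cM),
      drc_half = .drc_detect(panel, rows[seq_len(n_hap_drc / 2)], focal_cM))
  }
  res <- bind_rows(out)
  attr(res, "q99") <- reference$q99
  res
}
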