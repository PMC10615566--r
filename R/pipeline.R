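.pipeline_defaults <- function() {
  list(
    seed = 1,
    input = NULL,   # list(vcf=, map=, ancestral=, labels=) to skip simulation
    sim = list(n_founders = 1000, pop_size = 500, n_generations_burnin = 10,
               split_generation = 3, migration_rate = 0,
               chrom_length_cM = 50, n_variants = 2000, sweep = NULL),
    qc = list(call_rate_min = 0.97, hwe_alpha = 1e-6, pihat_max = 0.25,
              prune_window = 100, prune_step = 10, prune_r2 = 0.2,
              prune_maf = 0.05, pca_k = 20, pc_outlier_sd = 3),
    ihs = list(maf_min = 0.01, ehh_cutoff = 0.05, n_bins = 100),
    fst = list(maf_min = 0.01, n_blocks = 100),
    drc = list(min_length_cM = 0.3, max_mismatch_per_cM = 1, seed_snps = 64,
               bin_size_cM = 0.05, timescales = c(20, 50, 150),
               alpha_exclude = NULL, max_haplotypes = NULL),
    postfilter = list(merge_gap_cM = 0.1, sv_bed = NULL,
                      min_sv_length = 10000, min_af = 0.01,
                      min_overlap_frac = 0.10),
    groups = NULL)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the pipeline defaults. Unknown keys (at the top
#' level or inside a block) are rejected before any computation. Settings can
#' also be read from a YAML file.
#'
#' @param ... named settings, each either a scalar (e.g. `seed`) or a named
#'   list for a stage block (`sim`, `qc`, `ihs`, `fst`, `drc`, `postfilter`),
#'   plus `groups` (character) and `input` (named list of file paths).
#' @param file optional YAML file; `...` overrides its values.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., file = NULL) {
  user <- list(...)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    user <- utils::modifyList(from_file, user)
  }
  cfg <- .pipeline_defaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]])) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), c(names(cfg[[k]]),
                                         if (k == "sim") "sweep",
                                         if (k == "input")
                                           c("vcf", "map", "ancestral", "labels")))
      if (length(bad)) {
        stop("unknown key(s) in '", k, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full selection-scan pipeline
#'
#' Orchestrates data acquisition (simulation, or reading a phased VCF with
#' map/ancestral/label tables), variant and sample QC, the iHS, F_ST and DRC
#' scans per subpopulation, significance thresholds, locus merging and
#' optional SV filtering. All randomness derives from `config$seed`; rerunning
#' with the same configuration reproduces every output table.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; tables are written as TSV plus a JSON run
#'   log (`run_log.json`).
#' @return invisibly, a list with the in-memory results (`panel`, `qc`,
#'   `ihs`, `fst`, `drc`, `loci`, `thresholds`, `log`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("sweepscan")))

  # --- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    inp <- config$input
    map <- read_genetic_map(inp$map)
    anc <- read_ancestral_table(inp$ancestral)
    panel <- read_phased_vcf(inp$vcf, ancestral = anc, map = map)
    panel <- set_groups(panel, read_subpop_labels(inp$labels))
  } else {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    sim <- simulate_panel(do.call(sim_config, sim_args))
    panel <- sim$panel
    log$sweep_site <- sim$truth$sweep_site
  }
  log$initial <- c(samples = n_samples(panel), variants = n_variants(panel))

  # --- QC -----------------------------------------------------------------
  qc_cfg <- config$qc
  vq <- filter_variants_two_stage(panel, call_rate_min = qc_cfg$call_rate_min,
                                  hwe_alpha = qc_cfg$hwe_alpha)
  panel <- vq$panel
  pruned <- ld_prune(panel, window_snps = qc_cfg$prune_window,
                     step_snps = qc_cfg$prune_step, r2_max = qc_cfg$prune_r2,
                     maf_min = qc_cfg$prune_maf)
  rel <- relatedness_pihat(panel, variant_idx = pruned)
  rf <- filter_related_samples(panel, rel, pihat_max = qc_cfg$pihat_max)
  panel <- rf$panel
  pca <- pca_top_k(panel, k = min(qc_cfg$pca_k, n_samples(panel) - 1),
                   variant_idx = ld_prune(panel,
                                          window_snps = qc_cfg$prune_window,
                                          step_snps = qc_cfg$prune_step,
                                          r2_max = qc_cfg$prune_r2,
                                          maf_min = qc_cfg$prune_maf))
  out_pc <- pc_outlier_filter(pca, n_sd = qc_cfg$pc_outlier_sd)
  if (nrow(out_pc)) {
    panel <- subset_panel(panel,
                          samples = !(panel$samples$sample_id %in%
                                        out_pc$sample_id))
  }
  report <- vq$report
  report$removed_samples <- c(relatedness = length(rf$removed),
                              pc_outlier = nrow(out_pc))
  write_scan_table(tidy(report), file.path(out_dir, "qc_report.tsv"))
  log$qc <- list(variants = unclass(report)[c("initial_variants",
                                              "removed_variants",
                                              "recovered_variants",
                                              "final_variants")],
                 removed_samples = as.list(report$removed_samples))

  groups <- config$groups
  if (is.null(groups)) groups <- unique(panel$samples$group)

  # --- iHS per group ------------------------------------------------------
  ihs_cfg <- config$ihs
  ihs_tabs <- list()
  for (g in groups) {
    sc <- ihs_scan(panel, group = g, maf_min = ihs_cfg$maf_min,
                   ehh_cutoff = ihs_cfg$ehh_cutoff) %>%
      normalize_ihs(n_bins = ihs_cfg$n_bins)
    sc$p <- ihs_pvalue(sc$ihs_norm)
    ihs_tabs[[g]] <- sc
    write_scan_table(sc, file.path(out_dir, paste0("ihs_", g, ".tsv")))
  }
  n_scored <- sum(!is.na(ihs_tabs[[1]]$ihs_norm))
  thr_ihs <- bonferroni_threshold(0.05, n_tests = max(n_scored, 1),
                                  n_groups = length(groups))

  # --- F_ST ---------------------------------------------------------------
  fst_cfg <- config$fst
  fst_tab <- NULL
  thr_fst <- NULL
  if (length(groups) >= 2) {
    fst_tab <- fst_scan(panel, groups[1], groups[2],
                        maf_min = fst_cfg$maf_min) %>%
      fst_pvalues()
    write_scan_table(fst_tab, file.path(out_dir, "fst.tsv"))
    thr_fst <- bonferroni_threshold(0.05, n_tests = nrow(fst_tab))
    wm <- suppressWarnings(weighted_mean_fst(fst_tab,
                                             n_blocks = fst_cfg$n_blocks))
    log$fst <- list(weighted_mean = wm$fst, se = wm$se)
  }

  # --- DRC per group ------------------------------------------------------
  drc_cfg <- config$drc
  drc_tabs <- list()
  thr_drc <- NULL
  for (g in groups) {
    rows <- .group_hap_rows(panel, g)
    if (!is.null(drc_cfg$max_haplotypes) &&
        length(rows) > drc_cfg$max_haplotypes) {
      rows <- rows[seq_len(drc_cfg$max_haplotypes)]
    }
    seg <- detect_ibd(panel, min_length_cM = drc_cfg$min_length_cM,
                      max_mismatch_per_cM = drc_cfg$max_mismatch_per_cM,
                      seed_snps = drc_cfg$seed_snps, hap_rows = rows)
    bins <- drc_bins(seg, n_haplotypes = length(rows),
                     bin_size_cM = drc_cfg$bin_size_cM,
                     timescales = drc_cfg$timescales,
                     chrom_length_cM = max(panel$variants$cM))
    thr_drc <- bonferroni_threshold(0.05, n_tests = nrow(bins),
                                    n_groups = length(groups),
                                    n_timescales = length(drc_cfg$timescales))
    for (ts in drc_cfg$timescales) {
      col <- paste0("drc_", ts)
      vals <- bins[[col]]
      alpha_ex <- drc_cfg$alpha_exclude
      if (is.null(alpha_ex)) alpha_ex <- thr_drc$threshold
      if (sum(vals > 0) >= 100 && var(vals[vals > 0]) > 0) {
        null <- fit_gamma_null(vals, alpha_exclude = alpha_ex)
        bins[[paste0("p_", col)]] <- drc_pvalues(vals, null)
      } else {
        bins[[paste0("p_", col)]] <- NA_real_
      }
    }
    drc_tabs[[g]] <- bins
    write_scan_table(bins, file.path(out_dir, paste0("drc_", g, ".tsv")))
  }

  # --- thresholds, loci, SV filter ---------------------------------------
  pf <- config$postfilter
  loci <- list()
  for (g in groups) {
    loci[[paste0("ihs_", g)]] <-
      merge_to_loci(ihs_tabs[[g]], thr_ihs$threshold, p_col = "p",
                    merge_gap_cM = pf$merge_gap_cM)
    if ("p_drc_150" %in% names(drc_tabs[[g]])) {
      bins_g <- drc_tabs[[g]]
      # physical bounds for bins via inverse interpolation of the panel map
      v <- panel$variants
      bins_g$start_bp <- stats::approx(v$cM, v$bp, xout = bins_g$start_cM,
                                       rule = 2, ties = "ordered")$y
      bins_g$end_bp <- stats::approx(v$cM, v$bp, xout = bins_g$end_cM,
                                     rule = 2, ties = "ordered")$y
      loci[[paste0("drc150_", g)]] <-
        merge_to_loci(bins_g, thr_drc$threshold, p_col = "p_drc_150",
                      merge_gap_cM = pf$merge_gap_cM)
    }
  }
  if (!is.null(pf$sv_bed)) {
    svs <- read_sv_bed(pf$sv_bed)
    loci <- lapply(loci, function(l) {
      if (nrow(l) && !any(is.na(l$start_bp))) {
        sv_overlap_filter(l, svs, min_sv_length = pf$min_sv_length,
                          min_af = pf$min_af,
                          min_overlap_frac = pf$min_overlap_frac)
      } else l
    })
  }
  for (nm in names(loci)) {
    write_scan_table(loci[[nm]], file.path(out_dir, paste0("loci_", nm, ".tsv")))
  }

  thresholds <- bind_rows(ihs = thr_ihs, fst = thr_fst, drc = thr_drc,
                          .id = "scan")
  write_scan_table(thresholds, file.path(out_dir, "thresholds.tsv"))
  log$thresholds <- as.list(stats::setNames(thresholds$threshold,
                                            thresholds$scan))
  log$final <- c(samples = n_samples(panel), variants = n_variants(panel))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(panel = panel, qc = report, ihs = ihs_tabs, fst = fst_tab,
                 drc = drc_tabs, loci = loci, thresholds = thresholds,
                 log = log))
}
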