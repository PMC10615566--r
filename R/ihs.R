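#' Extended haplotype homozygosity curve
#'
#' EHH at genetic distance x from a core SNP is the probability that two
#' randomly drawn carrier haplotypes of the core allele are identical at all
#' markers from the core out to x: `sum_g C(n_g, 2) / C(n, 2)` over the
#' groups g of carriers still identical. Computed marker by marker to the
#' left (negative distances) and right (positive distances) of the core.
#'
#' @param panel a [haplotype_panel] with cM positions and no missing data.
#' @param core variant index (1-based) of the core SNP.
#' @param allele `"derived"` or `"ancestral"`: which carriers to follow.
#' @param hap_rows optional haplotype row subset (e.g. one subpopulation).
#' @return tibble of class `ehh_curve` with `distance_cM` (signed) and `ehh`;
#'   the core sits at distance 0 with EHH 1. Truncated after the first marker
#'   where EHH reaches 0.
#' @export
ehh_curve <- function(panel, core, allele = c("derived", "ancestral"),
                      hap_rows = NULL) {
  allele <- match.arg(allele)
  h <- panel$haplotypes
  if (!is.null(hap_rows)) h <- h[hap_rows, , drop = FALSE]
  .check_scan_ready(h, panel$variants$cM)
  a <- if (allele == "derived") 1L else 0L
  if (sum(h[, core] == a) < 2) {
    stop("fewer than 2 carrier haplotypes of the ", allele,
         " allele at the core", call. = FALSE)
  }
  curve <- as_tibble(cpp_ehh_curve(h, panel$variants$cM, core - 1L, a))
  structure(curve, class = c("ehh_curve", class(curve)),
            core = core, allele = allele)
}

.check_scan_ready <- function(h, cM) {
  if (anyNA(h)) {
    stop("haplotype scans require complete (non-missing) haplotypes",
         call. = FALSE)
  }
  if (anyNA(cM)) stop("variant cM positions are required", call. = FALSE)
  invisible(TRUE)
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoid integration of EHH over genetic distance, each side of the core
#' separately, proceeding outward until the first marker whose EHH falls
#' below `ehh_cutoff`; that marker's trapezoid is included and integration
#' stops. A side that reaches the chromosome end while EHH is still at or
#' above the cutoff is flagged edge-truncated.
#'
#' @param curve an [ehh_curve()] (or any tibble with signed `distance_cM`
#'   and `ehh` including the core point at 0).
#' @param ehh_cutoff integration stop threshold (0.05, the conventional
#'   default of standard iHS implementations).
#' @return list with `ihh` (cM, both sides summed) and `edge_truncated`.
#' @export
integrate_ihh <- function(curve, ehh_cutoff = 0.05) {
  one_side <- function(d, e) {
    # d: distances from core in increasing outward order, starting after 0
    ihh <- 0
    prev_d <- 0
    prev_e <- 1
    for (i in seq_along(d)) {
      ihh <- ihh + (prev_e + e[i]) / 2 * (d[i] - prev_d)
      if (e[i] < ehh_cutoff) return(list(ihh = ihh, edge = FALSE))
      prev_d <- d[i]
      prev_e <- e[i]
    }
    list(ihh = ihh, edge = TRUE)
  }
  left <- curve[curve$distance_cM < 0, ]
  right <- curve[curve$distance_cM > 0, ]
  l <- one_side(abs(left$distance_cM[order(left$distance_cM,
                                           decreasing = TRUE)]),
                left$ehh[order(left$distance_cM, decreasing = TRUE)])
  r <- one_side(right$distance_cM[order(right$distance_cM)],
                right$ehh[order(right$distance_cM)])
  list(ihh = l$ihh + r$ihh, edge_truncated = l$edge || r$edge)
}

#' Genome scan of the integrated haplotype score
#'
#' For every variant passing the minor-allele-frequency floor and carrying a
#' determined ancestral state, computes the integrated EHH over ancestral
#' (`ihh_a`) and derived (`ihh_d`) carriers and the raw score
#' `ihs_raw = ln(ihh_a / ihh_d)`. Scores are standardised afterwards with
#' [normalize_ihs()]; variants with zero iHH on either allele are flagged
#' `undefined` and excluded from normalisation.
#'
#' @param panel a polarised [haplotype_panel] (1 = derived) with cM
#'   positions and complete haplotypes.
#' @param group optional subpopulation label: scan only that group's
#'   haplotypes (requires a `group` column, see [set_groups()]).
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @param ehh_cutoff EHH integration cutoff passed to the iHH integration.
#' @param variants optional variant indices restricting which cores are
#'   scored (candidate filters still apply); default: all passing variants.
#' @return tibble of class `ihs_scan` with columns `chrom`, `bp`, `cM`,
#'   `daf`, `ihh_a`, `ihh_d`, `ihs_raw`, `edge_truncated`, `undefined`.
#' @export
ihs_scan <- function(panel, group = NULL, maf_min = 0.01,
                     ehh_cutoff = 0.05, variants = NULL) {
  h <- panel$haplotypes
  if (!is.null(group)) h <- h[.group_hap_rows(panel, group), , drop = FALSE]
  .check_scan_ready(h, panel$variants$cM)
  p <- colMeans(h)
  maf <- pmin(p, 1 - p)
  pass <- maf >= maf_min
  if ("ancestral_missing" %in% names(panel$variants)) {
    pass <- pass & !panel$variants$ancestral_missing
  }
  if (!is.null(variants)) {
    keep <- rep(FALSE, length(pass))
    keep[variants] <- TRUE
    pass <- pass & keep
  }
  cores <- which(pass)
  res <- as_tibble(cpp_ihs_scan(h, panel$variants$cM, cores - 1L, ehh_cutoff))
  out <- dplyr::bind_cols(
    panel$variants[cores, c("chrom", "bp", "cM")],
    tibble(daf = p[cores]), res) %>%
    mutate(ihs_raw = ifelse(.data$undefined, NA_real_,
                            log(.data$ihh_a / .data$ihh_d)))
  structure(out, class = c("ihs_scan", class(out)), group = group,
            maf_min = maf_min, ehh_cutoff = ehh_cutoff)
}

#' Standardise iHS within derived-allele-frequency bins
#'
#' Raw iHS depends systematically on allele frequency, so scores are z-scored
#' within `n_bins` equal-width derived-allele-frequency bins on (0, 1):
#' `ihs_norm = (ihs_raw - bin mean) / bin SD` (sample SD, n - 1). Records in
#' bins with fewer than 2 defined scores or zero SD are flagged
#' `norm_undefined` and keep `NA`.
#'
#' @param records an [ihs_scan()] tibble.
#' @param n_bins number of frequency bins (default 100).
#' @param reference optional [ihs_scan()] tibble whose bin means and SDs are
#'   used instead of the records' own (e.g. a neutral genome-wide background
#'   when `records` covers a region where selection candidates are not a
#'   negligible fraction of all markers).
#' @return the records with `ihs_norm` and `norm_undefined` columns added.
#' @export
normalize_ihs <- function(records, n_bins = 100, reference = NULL) {
  bin <- pmin(pmax(ceiling(records$daf * n_bins), 1L), n_bins)
  src <- if (is.null(reference)) records else reference
  src_bin <- pmin(pmax(ceiling(src$daf * n_bins), 1L), n_bins)
  ok_src <- !is.na(src$ihs_raw)
  ok <- !is.na(records$ihs_raw)
  stats <- tibble(bin = src_bin[ok_src], raw = src$ihs_raw[ok_src]) %>%
    group_by(.data$bin) %>%
    summarise(m = mean(.data$raw), s = sd(.data$raw), k = n(),
              .groups = "drop")
  idx <- match(bin, stats$bin)
  m <- stats$m[idx]
  s <- stats$s[idx]
  k <- stats$k[idx]
  bad <- !ok | is.na(s) | k < 2 | s == 0
  records$ihs_norm <- ifelse(bad, NA_real_, (records$ihs_raw - m) / s)
  records$norm_undefined <- bad
  records
}

#' Two-sided normal p-value for a normalised iHS score
#'
#' Under neutrality the standardised score is treated as standard normal;
#' selection can lengthen either allele's haplotype background, so the test
#' is two-sided: `p = 2 * pnorm(-|z|)`.
#'
#' @param ihs_norm numeric vector of normalised scores (`NA` passes through).
#' @return p-values in (0, 1].
#' @export
ihs_pvalue <- function(ihs_norm) {
  2 * pnorm(-abs(ihs_norm))
}
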