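#' Bonferroni genome-wide significance threshold
#'
#' `alpha / (n_tests * n_groups * n_timescales)`: the per-test level after
#' correcting for the number of scored tests, scanned subpopulations and (for
#' DRC) timescales.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (scored variants or bins).
#' @param n_groups number of subpopulations scanned (default 1).
#' @param n_timescales number of timescales scanned (default 1).
#' @return tibble with the inputs, `threshold` (full precision) and
#'   `threshold_3sig` (rounded to 3 significant digits, as usually printed).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests, n_groups = 1,
                                 n_timescales = 1) {
  if (any(c(n_tests, n_groups, n_timescales) <= 0)) {
    stop("all counts must be positive", call. = FALSE)
  }
  thr <- alpha / (n_tests * n_groups * n_timescales)
  tibble(alpha = alpha, n_tests = n_tests, n_groups = n_groups,
         n_timescales = n_timescales, threshold = thr,
         threshold_3sig = signif(thr, 3))
}

#' Merge significant records into candidate loci
#'
#' Records at or below the significance threshold are sorted by position and
#' neighbours within `merge_gap_cM` are joined into one locus; locus bounds
#' are the min/max member coordinates and the lead p-value is the member
#' minimum. Works for per-variant records (columns `bp` and `cM`) and for
#' per-bin records (`start_cM`/`end_cM`, optionally `start_bp`/`end_bp`).
#'
#' @param records tibble with `chrom`, a p-value column, and coordinates.
#' @param threshold significance threshold on the p-values.
#' @param p_col name of the p-value column (default `"p"`).
#' @param merge_gap_cM maximum genetic gap joined into one locus
#'   (default 0.1).
#' @return tibble of class `locus_table`: `chrom`, `start_bp`, `end_bp`,
#'   `start_cM`, `end_cM`, `n_members`, `lead_p`.
#' @export
merge_to_loci <- function(records, threshold, p_col = "p",
                          merge_gap_cM = 0.1) {
  rec <- as_tibble(records)
  if (!p_col %in% names(rec)) {
    stop("records have no '", p_col, "' column", call. = FALSE)
  }
  if (!"start_cM" %in% names(rec)) {
    rec$start_cM <- rec$cM
    rec$end_cM <- rec$cM
  }
  if (!"start_bp" %in% names(rec)) {
    if ("bp" %in% names(rec)) {
      rec$start_bp <- rec$bp
      rec$end_bp <- rec$bp
    } else {
      rec$start_bp <- NA_real_
      rec$end_bp <- NA_real_
    }
  }
  sig <- rec %>%
    filter(!is.na(.data[[p_col]]), .data[[p_col]] <= threshold) %>%
    arrange(.data$chrom, .data$start_cM)
  if (!nrow(sig)) {
    out <- tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), start_cM = numeric(),
                  end_cM = numeric(), n_members = integer(),
                  lead_p = numeric())
    return(structure(out, class = c("locus_table", class(out))))
  }
  sig <- sig %>%
    group_by(.data$chrom) %>%
    mutate(new_locus = c(TRUE, utils::tail(.data$start_cM, -1) -
                           utils::head(.data$end_cM, -1) > merge_gap_cM),
           locus_id = cumsum(.data$new_locus)) %>%
    ungroup()
  out <- sig %>%
    group_by(.data$chrom, .data$locus_id) %>%
    summarise(start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
              start_cM = min(.data$start_cM), end_cM = max(.data$end_cM),
              n_members = n(), lead_p = min(.data[[p_col]]),
              .groups = "drop") %>%
    select(-"locus_id") %>%
    arrange(.data$chrom, .data$start_cM)
  structure(out, class = c("locus_table", class(out)),
            threshold = threshold, merge_gap_cM = merge_gap_cM)
}

#' Flag loci overlapping common structural variants
#'
#' Haplotype-based scan hits can be artefacts of structural variation that
#' suppresses recombination in heterozygotes, so loci are checked against an
#' SV catalogue: SVs are first restricted to length at least `min_sv_length`
#' and allele frequency at least `min_af`; a locus is flagged when its
#' physical overlap with some retained SV covers at least
#' `min_overlap_frac` of that SV's length (inclusive boundary). Flagged loci
#' are retained in the output with `sv_overlap = TRUE` rather than dropped.
#' The same operation serves for segmental-duplication interval sets (pass
#' `min_af = 0` and a `flag_col` name).
#'
#' @param loci a [merge_to_loci()] table (physical coordinates required).
#' @param svs tibble from [read_sv_bed()]: `chrom`, `start`, `end` (0-based
#'   half-open), `af`, `sv_length`.
#' @param min_sv_length minimum SV length in bp (default 10 kb).
#' @param min_af minimum SV allele frequency (default 1%).
#' @param min_overlap_frac minimum overlap as a fraction of the SV length
#'   (default 10%, inclusive).
#' @param flag_col name of the flag column added (default `"sv_overlap"`).
#' @return `loci` with the logical flag column added.
#' @export
sv_overlap_filter <- function(loci, svs, min_sv_length = 10000,
                              min_af = 0.01, min_overlap_frac = 0.10,
                              flag_col = "sv_overlap") {
  if (any(is.na(loci$start_bp))) {
    stop("loci need physical coordinates for SV filtering", call. = FALSE)
  }
  if (any(svs$start >= svs$end)) stop("malformed SV intervals", call. = FALSE)
  keep <- svs$sv_length >= min_sv_length & !is.na(svs$af) & svs$af >= min_af
  sv <- svs[keep, , drop = FALSE]
  flag <- vapply(seq_len(nrow(loci)), function(i) {
    ch <- loci$chrom[i]
    # locus bp treated as 1-based inclusive -> half-open [start-1, end)
    ls <- loci$start_bp[i] - 1
    le <- loci$end_bp[i]
    s <- sv[sv$chrom == ch, , drop = FALSE]
    if (!nrow(s)) return(FALSE)
    ov <- pmax(0, pmin(le, s$end) - pmax(ls, s$start))
    any(ov >= min_overlap_frac * s$sv_length)
  }, logical(1))
  loci[[flag_col]] <- flag
  loci
}
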