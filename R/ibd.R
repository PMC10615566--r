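#' Detect identity-by-descent segments between haplotype pairs
#'
#' A light-weight IBD detector for phased panels: for every haplotype pair,
#' maximal runs of exact allele identity spanning at least `seed_snps`
#' markers seed a candidate segment, which is then extended through isolated
#' mismatches while each extension step's marginal mismatch density stays at
#' or below `max_mismatch_per_cM`; overlapping extensions are merged and
#' segments of at least `min_length_cM` are reported. The quality score of a
#' segment is its fraction of matching markers; its age is estimated from the
#' genetic length via [estimate_age()].
#'
#' @param panel a [haplotype_panel] with cM positions and complete
#'   haplotypes.
#' @param min_length_cM shortest segment reported (cM).
#' @param max_mismatch_per_cM tolerated marginal mismatch density when
#'   extending a seed (default 1 per cM).
#' @param seed_snps exact-match run length that seeds a segment (default 64).
#' @param hap_rows optional haplotype row subset (e.g. one subpopulation);
#'   reported indices refer to the original panel rows.
#' @param pairs optional two-column matrix of haplotype row pairs; defaults
#'   to all pairs of `hap_rows`.
#' @return tibble of class `ibd_segments`: `hap_i`, `hap_j`, `chrom`,
#'   `start_bp`, `end_bp`, `start_cM`, `end_cM`, `length_cM`, `quality`,
#'   `age_hat` (generations). The number of pairs scanned is kept in the
#'   `n_pairs` attribute.
#' @export
detect_ibd <- function(panel, min_length_cM = 0.3, max_mismatch_per_cM = 1,
                       seed_snps = 64, hap_rows = NULL, pairs = NULL) {
  cM <- panel$variants$cM
  if (anyNA(cM)) stop("panel has no cM positions", call. = FALSE)
  h <- panel$haplotypes
  if (anyNA(h)) stop("IBD detection requires complete haplotypes", call. = FALSE)
  if (is.null(hap_rows)) hap_rows <- seq_len(nrow(h))
  if (is.null(pairs)) {
    if (length(hap_rows) < 2) stop("need at least 2 haplotypes", call. = FALSE)
    pairs <- t(utils::combn(hap_rows, 2))
  }
  out <- lapply(unique(panel$variants$chrom), function(ch) {
    idx <- which(panel$variants$chrom == ch)
    seg <- cpp_detect_ibd(t(h[, idx, drop = FALSE]), cM[idx],
                          pairs[, 1] - 1L, pairs[, 2] - 1L,
                          min_length_cM, max_mismatch_per_cM,
                          as.integer(seed_snps))
    seg <- as_tibble(seg)
    tibble(hap_i = seg$hap_i, hap_j = seg$hap_j, chrom = ch,
           start_bp = panel$variants$bp[idx][seg$start_idx],
           end_bp = panel$variants$bp[idx][seg$end_idx],
           start_cM = cM[idx][seg$start_idx],
           end_cM = cM[idx][seg$end_idx],
           quality = seg$quality)
  })
  res <- bind_rows(out) %>%
    mutate(length_cM = .data$end_cM - .data$start_cM,
           age_hat = estimate_age(pmax(.data$length_cM, 1e-12)))
  structure(res, class = c("ibd_segments", class(res)),
            n_pairs = nrow(pairs))
}

#' Estimate IBD segment age from genetic length
#'
#' A tract inherited from a common ancestor g generations back has expected
#' genetic length about `50 / g` cM (recombination breaks it down on both
#' lineages over 2g meioses), so the age estimate is `g_hat = 50 / length`,
#' monotone decreasing in length.
#'
#' @param length_cM segment genetic length(s), strictly positive.
#' @return estimated age(s) in generations.
#' @export
estimate_age <- function(length_cM) {
  if (any(is.na(length_cM)) || any(length_cM <= 0)) {
    stop("segment length must be positive", call. = FALSE)
  }
  50 / length_cM
}

#' Density of recent coalescence per genomic bin
#'
#' Tiles each chromosome with non-overlapping bins of `bin_size_cM` and, for
#' each timescale T, sums the quality scores of IBD segments whose estimated
#' age is at most T generations and that overlap the bin, counting each
#' haplotype pair at most once per bin (the pair's best-quality segment), and
#' divides by the number of haplotype pairs `C(n_haplotypes, 2)`.
#'
#' @param segments an [detect_ibd()] table (needs `chrom`, `start_cM`,
#'   `end_cM`, `quality`, `age_hat`, `hap_i`, `hap_j`).
#' @param n_haplotypes number of haplotypes scanned (for the pair count).
#' @param bin_size_cM bin width in cM (default 0.05).
#' @param timescales ages in generations defining DRC_T (default 20/50/150).
#' @param chrom_length_cM optional named (by chromosome) or scalar genetic
#'   length; defaults to the last segment end per chromosome.
#' @return tibble of class `drc_scan`: `chrom`, `bin`, `start_cM`, `end_cM`
#'   and one `drc_<T>` column per timescale.
#' @export
drc_bins <- function(segments, n_haplotypes, bin_size_cM = 0.05,
                     timescales = c(20, 50, 150), chrom_length_cM = NULL) {
  if (n_haplotypes < 2) stop("need at least 2 haplotypes", call. = FALSE)
  n_pairs <- .choose2(n_haplotypes)
  chroms <- unique(segments$chrom)
  if (!length(chroms)) chroms <- "chr1"

  grid <- purrr::map_dfr(chroms, function(ch) {
    len <- if (is.null(chrom_length_cM)) {
      max(segments$end_cM[segments$chrom == ch], 0)
    } else if (!is.null(names(chrom_length_cM))) {
      chrom_length_cM[[ch]]
    } else chrom_length_cM
    nb <- max(1L, ceiling(len / bin_size_cM))
    tibble(chrom = ch, bin = seq_len(nb),
           start_cM = (seq_len(nb) - 1) * bin_size_cM,
           end_cM = seq_len(nb) * bin_size_cM)
  })

  seg <- as_tibble(segments)
  if (!nrow(seg)) {
    for (ts in timescales) grid[[paste0("drc_", ts)]] <- 0
    return(structure(grid, class = c("drc_scan", class(grid)),
                     n_haplotypes = n_haplotypes, bin_size_cM = bin_size_cM,
                     timescales = timescales))
  }
  # global bin ids: per-chromosome offset into the tiled grid
  offs <- c(0, cumsum(tapply(grid$bin, factor(grid$chrom,
                                              levels = chroms), max)))
  names(offs) <- c(chroms, "..end")
  seg_off <- offs[match(seg$chrom, chroms)]
  pair_id <- as.numeric(factor(paste(seg$hap_i, seg$hap_j)))
  k1 <- pmax(floor(seg$start_cM / bin_size_cM), 0)
  k2 <- pmax(ceiling(seg$end_cM / bin_size_cM) - 1, k1)
  nb <- k2 - k1 + 1
  bin_g <- sequence(nb) - 1L + rep(k1, nb) + 1L + rep(seg_off, nb)
  pair_g <- rep(pair_id, nb)
  qual_g <- rep(seg$quality, nb)
  age_g <- rep(seg$age_hat, nb)
  # per (bin, pair): keep the best-quality segment once
  key <- bin_g * (max(pair_g) + 1) + pair_g
  ord <- order(key, -qual_g)
  key <- key[ord]; bin_g <- bin_g[ord]; qual_g <- qual_g[ord]
  age_g <- age_g[ord]
  for (ts in timescales) {
    keep <- age_g <= ts
    b <- bin_g[keep]; q <- qual_g[keep]
    first <- !duplicated(key[keep])
    tot <- rowsum(q[first], b[first])
    col <- paste0("drc_", ts)
    grid[[col]] <- 0
    idx <- as.integer(rownames(tot))
    grid[[col]][idx] <- tot[, 1] / n_pairs
  }
  structure(grid, class = c("drc_scan", class(grid)),
            n_haplotypes = n_haplotypes, bin_size_cM = bin_size_cM,
            timescales = timescales)
}

#' Fit a Gamma empirical null with iterative exclusion of selected regions
#'
#' Fits a Gamma distribution by maximum likelihood (moment-fit
#' initialisation) to the strictly positive DRC values, computes upper-tail
#' p-values for all values, excludes those with p below `alpha_exclude`
#' (putative selection targets), and repeats until the exclusion set is
#' stable or `max_iter` is reached. Zero-valued bins are excluded from the
#' likelihood; their mass fraction is recorded so tail probabilities remain
#' interpretable as conditional on a positive statistic.
#'
#' @param drc_values numeric vector of per-bin DRC statistics.
#' @param alpha_exclude exclusion p-value threshold; defaults to the
#'   Bonferroni level `0.05 / length(drc_values)`.
#' @param max_iter iteration cap (default 20).
#' @return object of class `gamma_null`: `shape`, `rate`, `excluded`
#'   (indices into `drc_values`), `n_iterations`, `converged`, `zero_mass`,
#'   `n_fit`.
#' @export
fit_gamma_null <- function(drc_values, alpha_exclude = NULL, max_iter = 20) {
  if (is.null(alpha_exclude)) alpha_exclude <- 0.05 / length(drc_values)
  pos <- which(drc_values > 0)
  if (length(pos) < 100) {
    stop("need at least 100 positive bins to fit the null", call. = FALSE)
  }
  x_all <- drc_values[pos]
  if (var(x_all) == 0) stop("degenerate input: all values identical", call. = FALSE)
  zero_mass <- 1 - length(pos) / length(drc_values)

  excluded <- integer(0)
  fit <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    inc <- setdiff(seq_along(x_all), excluded)
    x <- x_all[inc]
    m <- mean(x)
    v <- var(x)
    if (v == 0) stop("degenerate input after exclusion", call. = FALSE)
    start <- list(shape = m^2 / v, rate = m / v)
    fit <- fitdistrplus::fitdist(x, "gamma", method = "mle", start = start,
                                 keepdata = FALSE)
    p <- pgamma(x_all, shape = fit$estimate[["shape"]],
                rate = fit$estimate[["rate"]], lower.tail = FALSE)
    new_excluded <- which(p < alpha_exclude)
    if (identical(new_excluded, excluded)) {
      converged <- TRUE
      break
    }
    excluded <- new_excluded
  }
  if (!converged) {
    warning("exclusion set did not stabilise within ", max_iter,
            " iterations; returning last fit", call. = FALSE)
  }
  structure(list(shape = unname(fit$estimate[["shape"]]),
                 rate = unname(fit$estimate[["rate"]]),
                 excluded = pos[excluded],
                 n_iterations = it, converged = converged,
                 zero_mass = zero_mass, n_fit = length(x_all) - length(excluded)),
            class = "gamma_null")
}

#' @export
print.gamma_null <- function(x, ...) {
  cat("<gamma_null> Gamma(shape =", format(x$shape, digits = 4),
      ", rate =", format(x$rate, digits = 4), ")\n")
  cat("  fitted on", x$n_fit, "bins;", length(x$excluded),
      "excluded in", x$n_iterations, "iteration(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (x$zero_mass > 0) {
    cat("  zero-valued bin mass:", format(x$zero_mass, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
tidy.gamma_null <- function(x, ...) {
  tibble(term = c("shape", "rate"), estimate = c(x$shape, x$rate))
}

#' @export
glance.gamma_null <- function(x, ...) {
  tibble(shape = x$shape, rate = x$rate, n_fit = x$n_fit,
         n_excluded = length(x$excluded), n_iterations = x$n_iterations,
         converged = x$converged, zero_mass = x$zero_mass)
}

#' Upper-tail p-values from a fitted Gamma null
#'
#' @param x a numeric vector of DRC values, or a [drc_bins()] table (every
#'   `drc_<T>` column then gets a matching `p_drc_<T>` column).
#' @param null a [fit_gamma_null()] object.
#' @return p-values in (0, 1] (a vector, or the table with p columns added).
#' @export
drc_pvalues <- function(x, null) {
  surv <- function(v) pgamma(v, shape = null$shape, rate = null$rate,
                             lower.tail = FALSE)
  if (is.data.frame(x)) {
    for (col in grep("^drc_", names(x), value = TRUE)) {
      x[[paste0("p_", col)]] <- surv(x[[col]])
    }
    return(x)
  }
  surv(x)
}
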