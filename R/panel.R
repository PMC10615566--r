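#' Phased haplotype panel
#'
#' Container for a phased, biallelic SNP panel. Haplotypes are stored as a
#' binary matrix with two adjacent rows per sample (maternal/paternal order is
#' arbitrary but stable); alleles are coded `1` = derived, `0` = ancestral
#' once the panel has been polarised. Missing genotypes are `NA` in both rows
#' of the affected sample.
#'
#' @param haplotypes integer matrix, `2 * n_samples` rows by `n_variants`
#'   columns, entries 0/1/`NA`.
#' @param samples tibble with at least a `sample_id` column (and optionally a
#'   `group` column of subpopulation labels), one row per sample.
#' @param variants tibble with one row per variant and at least `chrom`, `bp`
#'   (1-based physical position), `cM` (genetic position). Optional columns:
#'   `ref`, `alt`, `ancestral_is_ref`, `ancestral_missing`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, samples, variants) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  if (nrow(haplotypes) != 2L * nrow(samples)) {
    stop("haplotype matrix must have two rows per sample", call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(variants)) {
    stop("haplotype matrix columns must match variant table rows", call. = FALSE)
  }
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("haplotype entries must be 0, 1 or NA", call. = FALSE)
  }
  if (!"sample_id" %in% names(samples)) {
    stop("samples must have a sample_id column", call. = FALSE)
  }
  for (col in c("chrom", "bp", "cM")) {
    if (!col %in% names(variants)) {
      stop("variants must have a ", col, " column", call. = FALSE)
    }
  }
  for (ch in unique(variants$chrom)) {
    idx <- variants$chrom == ch
    if (is.unsorted(variants$bp[idx], strictly = TRUE)) {
      stop("bp must be strictly increasing within chromosome", call. = FALSE)
    }
    cm <- variants$cM[idx]
    if (any(!is.na(cm)) && is.unsorted(cm[!is.na(cm)])) {
      stop("cM must be non-decreasing within chromosome", call. = FALSE)
    }
  }
  structure(list(haplotypes = haplotypes, samples = samples,
                 variants = variants),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$samples), " samples x ",
      nrow(x$variants), " variants (",
      length(unique(x$variants$chrom)), " chromosome",
      if (length(unique(x$variants$chrom)) > 1) "s" else "", ")\n", sep = "")
  miss <- mean(is.na(x$haplotypes))
  if (miss > 0) cat("  missing haplotype entries: ",
                    format(100 * miss, digits = 3), "%\n", sep = "")
  if ("group" %in% names(x$samples)) {
    tab <- table(x$samples$group)
    cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples, haplotypes and variants in a panel
#' @param panel a [haplotype_panel].
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_haplotypes <- function(panel) nrow(panel$haplotypes)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Derived allele frequency per variant
#'
#' @param panel a [haplotype_panel] (polarised: 1 = derived).
#' @return numeric vector of derived allele frequencies over non-missing
#'   haplotypes.
#' @export
derived_freq <- function(panel) {
  colMeans(panel$haplotypes, na.rm = TRUE)
}

#' Minor allele frequency per variant
#' @inheritParams derived_freq
#' @return numeric vector, `pmin(p, 1 - p)`.
#' @export
minor_freq <- function(panel) {
  p <- derived_freq(panel)
  pmin(p, 1 - p)
}

#' Genotype dosage matrix
#'
#' Sums the two haplotypes of each sample into a 0/1/2 derived-allele dosage.
#'
#' @inheritParams derived_freq
#' @return integer matrix, samples by variants; `NA` where either haplotype
#'   is missing.
#' @export
dosage <- function(panel) {
  h <- panel$haplotypes
  idx <- seq_len(nrow(h) / 2)
  d <- h[2 * idx - 1, , drop = FALSE] + h[2 * idx, , drop = FALSE]
  rownames(d) <- panel$samples$sample_id
  d
}

#' Subset a haplotype panel
#'
#' @inheritParams derived_freq
#' @param variants integer or logical index over variants (optional).
#' @param samples integer or logical index over samples (optional).
#' @return a [haplotype_panel] restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  h <- panel$haplotypes
  vtab <- panel$variants
  stab <- panel$samples
  if (!is.null(variants)) {
    h <- h[, variants, drop = FALSE]
    vtab <- vtab[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    sidx <- seq_len(nrow(stab))[samples]
    hidx <- as.vector(rbind(2L * sidx - 1L, 2L * sidx))
    h <- h[hidx, , drop = FALSE]
    stab <- stab[sidx, , drop = FALSE]
  }
  haplotype_panel(h, stab, vtab)
}

#' Attach subpopulation labels to a panel
#'
#' @inheritParams derived_freq
#' @param labels tibble with `sample_id` and `group` columns.
#' @return the panel with a `group` column merged into its sample table.
#' @export
set_groups <- function(panel, labels) {
  labels <- as_tibble(labels)
  if (!all(c("sample_id", "group") %in% names(labels))) {
    stop("labels must have sample_id and group columns", call. = FALSE)
  }
  miss <- setdiff(panel$samples$sample_id, labels$sample_id)
  if (length(miss)) {
    stop("labels missing for ", length(miss), " sample(s), e.g. ", miss[1],
         call. = FALSE)
  }
  panel$samples$group <- labels$group[match(panel$samples$sample_id,
                                            labels$sample_id)]
  panel
}

# haplotype row indices belonging to the samples of one group
.group_hap_rows <- function(panel, group) {
  sidx <- which(panel$samples$group == group)
  if (!length(sidx)) stop("no samples in group '", group, "'", call. = FALSE)
  as.vector(rbind(2L * sidx - 1L, 2L * sidx))
}
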