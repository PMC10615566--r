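#' Read a genetic map
#'
#' Expects a whitespace-separated table with columns chromosome, physical
#' position (bp) and genetic position (cM), with or without a header line.
#' Gzipped files are read transparently.
#'
#' @param path file path.
#' @return A `genetic_map`: tibble with `chrom`, `bp`, `cM`, sorted by
#'   chromosome and position.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", strsplit(trimws(first), "\\s+")[[1]][2])
  tab <- utils::read.table(path, header = has_header,
                           col.names = c("chrom", "bp", "cM"),
                           colClasses = c("character", "numeric", "numeric"))
  genetic_map(as_tibble(tab))
}

#' Construct a genetic map from a knot table
#'
#' @param knots tibble with `chrom`, `bp`, `cM`.
#' @return A `genetic_map` object.
#' @export
genetic_map <- function(knots) {
  knots <- as_tibble(knots) %>% arrange(.data$chrom, .data$bp)
  for (ch in unique(knots$chrom)) {
    k <- knots[knots$chrom == ch, ]
    if (is.unsorted(k$bp, strictly = TRUE)) {
      stop("map bp must be strictly increasing within chromosome", call. = FALSE)
    }
    if (is.unsorted(k$cM)) {
      stop("map cM must be non-decreasing", call. = FALSE)
    }
  }
  structure(knots, class = c("genetic_map", class(knots)))
}

#' Interpolate genetic position
#'
#' Piecewise-linear interpolation of cM at physical positions; positions
#' outside the knot range are linearly extrapolated using the terminal
#' segment's recombination rate and floored at 0 cM.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name (scalar).
#' @param bp numeric vector of physical positions.
#' @return numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chrom, bp) {
  k <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(k) < 2) {
    stop("chromosome '", chrom, "' absent from map (or has < 2 knots)",
         call. = FALSE)
  }
  kb <- k$bp
  kc <- k$cM
  n <- length(kb)
  out <- stats::approx(kb, kc, xout = bp, rule = 1, ties = "ordered")$y
  lo <- bp < kb[1]
  hi <- bp > kb[n]
  if (any(lo)) {
    rate <- (kc[2] - kc[1]) / (kb[2] - kb[1])
    out[lo] <- kc[1] - (kb[1] - bp[lo]) * rate
  }
  if (any(hi)) {
    rate <- (kc[n] - kc[n - 1]) / (kb[n] - kb[n - 1])
    out[hi] <- kc[n] + (bp[hi] - kb[n]) * rate
  }
  pmax(out, 0)
}

#' Read phased genotypes from VCF
#'
#' Reads a VCF 4.2 with phased GT for all samples, keeps biallelic SNPs only
#' (multiallelic or indel records are dropped with a counted warning), and
#' polarises alleles to ancestral = 0 / derived = 1 using an ancestral-allele
#' table. Variants whose ancestral allele is missing, `N`, or matches neither
#' REF nor ALT are kept but flagged `ancestral_missing` (ALT-dosage coding is
#' retained for them); downstream scans exclude flagged variants.
#'
#' @param path VCF path (optionally gzipped).
#' @param ancestral tibble with `chrom`, `bp`, `ancestral_allele` (as read by
#'   [read_ancestral_table()]), or `NULL` to keep ALT-dosage coding with all
#'   variants flagged.
#' @param map optional [genetic_map()] used to interpolate cM positions;
#'   without it `cM` is `NA`.
#' @return A [haplotype_panel].
#' @export
read_phased_vcf <- function(path, ancestral = NULL, map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]

  snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warning(sum(!snp), " non-biallelic-SNP record(s) dropped", call. = FALSE)
    fix <- fix[snp, , drop = FALSE]
    gt <- gt[snp, , drop = FALSE]
  }
  if (!nrow(fix)) stop("no biallelic SNP records in VCF", call. = FALSE)

  gt_field <- matrix(sub(":.*", "", gt), nrow = nrow(fix))
  unphased <- matrix(grepl("/", gt_field), nrow = nrow(fix))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at ", fix$CHROM[bad[1]], ":", fix$POS[bad[1]],
         " sample ", colnames(gt)[bad[2]], call. = FALSE)
  }
  a1 <- substr(gt_field, 1, 1)
  a2 <- substr(gt_field, 3, 3)
  to_int <- function(x) {
    y <- suppressWarnings(as.integer(x))
    if (any(!is.na(y) & !(y %in% 0:1))) {
      stop("non-biallelic allele index in GT", call. = FALSE)
    }
    y
  }
  m1 <- matrix(to_int(a1), nrow = nrow(fix))
  m2 <- matrix(to_int(a2), nrow = nrow(fix))

  n_s <- ncol(gt)
  hap <- matrix(NA_integer_, nrow = 2 * n_s, ncol = nrow(fix))
  hap[2 * seq_len(n_s) - 1, ] <- t(m1)
  hap[2 * seq_len(n_s), ] <- t(m2)

  variants <- tibble(chrom = fix$CHROM, bp = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     ancestral_is_ref = TRUE, ancestral_missing = TRUE)
  if (!is.null(ancestral)) {
    key <- paste(variants$chrom, variants$bp)
    anc <- ancestral$ancestral_allele[match(key, paste(ancestral$chrom,
                                                       ancestral$bp))]
    is_ref <- !is.na(anc) & anc == variants$ref
    is_alt <- !is.na(anc) & anc == variants$alt
    variants$ancestral_is_ref <- !is_alt     # TRUE also for flagged records
    variants$ancestral_missing <- !(is_ref | is_alt)
    flip <- which(is_alt)
    if (length(flip)) hap[, flip] <- 1L - hap[, flip]
  }
  variants$cM <- if (is.null(map)) NA_real_ else {
    unlist(lapply(split(seq_len(nrow(variants)), variants$chrom), function(i) {
      interpolate_cM(map, variants$chrom[i[1]], variants$bp[i])
    })[unique(variants$chrom)], use.names = FALSE)
  }
  samples <- tibble(sample_id = colnames(gt))
  haplotype_panel(hap, samples, variants)
}

#' Write a phased panel to VCF
#'
#' Emits a minimal VCF 4.2 with phased GT (pipe separator). Alleles are
#' written against REF/ALT using the panel's `ancestral_is_ref` flag, so a
#' write/read round trip through [read_phased_vcf()] restores the panel.
#'
#' @param panel a [haplotype_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  v <- panel$variants
  h <- panel$haplotypes
  n_s <- n_samples(panel)
  ref <- if ("ref" %in% names(v)) v$ref else rep("A", nrow(v))
  alt <- if ("alt" %in% names(v)) v$alt else rep("G", nrow(v))
  is_ref <- if ("ancestral_is_ref" %in% names(v)) v$ancestral_is_ref else
    rep(TRUE, nrow(v))
  # allele index written to GT: derived carriers get ALT when ancestral==REF
  gt_alleles <- h
  flip <- which(!is_ref)
  if (length(flip)) gt_alleles[, flip] <- 1L - gt_alleles[, flip]

  a1 <- t(gt_alleles[2 * seq_len(n_s) - 1, , drop = FALSE])
  a2 <- t(gt_alleles[2 * seq_len(n_s), , drop = FALSE])
  cell <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                        ifelse(is.na(a2), ".", a2)),
                 nrow = nrow(v))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t"),
    paste(v$chrom, format(v$bp, scientific = FALSE, trim = TRUE), ".",
          ref, alt, ".", "PASS", ".", "GT",
          apply(cell, 1, paste, collapse = "\t"), sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write an ancestral-allele table
#'
#' TSV with columns `chrom`, `bp`, `ancestral_allele`; `N` or `.` mark
#' undetermined ancestral states.
#'
#' @param path file path.
#' @return tibble with `chrom`, `bp`, `ancestral_allele`.
#' @export
read_ancestral_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), bp = readr::col_double(),
    ancestral_allele = readr::col_character()))
}

#' @rdname read_ancestral_table
#' @param tab the table to write.
#' @export
write_ancestral_table <- function(tab, path) {
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read / write subpopulation labels
#'
#' TSV with columns `sample_id`, `group`.
#' @param path file path.
#' @return tibble with `sample_id` and `group`.
#' @export
read_subpop_labels <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character()))
}

#' @rdname read_subpop_labels
#' @param tab the table to write.
#' @export
write_subpop_labels <- function(tab, path) {
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()] to write.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' Read structural-variant intervals from BED
#'
#' BED convention: 0-based half-open intervals. The fourth column carries the
#' allele frequency, either bare (`0.05`) or as `AF=0.05`. An empty file
#' yields an empty table, not an error.
#'
#' @param path BED path.
#' @return tibble with `chrom`, `start`, `end`, `af`, `sv_length`.
#' @export
read_sv_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  af = numeric(), sv_length = numeric()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  chrom <- vapply(parts, `[`, "", 1)
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  af_raw <- vapply(parts, function(x) if (length(x) >= 4) x[4] else NA_character_, "")
  af <- as.numeric(sub("^AF=", "", af_raw))
  if (any(is.na(start) | is.na(end))) stop("malformed BED coordinates", call. = FALSE)
  if (any(start < 0)) stop("negative BED coordinates", call. = FALSE)
  if (any(start >= end)) stop("BED intervals must satisfy start < end", call. = FALSE)
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("allele frequency outside [0, 1]", call. = FALSE)
  }
  tibble(chrom = chrom, start = start, end = end, af = af,
         sv_length = end - start)
}

#' Read / write a scan table
#'
#' Lossless TSV round trip for per-variant or per-bin scan results.
#' @param table a data frame.
#' @param path file path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_scan_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Emits the four files the pipeline consumes: a phased VCF, a genetic map, an
#' ancestral-allele table and a subpopulation-label table. The files round
#' trip losslessly through the package readers.
#'
#' @param panel a [haplotype_panel].
#' @param truth the matching `sim_truth` (for labels).
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
emit_dataset <- function(panel, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  v <- panel$variants
  paths <- c(vcf = file.path(out_dir, "panel.vcf"),
             map = file.path(out_dir, "genetic_map.tsv"),
             ancestral = file.path(out_dir, "ancestral.tsv"),
             labels = file.path(out_dir, "labels.tsv"))
  write_phased_vcf(panel, paths[["vcf"]])
  write_genetic_map(genetic_map(v[, c("chrom", "bp", "cM")]), paths[["map"]])
  anc <- ifelse(v$ancestral_missing, "N",
                ifelse(v$ancestral_is_ref, v$ref, v$alt))
  write_ancestral_table(tibble(chrom = v$chrom, bp = v$bp,
                               ancestral_allele = anc),
                        paths[["ancestral"]])
  write_subpop_labels(truth$subpop_labels, paths[["labels"]])
  paths
}
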