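#' Plot an EHH decay curve
#'
#' @param object an [ehh_curve()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.ehh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_cM, y = .data$ehh)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from core (cM)", y = "EHH",
                  title = paste0("EHH, ", attr(object, "allele"),
                                 " allele at variant ", attr(object, "core"))) +
    ggplot2::ylim(0, 1)
}

.manhattan <- function(df, p_col, ylab, threshold = NULL) {
  df <- df[!is.na(df[[p_col]]), , drop = FALSE]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bp / 1e6,
                                         y = -log10(.data[[p_col]]),
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.5, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab)
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Manhattan plot of an iHS scan
#'
#' Expects normalised scores; p-values are computed on the fly with
#' [ihs_pvalue()] when no `p` column is present.
#'
#' @param object an [ihs_scan()] tibble (after [normalize_ihs()]).
#' @param threshold optional genome-wide significance level drawn as a line.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.ihs_scan <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object)
  if (!"p" %in% names(df)) {
    if (!"ihs_norm" %in% names(df)) {
      stop("normalise the scan first (normalize_ihs())", call. = FALSE)
    }
    df$p <- ihs_pvalue(df$ihs_norm)
  }
  .manhattan(df, "p", expression(-log[10](p[iHS])), threshold)
}

#' Manhattan plot of a per-variant F_ST scan
#'
#' @param object an [fst_scan()] tibble (after [fst_pvalues()]).
#' @param threshold optional genome-wide significance level drawn as a line.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.fst_scan <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object)
  if (!"p_fst" %in% names(df)) {
    stop("compute p-values first (fst_pvalues())", call. = FALSE)
  }
  .manhattan(df, "p_fst", expression(-log[10](p[F[ST]])), threshold)
}

#' Manhattan-style plot of a DRC scan
#'
#' @param object a [drc_bins()] table with p-value columns
#'   (see [drc_pvalues()]).
#' @param stat which timescale to plot, e.g. `"drc_150"` (default: the
#'   largest available).
#' @param threshold optional genome-wide significance level drawn as a line.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.drc_scan <- function(object, stat = NULL, threshold = NULL, ...) {
  df <- as_tibble(object)
  cols <- grep("^p_drc_", names(df), value = TRUE)
  if (!length(cols)) stop("compute p-values first (drc_pvalues())", call. = FALSE)
  if (is.null(stat)) {
    stat <- sub("^p_", "", cols[which.max(as.numeric(sub("p_drc_", "", cols)))])
  }
  pcol <- paste0("p_", stat)
  df$mid_cM <- (df$start_cM + df$end_cM) / 2
  df <- df[!is.na(df[[pcol]]), , drop = FALSE]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_cM,
                                         y = -log10(.data[[pcol]]))) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)",
                  y = bquote(-log[10](p) ~ "," ~ .(stat)))
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Scatter plot of PCA scores
#'
#' @param object a [pca_top_k()] result.
#' @param components which two PCs to draw (default 1:2).
#' @param groups optional tibble (`sample_id`, `group`) used to colour
#'   points.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.panel_pca <- function(object, components = 1:2, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    df <- left_join(df, as_tibble(groups), by = "sample_id")
  }
  xs <- paste0("PC", components[1])
  ys <- paste0("PC", components[2])
  aes <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data[[xs]], y = .data[[ys]], colour = .data$group)
  } else {
    ggplot2::aes(x = .data[[xs]], y = .data[[ys]])
  }
  ggplot2::ggplot(df, aes) + ggplot2::geom_point(size = 0.8)
}
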