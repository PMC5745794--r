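# ggplot2 autoplot methods for the package's result types.

#' Plot a sweep scan
#'
#' Statistic along the scan grid with the calibrated cutoff (dashed) and
#' significant regions shaded, when a cutoff is set.
#'
#' @param object A `sweep_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                         y = .data$statistic)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)",
                  y = toupper(attr(object, "method")),
                  title = sprintf("%s sweep scan", toupper(attr(object, "method")))) +
    ggplot2::theme_minimal()
  cutoff <- attr(object, "cutoff")
  if (is.finite(cutoff)) {
    regions <- merge_regions(object)
    if (nrow(regions)) {
      gp <- gp + ggplot2::geom_rect(
        data = regions, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        fill = "firebrick", alpha = 0.15)
    }
    gp <- gp + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                                   colour = "firebrick")
  }
  gp
}

#' Plot a LOD curve
#'
#' @param object A `lod_curve` from [interval_mapping()].
#' @param threshold Optional genome-wide LOD threshold to draw.
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @export
autoplot.lod_curve <- function(object, threshold = NULL, ...) {
  gp <- ggplot2::ggplot(tibble::as_tibble(object),
                        ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "map position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gp <- gp + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed", colour = "firebrick")
  }
  gp
}

#' Plot windowed statistics
#'
#' @param object A `window_stats` tibble (from [nucleotide_diversity()],
#'   [watterson_theta()] or [hudson_fst()]).
#' @param ... Unused.
#' @return A ggplot of the statistic along window midpoints.
#' @export
autoplot.window_stats <- function(object, ...) {
  statistic <- attr(object, "statistic")
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid,
                                   y = .data[[statistic]])) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = statistic) +
    ggplot2::theme_minimal()
}

#' Plot a joint SFS
#'
#' @param object A `joint_sfs`.
#' @param trans Count transformation (default log10(1 + x)).
#' @param ... Unused.
#' @return A ggplot heat map of spectrum cells (masked cells blank).
#' @export
autoplot.joint_sfs <- function(object, trans = function(x) log10(1 + x), ...) {
  m <- object$counts
  df <- tidyr::expand_grid(i = 0:(nrow(m) - 1), j = 0:(ncol(m) - 1))
  df$value <- as.numeric(m[cbind(df$i + 1, df$j + 1)])
  df$masked <- object$mask[cbind(df$i + 1, df$j + 1)]
  df$value[df$masked] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = trans(.data$value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92",
                                  name = "log10(1 + n)") +
    ggplot2::labs(x = "deme-2 allele count", y = "deme-1 allele count") +
    ggplot2::theme_minimal()
}

#' Plot a SNP saturation curve
#'
#' @param object A `saturation_curve` from [snp_saturation()].
#' @param ... Unused.
#' @return A ggplot with mean +/- sd ribbons.
#' @export
autoplot.saturation_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subsample_size,
                                   y = .data$mean_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_s - .data$sd_s,
                                      ymax = .data$mean_s + .data$sd_s),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "haplotypes sampled", y = "segregating sites") +
    ggplot2::theme_minimal()
}
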