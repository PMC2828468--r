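#' Plot a LogR track with deletion calls
#'
#' Scatter of per-SNP LogR along one chromosome for one sample, with the
#' strict threshold line and optional call intervals highlighted.
#'
#' @param tracks LogR matrix (samples x SNPs).
#' @param map A `genome_model` or SNP table.
#' @param sample Sample id (a row of `tracks`).
#' @param chrom Chromosome to show.
#' @param calls Optional call tibble to overlay.
#' @param threshold Threshold line, default the strict caller default.
#' @param xlim Optional bp window.
#' @return A ggplot object.
#' @export
plot_logr_track <- function(tracks, map, sample, chrom, calls = NULL,
                            threshold = DELHOT_STRICT_THRESHOLD, xlim = NULL) {
  snps <- as_snp_map(map)
  i <- which(snps$chrom == chrom)
  df <- tibble(pos = snps$pos[i] / 1e6, logr = tracks[sample, i])
  if (!is.null(xlim)) df <- dplyr::filter(df, .data$pos >= xlim[1] / 1e6,
                                          .data$pos <= xlim[2] / 1e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$logr)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = sprintf("%s position (Mb)", chrom), y = "LogR ratio",
                  title = sample) +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    cc <- dplyr::filter(calls, .data$sample == !!sample, .data$chrom == !!chrom)
    if (nrow(cc)) {
      p <- p + ggplot2::annotate("rect", xmin = cc$start / 1e6,
                                 xmax = cc$end / 1e6, ymin = -Inf, ymax = Inf,
                                 alpha = 0.15, fill = "firebrick")
    }
  }
  p
}

#' @describeIn scan_hotspots Occupancy histogram: observed number of bins
#'   holding k events against the homogeneous-Poisson expectation (log
#'   scale); the departure at high k is the hotspot signal.
#' @param object A `hotspot_scan`.
#' @param ... Unused.
#' @export
autoplot.hotspot_scan <- function(object, ...) {
  df <- object$expected |>
    tidyr::pivot_longer(c("observed", "expected"), names_to = "series",
                        values_to = "bins") |>
    dplyr::filter(.data$bins > 0 | .data$series == "observed")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = pmax(.data$bins, 1e-3),
                                   fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "independent deletions per bin", y = "number of bins",
                  fill = NULL,
                  title = sprintf("Poisson scan: N = %d events, %d bins of %g Mb",
                                  object$N, object$B, object$unit / 1e6)) +
    ggplot2::theme_minimal()
}

#' @describeIn trio_ledger Bar chart of the verification bookkeeping counts.
#' @param object A `trio_ledger`.
#' @param ... Unused.
#' @export
autoplot.trio_ledger <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!is.na(.data$count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                   y = stats::reorder(.data$metric, .data$count))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "count", y = NULL, title = "Trio verification ledger") +
    ggplot2::theme_minimal()
}
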