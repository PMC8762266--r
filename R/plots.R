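#' Plot stratified accuracy curves across panel sizes
#'
#' Accuracy (dosage r-squared) against the number of added NAT reference
#' genomes, one line per local-ancestry diplotype, faceted by MAF class.
#'
#' @param table Accuracy table from [incremental_experiment()].
#' @param bins MAF classes to show (default: all except `"all"`).
#' @return A ggplot object.
#' @export
plot_accuracy_curves <- function(table, bins = NULL) {
  if (is.null(bins)) bins <- setdiff(unique(table$bin), "all")
  df <- table[table$bin %in% bins & !is.na(table$r2), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$added_ref_count,
                                   y = .data$r2,
                                   colour = .data$diplotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~bin) +
    ggplot2::labs(x = "added NAT reference genomes",
                  y = expression(dosage ~ r^2),
                  colour = "diplotype") +
    ggplot2::theme_bw()
}

#' Plot improvement-over-baseline curves by MAF class
#'
#' `delta r2(s) = r2(s) - r2(0)` for the underrepresented diplotype, one
#' line per MAF class.
#'
#' @param gap Result of [gap_analysis()].
#' @return A ggplot object.
#' @export
plot_delta_curves <- function(gap) {
  df <- gap$delta[gap$delta$bin != "all", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$added_ref_count,
                                   y = .data$delta_r2,
                                   colour = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "added NAT reference genomes",
                  y = expression(Delta ~ r^2 ~ "vs base panel"),
                  colour = "MAF class") +
    ggplot2::theme_bw()
}
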