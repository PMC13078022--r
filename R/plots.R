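# ggplot2 views of the main result types. These are thin presentation
# layers: every number they draw comes from the tables the pipeline already
# produced.

#' Plot pair scores against permutation p-values
#'
#' @param object An `mf_pair_calls` tibble from [score_all_pairs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_pair_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score,
    y = -log10(.data$p_value), colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "clonality score", y = "-log10 permutation p",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of patient classes
#'
#' @param patients Classification tibble from [classify_patients()].
#' @return A ggplot.
#' @export
plot_patient_classification <- function(patients) {
  counts <- dplyr::count(patients, .data$label)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$label, y = .data$n,
    fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "patients") +
    ggplot2::theme_minimal()
}

#' Violin plot of a per-pair similarity metric by pair class
#'
#' The canonical view of the pair-class framework: clonal pairs should sit
#' above non-clonal pairs, and non-clonal pairs should overlap the
#' inter-patient distribution.
#'
#' @param records Pair-class records carrying a numeric metric column.
#' @param metric Column name to plot (e.g. `"cor_cn"`, `"cor_expr"`).
#' @return A ggplot.
#' @export
plot_pair_class_metric <- function(records, metric) {
  stopifnot(metric %in% names(records))
  df <- filter(records, !is.na(.data[[metric]]))
  df$pair_class <- factor(df$pair_class,
    levels = c("clonal", "non_clonal", "inter_patient"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_class, y = .data[[metric]],
    fill = .data$pair_class)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, fill = "white", outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Copy-number heatmap of tumor units
#'
#' @param unit_cn Aggregated unit copy-number tibble from
#'   [aggregate_unit_copy_number()].
#' @return A ggplot.
#' @export
plot_unit_copy_number <- function(unit_cn) {
  df <- mutate(unit_cn, bin = paste(.data$chrom, .data$start, sep = ":"))
  df$bin <- factor(df$bin, levels = unique(df$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$unit_id,
    fill = .data$cn)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "#2166AC",
      mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "CN") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
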