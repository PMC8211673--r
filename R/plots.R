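# ggplot2 views of the main result types.

#' Compare intra- and inter-individual distance distributions
#'
#' Box-and-jitter plot of one or more distance sets — typically the
#' intra-individual set against each year's inter-individual set, the
#' comparison that motivates the 0.4 threshold.
#'
#' @param ... Named [intra_individual()] / [inter_individual()] tibbles
#'   (names become x-axis labels).
#' @param threshold Optional horizontal reference line (e.g. 0.4).
#' @return A ggplot.
#' @export
plot_distance_comparison <- function(..., threshold = NULL) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  df <- purrr::imap_dfr(sets, ~tibble::tibble(set = .y,
                                              distance = .x$distance))
  df$set <- factor(df$set, levels = names(sets))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$set,
                                        y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.25, size = 0.6) +
    ggplot2::labs(x = NULL, y = "distance") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "orange")
  }
  p
}

#' Histogram of per-subject first-interval change with the threshold
#'
#' @param object A [stability_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_report <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$jsd_12)) +
    ggplot2::geom_histogram(binwidth = 0.025, boundary = 0,
                            fill = "grey65", colour = "white") +
    ggplot2::geom_vline(xintercept = thr, colour = "orange",
                        linewidth = 0.8) +
    ggplot2::labs(x = "intra-individual JSD (1st-2nd year)",
                  y = "subjects") +
    ggplot2::theme_minimal()
}

#' Per-family abundance changes, optionally split by group
#'
#' Boxplots of the signed year-to-year change in each family's relative
#' abundance; medians near zero with group-dependent spread is the
#' pattern the dispersion (Levene) comparison targets.
#'
#' @param deltas A [family_deltas()] tibble.
#' @param group Optional named vector or data frame mapping `subject_id`
#'   to a group label.
#' @return A ggplot.
#' @export
plot_family_deltas <- function(deltas, group = NULL) {
  df <- deltas
  if (!is.null(group)) {
    if (is.data.frame(group)) {
      df <- dplyr::left_join(df, group, by = "subject_id")
      names(df)[ncol(df)] <- "group"
    } else {
      df$group <- group[df$subject_id]
    }
  }
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$family, y = .data$delta)
  } else {
    ggplot2::aes(x = .data$family, y = .data$delta, fill = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "abundance change (year 2 - year 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
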