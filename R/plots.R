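#' Plot per-recipient evacuation margins
#'
#' Horizontal bar chart of the margin between tsunami arrival and total
#' evacuation time; delayed escapes (negative margins) plot to the left of
#' the zero line. Recipients with an undefined margin (outside the 30-cm
#' arrival field) are omitted with a caption note.
#'
#' @param object An `evac_timing` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.evac_timing <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(!is.na(.data$margin))
  n_na <- nrow(object) - nrow(df)
  df$id <- factor(df$id, levels = df$id[order(df$margin)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$margin, y = .data$id,
                                   fill = .data$delayed)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                               name = "delayed escape") +
    ggplot2::labs(
      x = "margin before tsunami arrival (min)", y = "recipient",
      caption = if (n_na > 0)
        sprintf("%d recipient(s) outside the 30-cm arrival field not shown", n_na)) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity analysis as a margin heatmap
#'
#' Tile map of integer-display margins, recipients by scenario (multi-way)
#' or parameter/factor run (one-way), with delayed cells outlined.
#'
#' @param object An `evac_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.evac_sensitivity <- function(object, ...) {
  df <- object$margins |> dplyr::filter(!is.na(.data$margin_display))
  df$run <- if (object$type == "multi_way") df$scenario else
    paste0(df$parameter, " x", df$factor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$id,
                                   fill = .data$margin_display)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$delayed), linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0,
                                  name = "margin (min)") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = NA, `TRUE` = "black"),
                                 name = "delayed") +
    ggplot2::labs(x = if (object$type == "multi_way") "scenario" else "run",
                  y = "recipient") +
    ggplot2::theme_minimal()
}
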