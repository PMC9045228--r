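#' Variant-frequency bar chart
#'
#' Bars at the per-variant mean relative abundance; when several replicates
#' are present (a `sample` or `replicate` column), whiskers show the
#' standard deviation across them.
#'
#' @param data Tibble with `variant` and `frequency` columns, optionally
#'   `sample`/`replicate`.
#' @return A ggplot object.
#' @export
plot_variant_frequencies <- function(data) {
  if (!all(c("variant", "frequency") %in% names(data))) {
    abort("`data` needs columns variant, frequency")
  }
  summ <- data |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      mean = mean(.data$frequency),
      sd = stats::sd(.data$frequency),
      n = dplyr::n(),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$variant, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "pilV variant", y = "relative abundance") +
    ggplot2::theme_classic()
  if (any(summ$n > 1L)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean - .data$sd, 0),
        ymax = .data$mean + .data$sd
      ),
      width = 0.25
    )
  }
  p
}

#' Transfer-rate heat map with censored cells marked
#'
#' Variant-by-recipient heat map of conjugation frequencies (log10 fill);
#' cells whose frequency is below the detection limit (`censored == TRUE`)
#' carry a cross mark.
#'
#' @param data Tibble with `variant`, `recipient`, `value` and optionally
#'   `censored` columns.
#' @return A ggplot object.
#' @export
plot_transfer_heatmap <- function(data) {
  needed <- c("variant", "recipient", "value")
  if (!all(needed %in% names(data))) {
    abort("`data` needs columns variant, recipient, value")
  }
  if (!"censored" %in% names(data)) data$censored <- FALSE
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$recipient, y = .data$variant, fill = log10(.data$value))
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "log10 frequency") +
    ggplot2::labs(x = "recipient strain", y = "pilV variant") +
    ggplot2::theme_minimal()
  cens <- data[data$censored, , drop = FALSE]
  if (nrow(cens)) {
    p <- p + ggplot2::geom_point(
      data = cens,
      ggplot2::aes(x = .data$recipient, y = .data$variant),
      shape = 4, size = 3, colour = "white", inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot shufflon_abundance
#' @export
autoplot.shufflon_abundance <- function(object, ...) {
  plot_variant_frequencies(object)
}

#' @method autoplot shufflon_enrichment
#' @export
autoplot.shufflon_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$variant, y = .data$log2fc)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$log2fc > 0), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "pilV variant", y = "log2 fold change (trans / donor)") +
    ggplot2::theme_classic()
}

#' @method autoplot shufflon_population
#' @export
autoplot.shufflon_population <- function(object, ...) {
  marg <- object |>
    dplyr::group_by(.data$active_variant) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    dplyr::rename(variant = "active_variant")
  plot_variant_frequencies(marg)
}
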