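#' Plot a weighted-reasons preference table
#'
#' Bar chart of the weighted-reasons index per trait group, faceted by the
#' stratification factors (site by breed when present), filled by quality
#' class.
#'
#' @param object A `pref_table` from [preference_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pref_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wr,
    y = stats::reorder(.data$trait_group, .data$wr, FUN = max)
  ))
  if ("quality" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$quality),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  if (all(c("site", "breed") %in% names(df))) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$breed), cols = ggplot2::vars(.data$site)
    )
  }
  p + ggplot2::labs(x = "weighted reasons (WR)", y = NULL, fill = NULL)
}

#' @rdname autoplot.pref_table
#' @export
autoplot.cluster_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  names(df)[names(df) == "cluster"] <- "trait_group"
  autoplot.pref_table(structure(df, by = attr(object, "by"),
                                class = c("pref_table", class(df))))
}

#' Plot least-squares means with letter groups
#'
#' Point-and-interval plot of the LS-means (estimate plus/minus one
#' standard error) with compact letter display labels when present.
#'
#' @param object A `lsmeans_tbl` from [ls_means()] or [letter_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsmeans_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  margin <- attr(object, "margin")
  df$level <- do.call(paste, c(df[margin], sep = " "))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                        y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$se, ymax = .data$estimate + .data$se
    )) +
    ggplot2::labs(x = NULL, y = attr(object, "response") %||% "LS-mean")
  if ("letters" %in% names(df)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data$letters,
                   y = .data$estimate + 1.5 * .data$se),
      vjust = 0
    )
  }
  p
}
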