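# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a measure table
#'
#' Returns the per-map measures in long form: one row per map and measure.
#'
#' @param x A `measure_tbl`.
#' @param ... Unused.
#' @return A tibble with columns `source_code`, `measure`, `bits` and, when
#'   normalized, `z`.
#' @export
tidy.measure_tbl <- function(x, ...) {
  long <- as_tibble(x) %>%
    select("source_code", "h_a", "h_b", "ur") %>%
    tidyr::pivot_longer(c("h_a", "h_b", "ur"),
                        names_to = "measure", values_to = "bits")
  if (isTRUE(attr(x, "normalized"))) {
    z <- as_tibble(x) %>%
      select("source_code", "z_alpha", "z_beta", "z_ur") %>%
      tidyr::pivot_longer(-"source_code", values_to = "z") %>%
      mutate(measure = c(z_alpha = "h_a", z_beta = "h_b",
                         z_ur = "ur")[.data$name]) %>%
      select("source_code", "measure", "z")
    long <- left_join(long, z, by = c("source_code", "measure"))
  }
  long
}

#' One-row summary of a measure table
#'
#' @param x A `measure_tbl`.
#' @param ... Unused.
#' @return A one-row tibble: number of maps measured and excluded, share of
#'   one-to-one maps, share of combination maps, and the mean of each
#'   measure in bits.
#' @export
glance.measure_tbl <- function(x, ...) {
  tibble(
    n_maps = nrow(x),
    n_excluded = attr(x, "n_excluded") %||% NA_integer_,
    prop_one_to_one = mean(x$m == 1L),
    prop_combination = mean(x$v != x$m),
    mean_h_a = mean(x$h_a),
    mean_h_b = mean(x$h_b),
    mean_ur = mean(x$ur)
  )
}

#' @export
tidy.word_graph <- function(x, ...) x$nodes

#' @export
glance.word_graph <- function(x, ...) {
  tibble(
    n_words = nrow(x$nodes),
    n_edges = nrow(x$edges),
    top_word = x$nodes$word[which.max(x$nodes$centrality)]
  )
}

#' Scatter plot of the two normalized entropic measures
#'
#' One point per map, alphabet-entropy score against representation-entropy
#' score, the view the outlier thresholds are drawn on.
#'
#' @param object A normalized `measure_tbl`.
#' @param threshold Optional Z cutoff drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.measure_tbl <- function(object, threshold = NULL, ...) {
  if (!isTRUE(attr(object, "normalized"))) {
    abort("normalize the table before plotting")
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$z_alpha, .data$z_beta)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = "Z(α)  (alphabet entropy, normalized)",
      y = "Z(β)  (representation entropy, normalized)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p +
      ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "red") +
      ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red")
  }
  p
}

#' Ranked-class bar chart
#'
#' Clustered bars of the per-class sums of the three normalized measures,
#' classes ordered from least to most total information gain.
#'
#' @param object A `class_score_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_score_tbl <- function(object, ...) {
  long <- object %>%
    mutate(label = factor(.data$label, levels = .data$label)) %>%
    tidyr::pivot_longer(c("sum_z_alpha", "sum_z_beta", "sum_z_ur"),
                        names_to = "measure", values_to = "sum_z")
  ggplot2::ggplot(long, ggplot2::aes(.data$sum_z, .data$label,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "sum of normalized measures", y = NULL, fill = NULL) +
    ggplot2::scale_fill_brewer(
      palette = "Dark2",
      labels = c(sum_z_alpha = "Z(α)", sum_z_beta = "Z(β)",
                 sum_z_ur = "Z(UR)")
    ) +
    ggplot2::theme_minimal()
}

#' Word-salience bar chart
#'
#' Top words of the co-occurrence network by eigenvector centrality.
#'
#' @param object A `word_graph`.
#' @param n Number of words to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.word_graph <- function(object, n = 20L, ...) {
  top <- object$nodes %>%
    arrange(dplyr::desc(.data$centrality)) %>%
    head(n) %>%
    mutate(word = factor(.data$word, levels = rev(.data$word)))
  ggplot2::ggplot(top, ggplot2::aes(.data$centrality, .data$word)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "eigenvector centrality", y = NULL) +
    ggplot2::theme_minimal()
}
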