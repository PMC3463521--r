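# ggplot2 displays for the main result types

#' Bar chart of karyomorph frequencies
#'
#' @param freqs a frequency table from [frequency_table()].
#' @param populations optional subset of population ids to show (the pooled
#'   row is kept if present).
#' @return A ggplot object.
#' @examples
#' plot_karyomorph_frequencies(
#'   frequency_table(example_karyomorph_counts()),
#'   populations = c("Xuankouzhen", "Gaotangsi", "pooled")
#' )
#' @export
plot_karyomorph_frequencies <- function(freqs, populations = NULL) {
  if (!is.null(populations)) {
    freqs <- filter(freqs, .data$population_id %in% populations)
  }
  ggplot2::ggplot(
    freqs,
    ggplot2::aes(x = .data$karyomorph, y = .data$freq)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$population_id)) +
    ggplot2::labs(
      x = "karyomorph", y = "frequency",
      title = "Karyomorph frequencies"
    ) +
    ggplot2::theme_minimal()
}

#' Frequency trajectory of a forward simulation
#'
#' @param trajectory a tibble from [simulate_generations()] or
#'   [simulate_dispersal()].
#' @return A ggplot object (one line per karyomorph over generations).
#' @examples
#' traj <- simulate_dispersal(N = 20, generations = 10,
#'                            params = segregation_params(0.9, 0.1, 0))
#' plot_trajectory(traj)
#' @export
plot_trajectory <- function(trajectory) {
  ggplot2::ggplot(
    trajectory,
    ggplot2::aes(x = .data$generation, y = .data$freq,
                 colour = .data$karyomorph)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "generation", y = "frequency", colour = "karyomorph",
      title = "Karyomorph frequency trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_gamete_pool observed versus model-expected karyomorph
#'   counts.
#' @param object a `gamete_pool_fit` object.
#' @method autoplot gamete_pool_fit
#' @export
autoplot.gamete_pool_fit <- function(object, ...) {
  df <- tibble(
    karyomorph = rep(names(object$observed), 2),
    count = c(unname(object$observed), unname(object$expected)),
    kind = rep(c("observed", "expected"), each = length(object$observed))
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$karyomorph, y = .data$count, fill = .data$kind)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(
      x = "karyomorph", y = "individuals (sqrt scale)", fill = NULL,
      title = "Gamete-pool fit: observed vs expected"
    ) +
    ggplot2::theme_minimal()
}
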