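# ggplot2 visualisations for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.delta_d_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$ligation_rate),
                                       y = factor(.data$hydrolysis_rate),
                                       fill = .data$mean_delta_D)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * D ~ "(bits)")) +
    ggplot2::labs(x = "ligation rate", y = "hydrolysis rate",
                  title = "Diversity change per recombination round")
}

#' @exportS3Method ggplot2::autoplot
autoplot.freq_profile <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position, y = .data$freq,
                                 colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position", y = "frequency")
}

#' Plot an RGB signature strip of a frequency profile
#'
#' One tile per position, coloured by the RGB transformation of the
#' nucleotide frequencies (pure C blue, U red, A green, G yellow).
#'
#' @param profile a [frequency_profile()].
#' @return a ggplot object.
#' @export
plot_rgb_signature <- function(profile) {
  sig <- rgb_signature(profile)
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$position, y = 1, fill = .data$hex)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_identity() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "nucleotide signature")
}

#' @exportS3Method ggplot2::autoplot
autoplot.structure_profile <- function(object, ...) {
  tidyr::pivot_longer(as_tibble(object), c("obp", "cbp", "unp"),
                      names_to = "element", values_to = "freq") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$position, y = .data$freq,
                                 fill = .data$element)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = c(obp = "#2e7d32", cbp = "#ef6c00",
                                          unp = "grey70")) +
    ggplot2::labs(x = "position", y = "frequency")
}

#' @exportS3Method ggplot2::autoplot
autoplot.junction_fingerprint <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_plus1, y = .data$n_minus1,
                                       fill = .data$log2_enrichment)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "log2 obs/exp") +
    ggplot2::labs(x = "N+1", y = "N-1",
                  title = "junction dinucleotide fingerprint")
}
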